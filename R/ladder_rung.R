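#' Rung reference line of a ladder run
#'
#' The rung line is the image-y height at which toes rest on the rungs.
#' A configured value is passed through; otherwise it is estimated
#' robustly as an upper quantile of the toe's y values during stance
#' (the paw rests on the rung during stance, so its y concentrates at
#' the rung line; missteps are rare and deeper, and the quantile keeps
#' them out).
#'
#' @param run A side-view [pose_run()] of a ladder crossing.
#' @param rung_y Optional configured rung line (image-y pixels);
#'   returned unchanged when given.
#' @param toe Toe track used for estimation.
#' @param phases Optional `phase_track` for the same toe; when given,
#'   only stance frames enter the estimate.
#' @param prob Quantile of the y distribution used as the estimate
#'   (default 0.75).
#' @return Rung line in image-y pixels.
#' @export
rung_reference <- function(run = NULL, rung_y = NULL,
                           toe = c("front_toe", "back_toe"),
                           phases = NULL, prob = 0.75) {
  if (!is.null(rung_y)) {
    stopifnot(is.numeric(rung_y), length(rung_y) == 1L)
    return(rung_y)
  }
  if (is.null(run) || !inherits(run, "pose_run"))
    stop("rung reference needs either a configured rung_y or a pose_run",
         call. = FALSE)
  toe <- intersect(toe, names(run$series))
  if (!length(toe))
    stop("no toe track available to estimate the rung line", call. = FALSE)
  s <- run$series[[toe[1L]]]
  keep <- s$mask & !is.na(s$y)
  if (!is.null(phases)) keep <- keep & phases$phase == "stance"
  yv <- s$y[keep]
  if (!length(yv))
    stop("no valid toe frames to estimate the rung line", call. = FALSE)
  unname(stats::quantile(yv, prob, type = 7))
}

#' Detect missteps below the rung line
#'
#' A misstep occurs when the toe tip reaches at least `depth_cm`
#' (default 0.5 cm) below the ladder rung line. Contiguous
#' below-threshold frame runs form one event each; events separated by
#' fewer than `merge_gap` frames are merged, and events shorter than
#' `min_len` frames are discarded as tracking jitter.
#'
#' @param toe The toe-tip [keypoint_series()] (side view; image y grows
#'   downward, so below the rung line means `y > rung_y`).
#' @param rung_y Rung line in image-y pixels.
#' @param calibration A [gait_calibration()].
#' @param depth_cm Misstep depth threshold in cm (default 0.5).
#' @param merge_gap Events separated by fewer than this many frames are
#'   merged (default 5).
#' @param min_len Minimum event length in frames (default 2).
#' @return Data frame of class `misstep_events` with columns `paw`,
#'   `start_frame`, `end_frame` (half-open) and `min_depth` (the
#'   deepest excursion of the event, cm below the rung line). Zero rows
#'   when no misstep occurred.
#' @export
detect_missteps <- function(toe, rung_y, calibration = gait_calibration(),
                            depth_cm = 0.5, merge_gap = 5L, min_len = 2L) {
  stopifnot(inherits(toe, "keypoint_series"),
            inherits(calibration, "gait_calibration"),
            depth_cm > 0)
  depth <- (toe$y - rung_y) / calibration$px_per_cm
  below <- toe$mask & !is.na(toe$y) & depth >= depth_cm
  r <- rle(as.logical(below))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- data.frame(start = starts[r$values], end = ends[r$values] + 1L)
  if (nrow(ev) > 1L) {
    merged <- ev[1L, , drop = FALSE]
    for (i in 2L:nrow(ev)) {
      gap <- ev$start[i] - merged$end[nrow(merged)]
      if (gap < merge_gap) merged$end[nrow(merged)] <- ev$end[i]
      else merged <- rbind(merged, ev[i, ])
    }
    ev <- merged
  }
  if (nrow(ev)) ev <- ev[ev$end - ev$start >= min_len, , drop = FALSE]
  out <- data.frame(
    paw = rep(toe$bodypart, nrow(ev)),
    start_frame = ev$start, end_frame = ev$end,
    min_depth = vapply(seq_len(nrow(ev)), function(i)
      max(depth[ev$start[i]:(ev$end[i] - 1L)], na.rm = TRUE), numeric(1)),
    stringsAsFactors = FALSE)
  class(out) <- c("misstep_events", "data.frame")
  out
}

#' Ladder error rate
#'
#' `errors / total steps x 100`, in percent.
#'
#' @param missteps Misstep count (errors).
#' @param total_steps Total step count (> 0).
#' @return Error rate in percent; NA with attribute `"undefined"` when
#'   `total_steps` is 0.
#' @export
error_rate <- function(missteps, total_steps) {
  stopifnot(missteps >= 0, total_steps >= 0, missteps <= total_steps ||
              total_steps == 0)
  if (total_steps == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  missteps / total_steps * 100
}

#' Per-paw ladder run result
#'
#' @param steps Named integer vector: total steps per paw.
#' @param missteps Named integer vector (same names): missteps per paw.
#' @return Object of class `ladder_result`: data frame with per-paw
#'   rows plus a pooled row (`paw == "all"`), columns `paw`,
#'   `total_steps`, `missteps`, `error_rate` (percent).
#' @export
ladder_result <- function(steps, missteps) {
  if (!setequal(names(steps), names(missteps)))
    stop("steps and missteps must cover the same paws", call. = FALSE)
  paws <- names(steps)
  er <- vapply(paws, function(p)
    as.numeric(error_rate(missteps[[p]], steps[[p]])), numeric(1))
  out <- data.frame(
    paw = c(paws, "all"),
    total_steps = c(unname(as.integer(steps[paws])), sum(as.integer(steps))),
    missteps = c(unname(as.integer(missteps[paws])), sum(as.integer(missteps))),
    stringsAsFactors = FALSE)
  out$error_rate <- c(unname(er),
                      as.numeric(error_rate(sum(missteps), sum(steps))))
  class(out) <- c("ladder_result", "data.frame")
  out
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("<ladder_result>\n")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Compare automated misstep scoring with human annotations
#'
#' @param auto Named list (by video id), each element a list with
#'   `events` (a `misstep_events` data frame) and `total_steps`
#'   (pooled step count of the video).
#' @param human Data frame with columns `video_id`, `rater_id`, `paw`,
#'   `frame`, `event` (logical/0-1 flag; rows with `event` truthy mark
#'   one annotated misstep at `frame`).
#' @param tol_frames An automated event matches an annotated frame when
#'   the frame lies within the event extended by this many frames
#'   (default 5).
#' @return List with `rates` (per video x rater error-rate matrix,
#'   machine in column `"auto"`), `correlation` (Pearson matrix across
#'   raters incl. the machine), `recall` (fraction of annotated events
#'   matched by an automated event) and `n_events` (annotated event
#'   count).
#' @export
compare_to_annotations <- function(auto, human, tol_frames = 5L) {
  need <- c("video_id", "rater_id", "paw", "frame", "event")
  if (!all(need %in% names(human)))
    stop("annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  human <- human[as.logical(human$event), , drop = FALSE]
  vids_auto <- names(auto)
  vids_hum <- unique(as.character(human$video_id))
  unmatched <- c(setdiff(vids_hum, vids_auto), setdiff(vids_auto, vids_hum))
  if (length(unmatched))
    stop("unmatched video identifiers: ", paste(unique(unmatched), collapse = ", "),
         call. = FALSE)
  raters <- unique(as.character(human$rater_id))
  rates <- matrix(NA_real_, nrow = length(vids_auto),
                  ncol = length(raters) + 1L,
                  dimnames = list(vids_auto, c("auto", raters)))
  hit <- 0L; tot <- 0L
  for (v in vids_auto) {
    a <- auto[[v]]
    rates[v, "auto"] <- error_rate(nrow(a$events), a$total_steps)
    hv <- human[human$video_id == v, , drop = FALSE]
    for (r in raters) {
      hr <- hv[hv$rater_id == r, , drop = FALSE]
      rates[v, r] <- error_rate(nrow(hr), a$total_steps)
      for (i in seq_len(nrow(hr))) {
        tot <- tot + 1L
        ok <- any(hr$frame[i] >= a$events$start_frame - tol_frames &
                    hr$frame[i] < a$events$end_frame + tol_frames &
                    a$events$paw == hr$paw[i])
        if (ok) hit <- hit + 1L
      }
    }
  }
  corr <- suppressWarnings(stats::cor(rates, use = "pairwise.complete.obs"))
  list(rates = rates, correlation = corr,
       recall = if (tot > 0) hit / tot else NA_real_, n_events = tot)
}
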