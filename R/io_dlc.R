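#' A single keypoint time series
#'
#' One tracked bodypart: per-frame image coordinates, detection
#' likelihood and a validity mask. Masked frames carry no usable
#' coordinate and are excluded from every downstream computation;
#' nothing is ever interpolated.
#'
#' @param bodypart Bodypart name.
#' @param x,y Per-frame image coordinates (y grows downwards).
#' @param likelihood Per-frame detection probability in \[0, 1\]
#'   (NA allowed).
#' @param mask Logical validity flag per frame; defaults to all valid.
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(bodypart, x, y, likelihood = rep(1, length(x)),
                            mask = NULL) {
  n <- length(x)
  if (length(y) != n || length(likelihood) != n)
    stop("x, y and likelihood must have identical length", call. = FALSE)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n)
    stop("mask length must equal the frame count", call. = FALSE)
  lk <- likelihood[!is.na(likelihood)]
  if (length(lk) && (any(lk < 0) || any(lk > 1)))
    stop("likelihood values must lie in [0, 1]", call. = FALSE)
  structure(
    list(bodypart = as.character(bodypart),
         x = as.numeric(x), y = as.numeric(y),
         likelihood = as.numeric(likelihood), mask = as.logical(mask)),
    class = "keypoint_series"
  )
}

#' Number of frames in a series or run
#' @param x A `keypoint_series` or `pose_run`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  if (inherits(x, "keypoint_series")) return(length(x$x))
  if (inherits(x, "pose_run")) {
    if (!length(x$series)) return(0L)
    return(length(x$series[[1L]]$x))
  }
  stop("n_frames() expects a keypoint_series or pose_run", call. = FALSE)
}

#' A calibrated keypoint run for one video and view
#'
#' @param series Named list of [keypoint_series()], keyed by bodypart.
#' @param view One of `"left"`, `"right"`, `"bottom"`.
#' @param calibration A [gait_calibration()].
#' @param metadata List with optional `animal`, `timepoint`, `run` fields.
#' @param direction Travel-direction flag; `+1` once x has been
#'   normalized so progression is towards +x (see
#'   [normalize_direction()]).
#' @return An object of class `pose_run`. Bodyparts outside the view's
#'   canonical set are kept but recorded in the `unknown_bodyparts`
#'   field.
#' @export
pose_run <- function(series, view = c("left", "right", "bottom"),
                     calibration = gait_calibration(), metadata = list(),
                     direction = NA_real_) {
  view <- match.arg(view)
  stopifnot(inherits(calibration, "gait_calibration"), is.list(series))
  if (!length(series)) stop("a pose_run needs at least one series", call. = FALSE)
  if (is.null(names(series)) || any(!nzchar(names(series))))
    names(series) <- vapply(series, function(s) s$bodypart, character(1))
  lens <- vapply(series, function(s) length(s$x), integer(1))
  if (length(unique(lens)) != 1L)
    stop("all series in a run must share one frame count", call. = FALSE)
  canonical <- view_bodyparts(view)
  unknown <- setdiff(names(series), canonical)
  structure(
    list(view = view, series = series, calibration = calibration,
         metadata = metadata, direction = direction,
         unknown_bodyparts = unknown),
    class = "pose_run"
  )
}

#' @export
print.pose_run <- function(x, ...) {
  cat(sprintf("<pose_run: %s view, %d bodyparts x %d frames>\n",
              x$view, length(x$series), n_frames(x)))
  md <- x$metadata
  if (length(md))
    cat("  metadata:", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  valid <- vapply(x$series, function(s) mean(s$mask), numeric(1))
  cat(sprintf("  valid fraction: %.2f-%.2f across bodyparts\n",
              min(valid), max(valid)))
  if (length(x$unknown_bodyparts))
    cat("  unknown bodyparts:", paste(x$unknown_bodyparts, collapse = ", "), "\n")
  invisible(x)
}

#' Read a keypoint table in the DeepLabCut CSV dialect
#'
#' The dialect has three header rows (`scorer`, `bodyparts`, `coords`)
#' followed by one data row per video frame; per bodypart there are
#' three columns `x`, `y`, `likelihood`. The first column indexes
#' frames.
#'
#' @param path Path to the CSV file.
#' @param view Camera view of the table.
#' @param calibration A [gait_calibration()].
#' @param metadata Optional metadata list attached to the run.
#' @return A [pose_run()] with one series per bodypart, mask all-valid.
#' @export
read_dlc_table <- function(path, view = c("left", "right", "bottom"),
                           calibration = gait_calibration(),
                           metadata = list()) {
  view <- match.arg(view)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(nf) < 4L)
    stop("DLC dialect error: need 3 header rows plus data in ", path,
         call. = FALSE)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("parse error: ragged row ", bad, " in ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  hdr <- c("scorer", "bodyparts", "coords")
  for (i in 1:3) {
    if (tolower(raw[i, 1L]) != hdr[i])
      stop("DLC dialect error: expected header row '", hdr[i],
           "' at line ", i, " of ", path, call. = FALSE)
  }
  coords <- as.character(raw[3L, -1L])
  if (!all(coords %in% c("x", "y", "likelihood")))
    stop("DLC dialect error: coords row entries must be x/y/likelihood",
         call. = FALSE)
  bps <- as.character(raw[2L, -1L])
  dat <- raw[-(1:3), , drop = FALSE]
  vals <- vapply(dat[, -1L, drop = FALSE], as.numeric,
                 numeric(nrow(dat)))
  vals <- matrix(vals, nrow = nrow(dat))
  series <- list()
  for (bp in unique(bps)) {
    idx <- which(bps == bp)
    get <- function(coord) {
      j <- idx[coords[idx] == coord]
      if (length(j) != 1L)
        stop("DLC dialect error: bodypart '", bp, "' lacks a single '",
             coord, "' column", call. = FALSE)
      vals[, j]
    }
    series[[bp]] <- keypoint_series(bp, get("x"), get("y"), get("likelihood"))
  }
  pose_run(series, view = view, calibration = calibration,
           metadata = metadata)
}

#' Write a run back out in the DeepLabCut CSV dialect
#'
#' Numbers are written with 17 significant digits so that a
#' write -> read -> write cycle is byte-identical and coordinates
#' round-trip exactly.
#'
#' @param run A [pose_run()].
#' @param path Output file path.
#' @param scorer Scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_dlc_table <- function(run, path, scorer = "gaitprofiler") {
  stopifnot(inherits(run, "pose_run"))
  if (!length(run$series)) stop("nothing to write: empty series collection",
                                call. = FALSE)
  bps <- names(run$series)
  n <- n_frames(run)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  cols <- list()
  for (bp in bps) {
    s <- run$series[[bp]]
    cols[[length(cols) + 1L]] <- fmt(s$x)
    cols[[length(cols) + 1L]] <- fmt(s$y)
    cols[[length(cols) + 1L]] <- fmt(s$likelihood)
  }
  body <- do.call(cbind, c(list(as.character(seq_len(n) - 1L)), cols))
  h1 <- c("scorer", rep(scorer, 3L * length(bps)))
  h2 <- c("bodyparts", rep(bps, each = 3L))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), length(bps)))
  lines <- c(paste(h1, collapse = ","),
             paste(h2, collapse = ","),
             paste(h3, collapse = ","),
             apply(body, 1L, paste, collapse = ","))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Mask low-likelihood keypoints
#'
#' Frames whose detection likelihood falls below the threshold are
#' masked out (excluded), never interpolated. Existing masks are kept:
#' filtering can only remove frames, so it is idempotent and monotone
#' in the threshold.
#'
#' @param run A [pose_run()].
#' @param threshold Likelihood cutoff in \[0, 1\]; defaults to the run
#'   calibration's `likelihood_threshold`.
#' @return The run with updated masks; the per-bodypart retained
#'   fraction is stored in the `qc` field (a data frame with columns
#'   `bodypart`, `retained`, `all_masked`).
#' @export
filter_likelihood <- function(run, threshold = run$calibration$likelihood_threshold) {
  stopifnot(inherits(run, "pose_run"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  for (bp in names(run$series)) {
    s <- run$series[[bp]]
    if (threshold == 0) next  # identity: no frame fails a zero threshold
    keep <- !is.na(s$likelihood) & s$likelihood >= threshold
    run$series[[bp]]$mask <- s$mask & keep
  }
  retained <- vapply(run$series, function(s) mean(s$mask), numeric(1))
  run$qc <- data.frame(bodypart = names(run$series),
                       retained = unname(retained),
                       all_masked = unname(retained) == 0,
                       row.names = NULL, stringsAsFactors = FALSE)
  run
}

#' Normalize the direction of travel
#'
#' Mirrors the x axis when the animal ran right-to-left, so that
#' progression is always towards +x. The net displacement sign of a
#' reference track (tail base, tail or head — first available) decides.
#'
#' @param run A [pose_run()].
#' @param reference Candidate reference bodyparts, tried in order.
#' @return The run with `direction = +1` and x mirrored if needed.
#' @export
normalize_direction <- function(run, reference = c("tail_base", "tail", "head")) {
  stopifnot(inherits(run, "pose_run"))
  ref <- intersect(reference, names(run$series))
  if (!length(ref))
    stop("no reference bodypart available to detect travel direction",
         call. = FALSE)
  s <- run$series[[ref[1L]]]
  xv <- s$x[s$mask & !is.na(s$x)]
  if (length(xv) < 2L)
    stop("reference track too short to detect travel direction", call. = FALSE)
  disp <- xv[length(xv)] - xv[1L]
  if (disp < 0) {
    for (bp in names(run$series)) run$series[[bp]]$x <- -run$series[[bp]]$x
  }
  run$direction <- 1
  run
}

# frames valid in both runs for one bodypart
.joint_valid <- function(a, b) {
  a$mask & b$mask & !is.na(a$x) & !is.na(a$y) & !is.na(b$x) & !is.na(b$y)
}

#' Labelling accuracy: per-bodypart pixel RMSE
#'
#' Root-mean-squared Euclidean distance between predicted and
#' ground-truth coordinates, computed per bodypart over frames valid in
#' both runs.
#'
#' @param predicted,truth Two [pose_run()]s with the same frame count
#'   and bodypart set.
#' @return Named numeric vector of RMSEs in pixels; `NA` (flagged via
#'   the `"undefined"` attribute) for bodyparts with no jointly valid
#'   frame.
#' @export
label_rmse <- function(predicted, truth) {
  stopifnot(inherits(predicted, "pose_run"), inherits(truth, "pose_run"))
  if (n_frames(predicted) != n_frames(truth))
    stop("runs must share the frame count", call. = FALSE)
  bps <- names(predicted$series)
  if (!setequal(bps, names(truth$series)))
    stop("runs must share the bodypart set", call. = FALSE)
  out <- vapply(bps, function(bp) {
    p <- predicted$series[[bp]]; g <- truth$series[[bp]]
    ok <- .joint_valid(p, g)
    if (!any(ok)) return(NA_real_)
    sqrt(mean((p$x[ok] - g$x[ok])^2 + (p$y[ok] - g$y[ok])^2))
  }, numeric(1))
  attr(out, "undefined") <- bps[is.na(out)]
  out
}

#' Fraction of confidently placed labels
#'
#' Fraction of jointly valid frames whose predicted keypoint lies
#' within `dist_px` pixels of the ground truth, per bodypart, plus the
#' pooled fraction under `"overall"`.
#'
#' @inheritParams label_rmse
#' @param dist_px Distance threshold in pixels (default: the predicted
#'   run calibration's `confidence_dist_px`, 17 px).
#' @return Named numeric vector (one entry per bodypart plus
#'   `"overall"`).
#' @export
confident_label_ratio <- function(predicted, truth,
                                  dist_px = predicted$calibration$confidence_dist_px) {
  stopifnot(inherits(predicted, "pose_run"), inherits(truth, "pose_run"),
            dist_px > 0)
  if (n_frames(predicted) != n_frames(truth))
    stop("runs must share the frame count", call. = FALSE)
  bps <- names(predicted$series)
  if (!setequal(bps, names(truth$series)))
    stop("runs must share the bodypart set", call. = FALSE)
  hit <- 0; tot <- 0
  out <- vapply(bps, function(bp) {
    p <- predicted$series[[bp]]; g <- truth$series[[bp]]
    ok <- .joint_valid(p, g)
    if (!any(ok)) return(NA_real_)
    d <- sqrt((p$x[ok] - g$x[ok])^2 + (p$y[ok] - g$y[ok])^2)
    hit <<- hit + sum(d <= dist_px); tot <<- tot + length(d)
    mean(d <= dist_px)
  }, numeric(1))
  c(out, overall = if (tot > 0) hit / tot else NA_real_)
}
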