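#' Per-frame horizontal paw speed
#'
#' Speed of a paw defined by the horizontal distance covered between two
#' consecutive frames, converted to cm/s. The first frame and any frame
#' adjacent to a masked frame have no speed (NA).
#'
#' @param series A [keypoint_series()] (travel-direction-normalized x).
#' @param calibration A [gait_calibration()].
#' @return Numeric vector of per-frame speeds in cm/s, same length as
#'   the series; NA where undefined.
#' @export
paw_speed <- function(series, calibration = gait_calibration()) {
  stopifnot(inherits(series, "keypoint_series"),
            inherits(calibration, "gait_calibration"))
  n <- length(series$x)
  if (n < 2L) stop("need at least 2 frames to compute speed", call. = FALSE)
  ok <- series$mask & !is.na(series$x)
  sp <- rep(NA_real_, n)
  d <- abs(diff(series$x))
  valid_pair <- ok[-n] & ok[-1L]
  sp[-1L][valid_pair] <- d[valid_pair] / calibration$px_per_cm * calibration$fps
  sp
}

# windowed median that tolerates NA gaps (runmed cannot);
# centre-NA frames stay NA so masked gaps propagate
.median_smooth <- function(v, k) {
  if (k <= 1L) return(v)
  half <- (k - 1L) %/% 2L
  n <- length(v)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (is.na(v[t])) next
    w <- v[max(1L, t - half):min(n, t + half)]
    out[t] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Classify stance and swing phases from paw speed
#'
#' A frame belongs to the swing phase when the (median-smoothed) paw
#' speed exceeds the threshold (10 cm/s), otherwise to stance. Phases
#' shorter than `min_phase` frames are merged into their surrounding
#' phase to debounce single-frame jitter. Frames without a defined
#' speed are `invalid`.
#'
#' @param speed Per-frame speed in cm/s, from [paw_speed()].
#' @param threshold Swing speed threshold in cm/s (default 10).
#' @param smooth Width of the median smoothing window in frames
#'   (default 3; 1 disables smoothing).
#' @param min_phase Minimum phase length in frames (default 3; 1
#'   disables debouncing).
#' @param paw Optional paw name carried along.
#' @return An object of class `phase_track`: list with `paw` and
#'   `phase`, a character vector over frames with values
#'   `"stance"`, `"swing"`, `"invalid"`.
#' @export
classify_phases <- function(speed, threshold = 10, smooth = 3L,
                            min_phase = 3L, paw = NA_character_) {
  stopifnot(is.numeric(speed), threshold > 0)
  sm <- .median_smooth(speed, smooth)
  phase <- ifelse(is.na(sm), "invalid",
                  ifelse(sm > threshold, "swing", "stance"))
  if (min_phase > 1L) phase <- .merge_short_phases(phase, min_phase)
  structure(list(paw = paw, phase = phase), class = "phase_track")
}

# merge stance/swing runs shorter than min_len into a neighbouring
# phase (the longer valid neighbour); invalid runs are left alone
.merge_short_phases <- function(phase, min_len) {
  repeat {
    r <- rle(phase)
    short <- which(r$lengths < min_len & r$values %in% c("stance", "swing"))
    # never merge a short run bounded only by invalid frames or edges
    cand <- NULL
    for (i in short) {
      left <- if (i > 1L && r$values[i - 1L] %in% c("stance", "swing")) i - 1L else NA
      right <- if (i < length(r$values) && r$values[i + 1L] %in% c("stance", "swing")) i + 1L else NA
      if (!is.na(left) || !is.na(right)) { cand <- i; break }
    }
    if (is.null(cand)) return(inverse.rle(r))
    i <- cand
    left_len <- if (i > 1L && r$values[i - 1L] %in% c("stance", "swing")) r$lengths[i - 1L] else -1L
    right_len <- if (i < length(r$values) && r$values[i + 1L] %in% c("stance", "swing")) r$lengths[i + 1L] else -1L
    r$values[i] <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
    phase <- inverse.rle(r)
  }
}

#' Segment a phase track into step cycles
#'
#' A step cycle spans one stance onset to the next stance onset of the
#' same paw. Incomplete leading and trailing fragments are dropped.
#' Cycles whose valid frames do not form one stance run followed by one
#' swing run are discarded.
#'
#' @param phases A `phase_track` from [classify_phases()].
#' @return An object of class `step_cycles`: a data frame with one row
#'   per cycle and columns `paw`, `start_frame`, `end_frame` (half-open:
#'   the cycle covers frames `start_frame` to `end_frame - 1`),
#'   `stance_start`, `stance_end`, `swing_start`, `swing_end` (also
#'   half-open). Empty (0-row) when no complete cycle exists, with
#'   attribute `"flagged"` set.
#' @export
segment_steps <- function(phases) {
  stopifnot(inherits(phases, "phase_track"))
  ph <- phases$phase
  n <- length(ph)
  prev_valid <- rep(NA_character_, n)
  last <- NA_character_
  for (t in seq_len(n)) {
    prev_valid[t] <- last
    if (ph[t] != "invalid") last <- ph[t]
  }
  onsets <- which(ph == "stance" & !is.na(prev_valid) & prev_valid == "swing")
  rows <- list()
  if (length(onsets) >= 2L) {
    for (i in seq_len(length(onsets) - 1L)) {
      s0 <- onsets[i]; s1 <- onsets[i + 1L]
      seg <- ph[s0:(s1 - 1L)]
      vals <- seg[seg != "invalid"]
      r <- rle(vals)
      if (length(r$values) != 2L || r$values[1L] != "stance" ||
          r$values[2L] != "swing") next
      idx <- s0:(s1 - 1L)
      sw_start <- idx[seg != "invalid"][r$lengths[1L] + 1L]
      # stance run ends at the last stance-labelled frame before swing
      st_end <- idx[seg != "invalid"][r$lengths[1L]] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        paw = phases$paw, start_frame = s0, end_frame = s1,
        stance_start = s0, stance_end = st_end,
        swing_start = sw_start, swing_end = s1,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(paw = character(0), start_frame = integer(0),
               end_frame = integer(0), stance_start = integer(0),
               stance_end = integer(0), swing_start = integer(0),
               swing_end = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("step_cycles", "data.frame")
  if (!nrow(out)) attr(out, "flagged") <- "no complete step cycle"
  out
}

#' @export
print.step_cycles <- function(x, ...) {
  cat(sprintf("<step_cycles: %d cycles>\n", nrow(x)))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Average step-cycle, stance and swing durations
#'
#' Frame counts are converted to seconds with the calibration frame
#' rate; per cycle, stance and swing durations sum to the cycle
#' duration.
#'
#' @param cycles A `step_cycles` data frame from [segment_steps()].
#' @param calibration A [gait_calibration()].
#' @return List with `cycle`, `stance`, `swing` mean durations (s),
#'   `duty_cycle` (mean stance/cycle fraction) and `n_cycles`. All NA
#'   with attribute `"undefined"` when no cycle is present.
#' @export
cycle_durations <- function(cycles, calibration = gait_calibration()) {
  stopifnot(inherits(cycles, "step_cycles"))
  if (!nrow(cycles)) {
    out <- list(cycle = NA_real_, stance = NA_real_, swing = NA_real_,
                duty_cycle = NA_real_, n_cycles = 0L)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  cyc <- cycles$end_frame - cycles$start_frame
  st <- cycles$stance_end - cycles$stance_start
  sw <- cycles$swing_end - cycles$swing_start
  list(cycle = mean(frames_to_seconds(cyc, calibration)),
       stance = mean(frames_to_seconds(st, calibration)),
       swing = mean(frames_to_seconds(sw, calibration)),
       duty_cycle = mean(st / cyc),
       n_cycles = nrow(cycles))
}

#' Stride length
#'
#' Average horizontal distance covered by a paw between successive
#' stance onsets, in cm.
#'
#' @param series The paw's [keypoint_series()].
#' @param cycles Its `step_cycles`.
#' @param calibration A [gait_calibration()].
#' @return Mean stride in cm; NA with attribute `"undefined"` when
#'   fewer than one complete cycle (i.e. < 2 onsets) exists.
#' @export
stride_length <- function(series, cycles, calibration = gait_calibration()) {
  stopifnot(inherits(series, "keypoint_series"), inherits(cycles, "step_cycles"))
  if (nrow(cycles) < 1L) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  onsets <- c(cycles$start_frame, cycles$end_frame[nrow(cycles)])
  x <- series$x[onsets]
  mean(abs(diff(x))) / calibration$px_per_cm
}

#' Diagonal-limb synchronization tally
#'
#' During coordinated gait the diagonal paw pairs plant together. Per
#' pair, frames where both paws are in stance count as synchronized
#' (`total_sync`); frames where exactly one paw of the pair is in
#' stance count as unsynchronized (`total_not_sync`). The asynchrony
#' ratio is `1 - total_sync / (total_sync + total_not_sync)`: 0 for a
#' fully synchronized gait, towards 1 as the pair decouples.
#'
#' @param phases Named list of `phase_track`s for all four paws
#'   (`front_toe_l`, `front_toe_r`, `back_toe_l`, `back_toe_r`), equal
#'   length.
#' @return List with one `sync_tally` per diagonal pair (`lf_rb`,
#'   `rf_lb`) and a `pooled` tally summing both pairs. Each tally holds
#'   `total_sync`, `total_not_sync`, `asynchrony`. A pair with zero
#'   tallied frames yields NA asynchrony, flagged.
#' @export
asynchrony <- function(phases) {
  need <- paw_names()
  if (!all(need %in% names(phases)))
    stop("phase tracks for all four paws are required", call. = FALSE)
  lens <- vapply(phases[need], function(p) length(p$phase), integer(1))
  if (length(unique(lens)) != 1L)
    stop("phase tracks must have equal length", call. = FALSE)
  tally <- function(a, b) {
    pa <- phases[[a]]$phase; pb <- phases[[b]]$phase
    ok <- pa != "invalid" & pb != "invalid"
    both <- sum(ok & pa == "stance" & pb == "stance")
    one <- sum(ok & xor(pa == "stance", pb == "stance"))
    asyn <- if (both + one > 0) 1 - both / (both + one) else NA_real_
    out <- structure(list(total_sync = both, total_not_sync = one,
                          asynchrony = asyn), class = "sync_tally")
    if (is.na(asyn)) attr(out, "undefined") <- TRUE
    out
  }
  pairs <- diagonal_pairs()
  res <- lapply(pairs, function(p) tally(p[1L], p[2L]))
  ts <- sum(vapply(res, `[[`, numeric(1), "total_sync"))
  tn <- sum(vapply(res, `[[`, numeric(1), "total_not_sync"))
  res$pooled <- structure(
    list(total_sync = ts, total_not_sync = tn,
         asynchrony = if (ts + tn > 0) 1 - ts / (ts + tn) else NA_real_),
    class = "sync_tally")
  res
}

#' @export
print.sync_tally <- function(x, ...) {
  cat(sprintf("<sync_tally: sync %d, not sync %d, asynchrony %.3f>\n",
              x$total_sync, x$total_not_sync, x$asynchrony))
  invisible(x)
}

#' Signed angle between the body axis and a paw
#'
#' The body axis runs from the back centre to the front centre; the paw
#' vector runs from the body-axis midpoint to the paw. The returned
#' angle is signed, in (-180, 180], positive when the paw lies to the
#' left of the travel-normalized body axis (image y grows downward, so
#' the sign is flipped relative to the raw cross product).
#'
#' @param paw,center_front,center_back [keypoint_series()] objects of
#'   equal length.
#' @return Numeric vector of per-frame angles in degrees; NA on frames
#'   where any input is masked or the body axis is degenerate.
#' @export
paw_body_angle <- function(paw, center_front, center_back) {
  stopifnot(inherits(paw, "keypoint_series"),
            inherits(center_front, "keypoint_series"),
            inherits(center_back, "keypoint_series"))
  n <- length(paw$x)
  if (length(center_front$x) != n || length(center_back$x) != n)
    stop("series must have equal length", call. = FALSE)
  ok <- paw$mask & center_front$mask & center_back$mask &
    !is.na(paw$x) & !is.na(center_front$x) & !is.na(center_back$x)
  ax <- center_front$x - center_back$x
  ay <- center_front$y - center_back$y
  degen <- abs(ax) < .Machine$double.eps & abs(ay) < .Machine$double.eps
  mx <- (center_front$x + center_back$x) / 2
  my <- (center_front$y + center_back$y) / 2
  vx <- paw$x - mx
  vy <- paw$y - my
  dot <- ax * vx + ay * vy
  # image y points down: negate the planar cross product so that
  # positive = paw to the animal's left when travelling towards +x
  crs <- -(ax * vy - ay * vx)
  ang <- atan2(crs, dot) * 180 / pi
  ang[!ok | degen] <- NA_real_
  ang[!is.na(ang) & ang <= -180] <- 180
  ang
}

#' Per-cycle amplitude of the paw-to-body angle
#'
#' @param angles Per-frame angles from [paw_body_angle()].
#' @param cycles `step_cycles` of the same paw.
#' @return Mean over cycles of (max - min) angle within each cycle,
#'   degrees; NA when no cycle has valid angles.
#' @export
paw_angle_amplitude <- function(angles, cycles) {
  stopifnot(inherits(cycles, "step_cycles"))
  if (!nrow(cycles)) return(NA_real_)
  amp <- vapply(seq_len(nrow(cycles)), function(i) {
    a <- angles[cycles$start_frame[i]:(cycles$end_frame[i] - 1L)]
    a <- a[!is.na(a)]
    if (!length(a)) return(NA_real_)
    max(a) - min(a)
  }, numeric(1))
  if (all(is.na(amp))) NA_real_ else mean(amp, na.rm = TRUE)
}
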