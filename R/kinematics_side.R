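#' Ground (height-zero) reference of a side view
#'
#' Tracker image coordinates grow downward, so physical height is
#' measured as `(ground_y - y) / px_per_cm`. The floor reference is the
#' per-run maximum image y (lowest point) of a toe-tip track.
#'
#' @param run A side-view [pose_run()].
#' @param toe Bodypart used as the floor reference (default front toe,
#'   falling back to back toe).
#' @return Ground reference in image-y pixels.
#' @export
ground_reference <- function(run, toe = c("front_toe", "back_toe")) {
  stopifnot(inherits(run, "pose_run"))
  toe <- intersect(toe, names(run$series))
  if (!length(toe)) stop("no toe track available for the ground reference",
                         call. = FALSE)
  s <- run$series[[toe[1L]]]
  yv <- s$y[s$mask & !is.na(s$y)]
  if (!length(yv)) stop("toe track has no valid frame", call. = FALSE)
  max(yv)
}

# frames of cycle i as an index vector; the window runs from the
# stance onset to the NEXT stance onset inclusive, so a step's net
# displacement spans exactly one cycle of motion
.cycle_frames <- function(cycles, i) {
  cycles$start_frame[i]:cycles$end_frame[i]
}

# apply fn(values within cycle) over cycles and average, NA-safe
.per_cycle_mean <- function(series_vals, valid, cycles, fn) {
  res <- vapply(seq_len(nrow(cycles)), function(i) {
    idx <- .cycle_frames(cycles, i)
    v <- series_vals[idx][valid[idx]]
    if (!length(v)) return(NA_real_)
    fn(v)
  }, numeric(1))
  if (all(is.na(res))) NA_real_ else mean(res, na.rm = TRUE)
}

#' Average height and total vertical movement of a joint
#'
#' Per step cycle, the average relative height (mean of the height
#' above the run's floor reference) and the total vertical movement
#' (highest minus lowest height within the cycle), averaged over
#' cycles, in cm.
#'
#' @param series The joint's [keypoint_series()] (side view).
#' @param cycles `step_cycles` defining the step windows.
#' @param calibration A [gait_calibration()].
#' @param ground_y Floor reference in image-y pixels, from
#'   [ground_reference()].
#' @return List with `avg_height` and `total_vertical`, cm; NA (flagged
#'   by attribute `"undefined"`) when no cycle holds a valid frame.
#' @export
vertical_stats <- function(series, cycles, calibration = gait_calibration(),
                           ground_y) {
  stopifnot(inherits(series, "keypoint_series"), inherits(cycles, "step_cycles"))
  if (!nrow(cycles)) {
    out <- list(avg_height = NA_real_, total_vertical = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  h <- (ground_y - series$y) / calibration$px_per_cm
  ok <- series$mask & !is.na(series$y)
  out <- list(
    avg_height = .per_cycle_mean(h, ok, cycles, mean),
    total_vertical = .per_cycle_mean(h, ok, cycles, function(v) max(v) - min(v)))
  if (is.na(out$avg_height)) attr(out, "undefined") <- TRUE
  out
}

#' Average step length and total horizontal movement of a joint
#'
#' Per step cycle, the average step length is the net x distance
#' covered by the joint, and the total horizontal movement is the
#' highest minus lowest x within the cycle; both averaged over cycles,
#' in cm.
#'
#' @inheritParams vertical_stats
#' @return List with `avg_step_length` and `total_horizontal`, cm.
#' @export
horizontal_stats <- function(series, cycles, calibration = gait_calibration()) {
  stopifnot(inherits(series, "keypoint_series"), inherits(cycles, "step_cycles"))
  if (!nrow(cycles)) {
    out <- list(avg_step_length = NA_real_, total_horizontal = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  ok <- series$mask & !is.na(series$x)
  ppc <- calibration$px_per_cm
  out <- list(
    avg_step_length = .per_cycle_mean(series$x, ok, cycles,
                                      function(v) abs(v[length(v)] - v[1L])) / ppc,
    total_horizontal = .per_cycle_mean(series$x, ok, cycles,
                                       function(v) max(v) - min(v)) / ppc)
  if (is.na(out$avg_step_length)) attr(out, "undefined") <- TRUE
  out
}

#' Maximum protraction and retraction excursions
#'
#' Within each step cycle, contiguous frames with positive
#' frame-to-frame x displacement form protraction phases and contiguous
#' negative displacements form retraction phases (displacements inside
#' a small dead-band around zero belong to neither). Per cycle the
#' maximum x excursion of each phase type is taken; the result is the
#' mean over cycles, in cm. Cycles without a phase contribute 0.
#'
#' @inheritParams vertical_stats
#' @param deadband Dead-band half-width in px/frame below which a
#'   displacement counts as stationary (default 0.25).
#' @return List with `max_protraction` and `max_retraction`, cm (both
#'   >= 0).
#' @export
protraction_retraction <- function(series, cycles,
                                   calibration = gait_calibration(),
                                   deadband = 0.25) {
  stopifnot(inherits(series, "keypoint_series"), inherits(cycles, "step_cycles"))
  if (!nrow(cycles)) {
    out <- list(max_protraction = NA_real_, max_retraction = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  ok <- series$mask & !is.na(series$x)
  per_cycle <- function(i) {
    idx <- .cycle_frames(cycles, i)
    x <- series$x[idx]; v <- ok[idx]
    x[!v] <- NA
    dx <- diff(x)
    sgn <- ifelse(is.na(dx), 0L, ifelse(dx > deadband, 1L,
                                        ifelse(dx < -deadband, -1L, 0L)))
    best <- c(pro = 0, ret = 0)
    r <- rle(sgn)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (r$values[j] == 0L) next
      seg <- pos[j]:(pos[j] + r$lengths[j] - 1L)
      exc <- abs(sum(dx[seg]))
      key <- if (r$values[j] == 1L) "pro" else "ret"
      best[key] <- max(best[key], exc)
    }
    best
  }
  m <- vapply(seq_len(nrow(cycles)), per_cycle, numeric(2))
  list(max_protraction = mean(m["pro", ]) / calibration$px_per_cm,
       max_retraction = mean(m["ret", ]) / calibration$px_per_cm)
}

#' Three-point joint angle
#'
#' The angle at vertex P1 subtended by P2 and P3, computed as
#' `atan2(P3.y - P1.y, P3.x - P1.x) - atan2(P2.y - P1.y, P2.x - P1.x)`
#' in degrees, normalized to \[0, 360). Inputs may be single points
#' (length-2 numeric `c(x, y)`) or per-frame coordinate vectors.
#'
#' @param p1,p2,p3 Each either `c(x, y)` or a list/data frame with
#'   numeric `x` and `y` vectors. P1 is the vertex.
#' @return Angle(s) in degrees in \[0, 360); NA where a point
#'   coincides with the vertex.
#' @export
joint_angle <- function(p1, p2, p3) {
  pt <- function(p) {
    if (is.numeric(p) && length(p) == 2L) list(x = p[1L], y = p[2L])
    else list(x = p$x, y = p$y)
  }
  a <- pt(p1); b <- pt(p2); d <- pt(p3)
  ang <- atan2(d$y - a$y, d$x - a$x) - atan2(b$y - a$y, b$x - a$x)
  deg <- (ang * 180 / pi) %% 360
  degen <- (b$x == a$x & b$y == a$y) | (d$x == a$x & d$y == a$y)
  deg[degen] <- NA_real_
  deg
}

#' Per-frame joint angles for a bodypart triple
#'
#' @param run A side-view [pose_run()].
#' @param vertex,from,to Bodypart names: the angle at `vertex` between
#'   the rays towards `from` and `to`.
#' @return Object of class `angle_triple`: list with the bodypart names
#'   and the per-frame `angles` (degrees, \[0, 360), NA on masked or
#'   degenerate frames).
#' @export
angle_triple <- function(run, vertex, from, to) {
  stopifnot(inherits(run, "pose_run"))
  need <- c(vertex, from, to)
  miss <- setdiff(need, names(run$series))
  if (length(miss)) stop("missing bodyparts: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  s1 <- run$series[[vertex]]; s2 <- run$series[[from]]; s3 <- run$series[[to]]
  ok <- s1$mask & s2$mask & s3$mask &
    !is.na(s1$x) & !is.na(s2$x) & !is.na(s3$x)
  ang <- joint_angle(list(x = s1$x, y = s1$y),
                     list(x = s2$x, y = s2$y),
                     list(x = s3$x, y = s3$y))
  ang[!ok] <- NA_real_
  structure(list(vertex = vertex, from = from, to = to, angles = ang),
            class = "angle_triple")
}

#' Angular variability of a joint triple over steps
#'
#' Per step cycle, the maximum, mean and minimum of the normalized
#' angle series; averaged across cycles.
#'
#' @param triple An [angle_triple()].
#' @param cycles `step_cycles` defining the step windows.
#' @return List with `max`, `mean`, `min` in degrees; all NA (flagged)
#'   when no cycle overlaps valid angles.
#' @export
angular_variability <- function(triple, cycles) {
  stopifnot(inherits(triple, "angle_triple"), inherits(cycles, "step_cycles"))
  empty <- list(max = NA_real_, mean = NA_real_, min = NA_real_)
  if (!nrow(cycles)) {
    attr(empty, "undefined") <- TRUE
    return(empty)
  }
  ok <- !is.na(triple$angles)
  out <- list(
    max = .per_cycle_mean(triple$angles, ok, cycles, max),
    mean = .per_cycle_mean(triple$angles, ok, cycles, mean),
    min = .per_cycle_mean(triple$angles, ok, cycles, min))
  if (is.na(out$mean)) attr(out, "undefined") <- TRUE
  out
}

#' The four canonical side-view angle triples
#'
#' Neighbouring-joint triples summarized per step: hip-ankle-toe,
#' iliac crest-hip-back ankle, elbow-wrist-front toe and
#' shoulder-elbow-wrist; the middle joint is the vertex.
#'
#' @return Data frame with columns `name`, `vertex`, `from`, `to`.
#' @export
canonical_angle_triples <- function() {
  data.frame(
    name = c("hip_ankle_toe", "iliac_hip_ankle",
             "elbow_wrist_fronttoe", "shoulder_elbow_wrist"),
    vertex = c("back_ankle", "hip", "wrist", "elbow"),
    from = c("hip", "iliac_crest", "elbow", "shoulder"),
    to = c("back_toe", "back_ankle", "front_toe", "wrist"),
    stringsAsFactors = FALSE)
}
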