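#' Compute every gait parameter for one run
#'
#' Drives the full per-run measurement chain: likelihood filtering and
#' travel-direction normalization, bottom-view step segmentation, step
#' timing / stride / synchronization / paw-angle parameters, and the
#' side-view height, excursion, protraction/retraction and joint-angle
#' parameters for whichever side views are present. Step windows for
#' the side views come from the bottom-view segmentation of the same
#' video (all three views share the frame clock); when the bottom view
#' is absent, the side-view toe is segmented with the same speed rule.
#'
#' @param bottom Bottom-view [pose_run()], or NULL.
#' @param left,right Side-view [pose_run()]s, or NULL.
#' @param calibration A [gait_calibration()].
#' @param speed_threshold Swing speed threshold in cm/s (default 10).
#' @param likelihood_threshold Keypoint likelihood cutoff (default from
#'   the calibration).
#' @return Named list of parameters (one scalar per parameter; NA where
#'   a view or enough steps are missing), with attribute `"qc"` (list
#'   of per-view retained fractions and per-paw cycle counts).
#' @export
run_parameters <- function(bottom = NULL, left = NULL, right = NULL,
                           calibration = gait_calibration(),
                           speed_threshold = 10,
                           likelihood_threshold = calibration$likelihood_threshold) {
  if (is.null(bottom) && is.null(left) && is.null(right))
    stop("at least one view is required", call. = FALSE)
  out <- list()
  qc <- list()
  prep <- function(run) {
    run <- filter_likelihood(run, likelihood_threshold)
    normalize_direction(run)
  }

  paw_cycles <- list()
  if (!is.null(bottom)) {
    bottom <- prep(bottom)
    qc$bottom_retained <- stats::setNames(bottom$qc$retained, bottom$qc$bodypart)
    phases <- list()
    for (p in paw_names()) {
      sp <- paw_speed(bottom$series[[p]], calibration)
      phases[[p]] <- classify_phases(sp, threshold = speed_threshold, paw = p)
      cyc <- segment_steps(phases[[p]])
      paw_cycles[[p]] <- cyc
      dur <- cycle_durations(cyc, calibration)
      out[[paste0(p, "_cycle_s")]] <- dur$cycle
      out[[paste0(p, "_stance_s")]] <- dur$stance
      out[[paste0(p, "_swing_s")]] <- dur$swing
      out[[paste0(p, "_duty_cycle")]] <- dur$duty_cycle
      out[[paste0(p, "_n_steps")]] <- dur$n_cycles
      out[[paste0(p, "_stride_cm")]] <- as.numeric(
        stride_length(bottom$series[[p]], cyc, calibration))
      out[[paste0(p, "_mean_swing_speed")]] <- {
        sw <- sp[phases[[p]]$phase == "swing"]
        if (any(!is.na(sw))) mean(sw, na.rm = TRUE) else NA_real_
      }
    }
    qc$cycle_counts <- vapply(paw_cycles, nrow, integer(1))
    sync <- asynchrony(phases)
    out$asynchrony_lf_rb <- sync$lf_rb$asynchrony
    out$asynchrony_rf_lb <- sync$rf_lb$asynchrony
    out$asynchrony_pooled <- sync$pooled$asynchrony
    cf <- bottom$series$center_front
    cb <- bottom$series$center_back
    if (!is.null(cf) && !is.null(cb)) {
      for (p in paw_names()) {
        ang <- paw_body_angle(bottom$series[[p]], cf, cb)
        out[[paste0(p, "_body_angle_amp")]] <-
          paw_angle_amplitude(ang, paw_cycles[[p]])
      }
    }
  }

  side_cols <- function(run, side) {
    run <- prep(run)
    qc[[paste0(side, "_retained")]] <<-
      stats::setNames(run$qc$retained, run$qc$bodypart)
    sfx <- if (side == "left") "_l" else "_r"
    # step windows: bottom-view segmentation of the same side's paws;
    # fall back to segmenting the side-view toe itself
    get_cycles <- function(limb) {
      paw <- paste0(limb, sfx)
      if (!is.null(paw_cycles[[paw]]) && nrow(paw_cycles[[paw]]))
        return(paw_cycles[[paw]])
      sp <- paw_speed(run$series[[limb]], calibration)
      segment_steps(classify_phases(sp, threshold = speed_threshold,
                                    paw = limb))
    }
    cyc_front <- get_cycles("front_toe")
    cyc_back <- get_cycles("back_toe")
    gy <- ground_reference(run)
    front_joints <- c("head", "front_toe", "wrist", "shoulder", "elbow")
    res <- list()
    for (bp in view_bodyparts(side)) {
      cyc <- if (bp %in% front_joints) cyc_front else cyc_back
      vs <- vertical_stats(run$series[[bp]], cyc, calibration, gy)
      hs <- horizontal_stats(run$series[[bp]], cyc, calibration)
      key <- paste0(side, "_", bp)
      res[[paste0(key, "_avg_height")]] <- vs$avg_height
      res[[paste0(key, "_total_vertical")]] <- vs$total_vertical
      res[[paste0(key, "_avg_step_length")]] <- hs$avg_step_length
      res[[paste0(key, "_total_horizontal")]] <- hs$total_horizontal
    }
    for (bp in c("front_toe", "back_toe")) {
      cyc <- if (bp == "front_toe") cyc_front else cyc_back
      pr <- protraction_retraction(run$series[[bp]], cyc, calibration)
      key <- paste0(side, "_", bp)
      res[[paste0(key, "_max_protraction")]] <- pr$max_protraction
      res[[paste0(key, "_max_retraction")]] <- pr$max_retraction
    }
    tri <- canonical_angle_triples()
    for (i in seq_len(nrow(tri))) {
      at <- angle_triple(run, tri$vertex[i], tri$from[i], tri$to[i])
      cyc <- if (tri$name[i] %in% c("elbow_wrist_fronttoe",
                                    "shoulder_elbow_wrist")) cyc_front
        else cyc_back
      av <- angular_variability(at, cyc)
      key <- paste0(side, "_angle_", tri$name[i])
      res[[paste0(key, "_max")]] <- av$max
      res[[paste0(key, "_mean")]] <- av$mean
      res[[paste0(key, "_min")]] <- av$min
    }
    res
  }

  # emit side columns (NA-filled when the view is missing) so every
  # run shares one column registry
  na_side <- function(side) {
    keys <- c()
    for (bp in view_bodyparts(side))
      keys <- c(keys, paste0(side, "_", bp, "_",
                             c("avg_height", "total_vertical",
                               "avg_step_length", "total_horizontal")))
    for (bp in c("front_toe", "back_toe"))
      keys <- c(keys, paste0(side, "_", bp, "_",
                             c("max_protraction", "max_retraction")))
    for (nm in canonical_angle_triples()$name)
      keys <- c(keys, paste0(side, "_angle_", nm, "_", c("max", "mean", "min")))
    stats::setNames(rep(list(NA_real_), length(keys)), keys)
  }
  out <- c(out,
           if (!is.null(left)) side_cols(left, "left") else na_side("left"),
           if (!is.null(right)) side_cols(right, "right") else na_side("right"))
  attr(out, "qc") <- qc
  out
}

#' Extract the parameter row of a simulated run
#'
#' Convenience wrapper of [run_parameters()] over a
#' [simulate_run()] result.
#'
#' @param sim A `simulated_run`.
#' @param ... Passed on to [run_parameters()].
#' @return Named parameter list (see [run_parameters()]).
#' @export
simulated_run_parameters <- function(sim, ...) {
  stopifnot(inherits(sim, "simulated_run"))
  run_parameters(bottom = sim$views$bottom, left = sim$views$left,
                 right = sim$views$right,
                 calibration = sim$views$bottom$calibration, ...)
}

#' Feature table of a simulated cohort
#'
#' Runs [run_parameters()] on every run of a [simulate_cohort()] result
#' and assembles the labelled feature table.
#'
#' @param cohort A `simulated_cohort`.
#' @param ... Passed on to [run_parameters()].
#' @return A `gait_feature_table` (see [build_feature_table()]).
#' @export
cohort_feature_table <- function(cohort, ...) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  rows <- lapply(seq_along(cohort$runs), function(i) {
    p <- simulated_run_parameters(cohort$runs[[i]], ...)
    m <- cohort$manifest[i, ]
    c(list(animal = m$animal, label = m$group, run = m$run), p)
  })
  build_feature_table(rows)
}
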