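# small constructors used across the suite; every fixture is built in
# code at test time

mk_series <- function(bp, x, y = rep(0, length(x)),
                      likelihood = rep(1, length(x)), mask = NULL) {
  keypoint_series(bp, x, y, likelihood, mask)
}

mk_run <- function(series, view = "bottom", cal = gait_calibration(),
                   metadata = list()) {
  pose_run(series, view = view, calibration = cal, metadata = metadata)
}

# step_cycles covering full periods of length `period` starting at
# `onsets[1]`; stance takes `stance_len` frames of each period
mk_cycles <- function(onsets, stance_len, paw = "front_toe_l") {
  k <- length(onsets) - 1L
  out <- data.frame(
    paw = rep(paw, k),
    start_frame = onsets[-length(onsets)],
    end_frame = onsets[-1L],
    stance_start = onsets[-length(onsets)],
    stance_end = onsets[-length(onsets)] + stance_len,
    swing_start = onsets[-length(onsets)] + stance_len,
    swing_end = onsets[-1L],
    stringsAsFactors = FALSE)
  class(out) <- c("step_cycles", "data.frame")
  out
}

mk_phase_track <- function(phase, paw = "front_toe_l") {
  structure(list(paw = paw, phase = phase), class = "phase_track")
}

# a textual DLC-dialect table written to a temp file
write_dlc_text <- function(bodyparts, frames, path = tempfile(fileext = ".csv"),
                           drop_header_row = NULL, seed = 42) {
  set.seed(seed)
  h1 <- paste(c("scorer", rep("net", 3 * length(bodyparts))), collapse = ",")
  h2 <- paste(c("bodyparts", rep(bodyparts, each = 3)), collapse = ",")
  h3 <- paste(c("coords", rep(c("x", "y", "likelihood"), length(bodyparts))),
              collapse = ",")
  rows <- vapply(seq_len(frames), function(i) {
    vals <- unlist(lapply(bodyparts, function(b)
      c(round(runif(1, 0, 500), 3), round(runif(1, 0, 500), 3),
        round(runif(1, 0.9, 1), 4))))
    paste(c(i - 1, vals), collapse = ",")
  }, character(1))
  lines <- c(h1, h2, h3, rows)
  if (!is.null(drop_header_row)) lines <- lines[-drop_header_row]
  writeLines(lines, path)
  path
}

# paws of a simulated bottom run -> phase tracks
sim_phase_tracks <- function(sim, cal = gait_calibration()) {
  b <- normalize_direction(filter_likelihood(sim$views$bottom))
  phases <- lapply(paw_names(), function(p)
    classify_phases(paw_speed(b$series[[p]], cal), paw = p))
  names(phases) <- paw_names()
  phases
}
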