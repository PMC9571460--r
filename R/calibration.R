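#' Camera and threshold calibration
#'
#' Bundles the constants that convert tracker pixels and frames into
#' physical units, together with the quality thresholds applied to
#' keypoint tables.
#'
#' @param px_per_cm Pixels per centimetre of the recording (default
#'   37.79528, i.e. 1 cm = 37.79528 px).
#' @param fps Frames per second of the video (default 60, i.e. 60 frames
#'   = 1 s).
#' @param likelihood_threshold Detection-likelihood cutoff in \[0, 1\];
#'   keypoints below it are excluded from analysis (default 0.95).
#' @param confidence_dist_px Distance threshold in pixels used when
#'   scoring predicted labels against human ground truth (default 17 px,
#'   about 0.45 cm).
#'
#' @return An object of class `gait_calibration`.
#' @examples
#' cal <- gait_calibration()
#' px_to_cm(17, cal)       # ~0.45 cm
#' frames_to_seconds(60, cal)  # 1 s
#' @export
gait_calibration <- function(px_per_cm = 37.79528, fps = 60,
                             likelihood_threshold = 0.95,
                             confidence_dist_px = 17) {
  stopifnot(
    is.numeric(px_per_cm), length(px_per_cm) == 1L, px_per_cm > 0,
    is.numeric(fps), length(fps) == 1L, fps > 0,
    is.numeric(likelihood_threshold), length(likelihood_threshold) == 1L,
    likelihood_threshold >= 0, likelihood_threshold <= 1,
    is.numeric(confidence_dist_px), length(confidence_dist_px) == 1L,
    confidence_dist_px > 0
  )
  structure(
    list(px_per_cm = px_per_cm, fps = fps,
         likelihood_threshold = likelihood_threshold,
         confidence_dist_px = confidence_dist_px),
    class = "gait_calibration"
  )
}

#' @export
print.gait_calibration <- function(x, ...) {
  cat("Gait calibration:\n")
  cat(sprintf("  %g px / cm, %g frames / s\n", x$px_per_cm, x$fps))
  cat(sprintf("  likelihood threshold %g, confidence distance %g px\n",
              x$likelihood_threshold, x$confidence_dist_px))
  invisible(x)
}

#' Convert pixels to centimetres
#'
#' @param px Numeric vector of pixel distances.
#' @param calibration A [gait_calibration()] object.
#' @return `px / px_per_cm`, in cm.
#' @export
px_to_cm <- function(px, calibration = gait_calibration()) {
  stopifnot(inherits(calibration, "gait_calibration"))
  px / calibration$px_per_cm
}

#' Convert centimetres to pixels
#'
#' @inheritParams px_to_cm
#' @param cm Numeric vector of distances in cm.
#' @return `cm * px_per_cm`, in pixels.
#' @export
cm_to_px <- function(cm, calibration = gait_calibration()) {
  stopifnot(inherits(calibration, "gait_calibration"))
  cm * calibration$px_per_cm
}

#' Convert a frame count to seconds
#'
#' @param n Numeric vector of frame counts (>= 0).
#' @inheritParams px_to_cm
#' @return `n / fps`, in seconds.
#' @export
frames_to_seconds <- function(n, calibration = gait_calibration()) {
  stopifnot(inherits(calibration, "gait_calibration"), all(n >= 0, na.rm = TRUE))
  n / calibration$fps
}

# canonical bodypart sets per camera view
#' Canonical bodypart names for a camera view
#'
#' Side views track 10 landmarks (head, front toe tip, wrist, shoulder,
#' elbow, back toe, back ankle, iliac crest, hip, tail); the bottom view
#' tracks 8 (head, right/left front toe, centre front, right/left back
#' toe, centre back, tail base).
#'
#' @param view One of `"left"`, `"right"`, `"bottom"`.
#' @return Character vector of bodypart names.
#' @export
view_bodyparts <- function(view = c("left", "right", "bottom")) {
  view <- match.arg(view)
  if (view == "bottom") {
    c("head", "front_toe_r", "front_toe_l", "center_front",
      "back_toe_r", "back_toe_l", "center_back", "tail_base")
  } else {
    c("head", "front_toe", "wrist", "shoulder", "elbow",
      "back_toe", "back_ankle", "iliac_crest", "hip", "tail")
  }
}

#' The four paw labels of the bottom view
#' @return Character vector of the four paw bodypart names.
#' @export
paw_names <- function() {
  c("front_toe_l", "front_toe_r", "back_toe_l", "back_toe_r")
}

#' Diagonal limb pairs
#'
#' During coordinated gait the diagonal paw pairs (front-left with
#' back-right; front-right with back-left) plant together.
#'
#' @return Named list of two character vectors of length 2.
#' @export
diagonal_pairs <- function() {
  list(
    lf_rb = c("front_toe_l", "back_toe_r"),
    rf_lb = c("front_toe_r", "back_toe_l")
  )
}
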