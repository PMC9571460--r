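#' Volume of a frustum between two parallel lesion sections
#'
#' Uses the conical-frustum form with the two section areas as bases:
#' `V = h/3 * (A1 + A2 + sqrt(A1 * A2))`. Symmetric in the two areas,
#' linear in the height; reduces to a cylinder (`A h`) for equal areas
#' and to a cone (`A h / 3`) when one area vanishes.
#'
#' @param a1,a2 Base areas in mm^2 (>= 0).
#' @param h Height (section spacing) in mm (> 0).
#' @return Volume in mm^3. Vectorized.
#' @export
frustum_volume <- function(a1, a2, h) {
  if (any(a1 < 0) || any(a2 < 0)) stop("areas must be non-negative",
                                       call. = FALSE)
  if (any(h <= 0)) stop("height must be positive", call. = FALSE)
  h / 3 * (a1 + a2 + sqrt(a1 * a2))
}

#' Total lesion volume from serial sections
#'
#' Adjacent cross-section pairs form frustums whose volumes are summed
#' to the total ischemic volume.
#'
#' @param area Lesion areas in mm^2, one per section.
#' @param position Anterior-posterior section positions in mm, strictly
#'   increasing.
#' @return Total volume in mm^3.
#' @export
lesion_volume <- function(area, position) {
  if (length(area) != length(position))
    stop("area and position must have equal length", call. = FALSE)
  if (length(area) < 2L)
    stop("at least two sections are required", call. = FALSE)
  if (any(diff(position) <= 0))
    stop("section positions must be strictly ordered", call. = FALSE)
  k <- length(area)
  sum(frustum_volume(area[-k], area[-1L], diff(position)))
}

#' Single-pellet grasping end score
#'
#' `end score = total score / number of attempts x 100`, with
#' per-attempt scores restricted to 0 (miss), 0.5 (drop) or 1
#' (successful grasp and retrieval).
#'
#' @param scores Optional vector of per-attempt scores in
#'   \{0, 0.5, 1\}; when given, `total_score` and `attempts` are taken
#'   from it.
#' @param total_score Sum of per-attempt scores.
#' @param attempts Number of attempts (> 0).
#' @return End score in percent; NA with attribute `"undefined"` when
#'   `attempts` is 0.
#' @export
grasp_end_score <- function(scores = NULL, total_score = NULL, attempts = NULL) {
  if (!is.null(scores)) {
    if (!all(scores %in% c(0, 0.5, 1)))
      stop("per-attempt scores must be 0, 0.5 or 1", call. = FALSE)
    total_score <- sum(scores)
    attempts <- length(scores)
  }
  stopifnot(!is.null(total_score), !is.null(attempts), attempts >= 0)
  if (attempts == 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  total_score / attempts * 100
}

#' Cylinder-test asymmetry ratios
#'
#' Paw preference = impaired forelimb contacts / total forelimb
#' contacts; symmetry = asymmetrical contacts / total contacts; paw
#' dragging = dragged impaired contacts / total impaired contacts.
#'
#' @param impaired_contacts,total_contacts,asym_contacts,dragged_impaired
#'   Non-negative counts; numerators must not exceed their denominators.
#' @return Named list of the three ratios in \[0, 1\]; a ratio with a
#'   zero denominator is NA, flagged via the `"undefined"` attribute.
#' @export
cylinder_ratios <- function(impaired_contacts, total_contacts,
                            asym_contacts, dragged_impaired) {
  stopifnot(impaired_contacts >= 0, total_contacts >= 0,
            asym_contacts >= 0, dragged_impaired >= 0,
            impaired_contacts <= total_contacts || total_contacts == 0,
            asym_contacts <= total_contacts || total_contacts == 0,
            dragged_impaired <= impaired_contacts || impaired_contacts == 0)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(paw_preference = ratio(impaired_contacts, total_contacts),
              symmetry = ratio(asym_contacts, total_contacts),
              dragging = ratio(dragged_impaired, impaired_contacts))
  und <- names(out)[vapply(out, is.na, logical(1))]
  if (length(und)) attr(out, "undefined") <- und
  out
}

#' Validated Bederson neurological score
#'
#' The modified Bederson scale grades global neurological deficit from
#' 0 (no observable deficit) to 5 (no spontaneous movement / death).
#' This is a data validator only; no computation is defined on it.
#'
#' @param x Integer score(s) in 0..5.
#' @return Ordered factor with the scale's descriptive labels.
#' @export
bederson_score <- function(x) {
  if (any(is.na(x)) || any(x != as.integer(x)) || any(x < 0) || any(x > 5))
    stop("Bederson scores must be integers in 0..5", call. = FALSE)
  labels <- c("no deficit", "forelimb flexion",
              "flexion + reduced lateral resistance", "circling",
              "circling + spinning", "no spontaneous movement")
  factor(labels[as.integer(x) + 1L], levels = labels, ordered = TRUE)
}
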