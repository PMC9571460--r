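#' Ground-truth gait parameters for the simulator
#'
#' Defines one animal's gait: step timing, stride, diagonal-limb
#' coupling, side-view joint lift amplitudes, injury-like amplitude
#' deficits, scheduled ladder missteps, and the tracker noise model.
#' Defaults describe a healthy adult mouse crossing a runway at a
#' steady ~12 cm/s: 2 step cycles per second, stance for 65% of the
#' cycle, 6 cm strides, diagonal pairs phase-locked half a cycle apart.
#'
#' @param cycle_duration Step-cycle duration in s (default 0.5).
#' @param duty_cycle Stance fraction of the cycle in (0, 1)
#'   (default 0.65).
#' @param stride Stride length in cm (default 6).
#' @param diagonal_phase Cycle-fraction offset between the two diagonal
#'   pairs (default 0.5: pairs alternate).
#' @param asynchrony_offset Cycle-fraction perturbation applied to the
#'   hind paw of each diagonal pair; 0 = perfect diagonal locking.
#' @param joint_amplitudes Named vector of vertical lift amplitudes in
#'   cm for side-view bodyparts (peak-to-trough per cycle).
#' @param deficit Named list with `left` and `right` multiplicative
#'   amplitude factors (1 = intact; e.g. 0.7 = 30% lift deficit).
#' @param toe_overshoot Fraction of the stride by which the toe
#'   overshoots at the end of swing and retracts (default 0.05).
#' @param missteps Data frame with columns `paw`, `time` (s), `depth`
#'   (cm below the rung line) scheduling ladder missteps.
#' @param noise_sd Gaussian pixel noise SD added to every coordinate
#'   (default 0).
#' @param dropout_rate Fraction of frames whose detection likelihood is
#'   drawn below 0.5 (tracking dropouts; default 0).
#' @param seed Master seed; every random stream is derived from it.
#' @return Object of class `gait_params`.
#' @export
gait_params <- function(cycle_duration = 0.5, duty_cycle = 0.65, stride = 6,
                        diagonal_phase = 0.5, asynchrony_offset = 0,
                        joint_amplitudes = NULL,
                        deficit = list(left = 1, right = 1),
                        toe_overshoot = 0.05,
                        missteps = NULL,
                        noise_sd = 0, dropout_rate = 0, seed = 1L) {
  if (is.null(joint_amplitudes))
    joint_amplitudes <- c(head = 0.2, front_toe = 0.8, wrist = 0.5,
                          shoulder = 0.25, elbow = 0.35, back_toe = 0.9,
                          back_ankle = 0.6, iliac_crest = 0.25, hip = 0.3,
                          tail = 0.3)
  if (is.null(missteps))
    missteps <- data.frame(paw = character(0), time = numeric(0),
                           depth = numeric(0), stringsAsFactors = FALSE)
  stopifnot(cycle_duration > 0, duty_cycle > 0, duty_cycle < 1, stride > 0,
            asynchrony_offset >= 0, asynchrony_offset < 1,
            all(joint_amplitudes >= 0), dropout_rate >= 0, dropout_rate < 1,
            noise_sd >= 0, toe_overshoot >= 0,
            all(c("left", "right") %in% names(deficit)))
  structure(
    list(cycle_duration = cycle_duration, duty_cycle = duty_cycle,
         stride = stride, diagonal_phase = diagonal_phase,
         asynchrony_offset = asynchrony_offset,
         joint_amplitudes = joint_amplitudes, deficit = deficit,
         toe_overshoot = toe_overshoot, missteps = missteps,
         noise_sd = noise_sd, dropout_rate = dropout_rate,
         seed = as.integer(seed)),
    class = "gait_params")
}

#' Analytic asynchrony of a diagonal pair
#'
#' For two paws with stance fraction `duty` whose cycles are offset by
#' `offset` (cycle fraction), the expected asynchrony ratio —
#' unsynchronized frames over (synchronized + unsynchronized) frames —
#' is `(2d - 2v) / (2d - v)` where `v` is the circular overlap of the
#' two stance arcs.
#'
#' @param duty Stance fraction in (0, 1).
#' @param offset Cycle-fraction offset in \[0, 1).
#' @return Asynchrony in \[0, 1\].
#' @export
analytic_asynchrony <- function(duty, offset) {
  stopifnot(duty > 0, duty < 1)
  de <- pmin(offset %% 1, 1 - offset %% 1)
  ov <- pmax(0, duty - de) + pmax(0, duty - (1 - de))
  ov <- pmin(ov, duty)
  (2 * duty - 2 * ov) / (2 * duty - ov)
}

# displacement profile of one swing: speed trapezoid with raised-cosine
# ramps (ramp = `f` of the swing each side) so the 10 cm/s threshold is
# crossed steeply and the recovered duty cycle stays close to nominal.
# maps w in [0,1] -> monotone displacement in [0,1]
.swing_disp <- function(w, f = 0.15) {
  v <- 1 / (1 - f)  # plateau speed (per unit swing)
  d <- numeric(length(w))
  w <- pmin(pmax(w, 0), 1)
  lo <- w < f
  hi <- w > 1 - f
  mid <- !lo & !hi
  d[lo] <- v / 2 * (w[lo] - (f / pi) * sin(pi * w[lo] / f))
  d[mid] <- v / 2 * f + v * (w[mid] - f)
  d[hi] <- 1 - (v / 2 * ((1 - w[hi]) - (f / pi) * sin(pi * (1 - w[hi]) / f)))
  d
}

# swing displacement with end-of-swing overshoot + retraction
.swing_disp_overshoot <- function(w, ov) {
  if (ov <= 0) return(.swing_disp(w))
  out <- numeric(length(w))
  fwd <- w <= 0.8
  out[fwd] <- (1 + ov) * .swing_disp(w[fwd] / 0.8)
  out[!fwd] <- (1 + ov) - ov * .swing_disp((w[!fwd] - 0.8) / 0.2)
  out
}

# cumulative progression in strides at cycle phase ph (can exceed 1)
.progression <- function(ph, duty, disp_fun) {
  k <- floor(ph)
  u <- ph - k
  adv <- ifelse(u < duty, 0, disp_fun((u - duty) / (1 - duty)))
  k + adv
}

# vertical lift bump over the swing: 0 at both ends, 1 mid-swing
.swing_lift <- function(u, duty) {
  w <- (u - duty) / (1 - duty)
  ifelse(u < duty, 0, sin(pi * pmin(pmax(w, 0), 1))^2)
}

# derived per-stream seed kept below 2^31
.stream_seed <- function(master, k) {
  as.integer((as.numeric(master) * 7919 + k * 104729) %% 2147483647)
}

.paw_phase_offsets <- function(params) {
  c(front_toe_l = 0,
    back_toe_r = params$asynchrony_offset,
    front_toe_r = params$diagonal_phase,
    back_toe_l = params$diagonal_phase + params$asynchrony_offset)
}

# first sampled frame (1-based) of each stance period of a paw
.stance_onset_frames <- function(offset, params, n, fps) {
  t_on <- (seq(-2, ceiling(n / fps / params$cycle_duration) + 2) - offset) *
    params$cycle_duration
  fr <- ceiling(t_on * fps - 1e-9) + 1L
  sort(unique(fr[fr >= 1L & fr <= n]))
}

#' Simulate one run as keypoint tables for all three views
#'
#' Builds bottom, left and right view keypoint tables with fully known
#' ground truth. Bottom-view paws advance one stride per cycle with
#' motion confined to the swing phase; diagonal pairs are phase-locked
#' by `diagonal_phase` and perturbed by `asynchrony_offset`. Side-view
#' joints lift with the configured amplitudes scaled by the per-side
#' deficit factors; toes follow a protraction/retraction excursion with
#' a small end-of-swing overshoot. Scheduled missteps appear as
#' transient toe dips below the rung line. Gaussian pixel noise and
#' likelihood dropouts are applied last. Deterministic given the seed.
#'
#' @param params A [gait_params()].
#' @param duration Run duration in s (>= 2 cycles; default 4).
#' @param calibration A [gait_calibration()].
#' @param metadata Metadata list propagated into each view's
#'   [pose_run()].
#' @return Object of class `simulated_run`: list with `views` (named
#'   list of `pose_run`s: `bottom`, `left`, `right`) and `truth`
#'   (parameters plus derived per-paw stance-onset frames, analytic
#'   asynchrony, per-joint height/excursion truth, misstep event
#'   windows and the rung line).
#' @export
simulate_run <- function(params, duration = 4,
                         calibration = gait_calibration(),
                         metadata = list()) {
  stopifnot(inherits(params, "gait_params"),
            duration >= 2 * params$cycle_duration)
  if (nrow(params$missteps) &&
      any(params$missteps$time + 0.075 > duration |
            params$missteps$time - 0.075 < 0))
    stop("infeasible misstep schedule: event outside the run duration",
         call. = FALSE)
  fps <- calibration$fps
  ppc <- calibration$px_per_cm
  n <- round(duration * fps)
  tt <- (seq_len(n) - 1L) / fps
  T <- params$cycle_duration
  duty <- params$duty_cycle
  offs <- .paw_phase_offsets(params)

  body_x0 <- 10                     # cm at frame 0
  body_speed <- params$stride / T   # cm/s
  body_x <- body_x0 + body_speed * tt

  paw_x_cm <- function(paw) {
    ph <- tt / T + offs[[paw]]
    base <- if (grepl("front", paw)) 2 else -2
    x0 <- body_x0 + base - params$stride * offs[[paw]]
    x0 + params$stride * .progression(ph, duty, .swing_disp)
  }
  paw_frac <- function(paw) (tt / T + offs[[paw]]) %% 1

  rng_k <- 0L
  noisy <- function(bp, x, y) {
    x <- rep_len(x, n)
    y <- rep_len(y, n)
    rng_k <<- rng_k + 1L
    set.seed(.stream_seed(params$seed, rng_k))
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(n, 0, params$noise_sd)
      y <- y + stats::rnorm(n, 0, params$noise_sd)
    }
    drop <- stats::runif(n) < params$dropout_rate
    lik <- 0.95 + 0.05 * stats::rbeta(n, 5, 1)
    lik[drop] <- stats::runif(sum(drop), 0, 0.5)
    keypoint_series(bp, x, y, lik)
  }

  # ---- bottom view (x = travel, y = lateral; image coords) ----
  y_mid <- 250
  lat <- c(front_toe_l = -1.2, front_toe_r = 1.2,
           back_toe_l = -1.5, back_toe_r = 1.5)
  bottom <- list()
  for (p in paw_names())
    bottom[[p]] <- noisy(p, paw_x_cm(p) * ppc, (y_mid / ppc + lat[[p]]) * ppc)
  bottom$center_front <- noisy("center_front", (body_x + 2) * ppc, y_mid)
  bottom$center_back <- noisy("center_back", (body_x - 2) * ppc, y_mid)
  bottom$head <- noisy("head", (body_x + 3.5) * ppc, y_mid)
  bottom$tail_base <- noisy("tail_base", (body_x - 3) * ppc, y_mid)
  bottom_run <- pose_run(bottom[view_bodyparts("bottom")], "bottom",
                         calibration, metadata)

  # ---- side views ----
  ground_y <- 420                   # rung/floor line, image-y px
  base_h <- c(head = 3.2, shoulder = 2.6, elbow = 1.8, wrist = 1.0,
              back_ankle = 1.2, hip = 2.4, iliac_crest = 2.8, tail = 2.2,
              front_toe = 0, back_toe = 0)
  x_off <- c(head = 4, shoulder = 2.5, elbow = 2.2, wrist = 2.1,
             back_ankle = -1.8, hip = -2.5, iliac_crest = -2.8, tail = -4.5)
  misstep_truth <- list()
  hw <- 0.075                       # misstep half-width, s

  side_view <- function(side) {
    sfx <- if (side == "left") "_l" else "_r"
    dfc <- params$deficit[[side]]
    amp <- params$joint_amplitudes * dfc
    fr_front <- paw_frac(paste0("front_toe", sfx))
    fr_back <- paw_frac(paste0("back_toe", sfx))
    series <- list()
    for (bp in view_bodyparts(side)) {
      if (bp %in% c("front_toe", "back_toe")) {
        paw <- paste0(bp, sfx)
        ph <- tt / T + offs[[paw]]
        base <- if (bp == "front_toe") 2 else -2
        x0 <- body_x0 + base - params$stride * offs[[paw]]
        disp <- function(w) .swing_disp_overshoot(w, params$toe_overshoot)
        x_cm <- x0 + params$stride * .progression(ph, duty, disp)
        u <- ph %% 1
        lift <- amp[[bp]] * .swing_lift(u, duty)
        y_px <- ground_y - lift * ppc
        ms <- params$missteps[params$missteps$paw == paw, , drop = FALSE]
        for (i in seq_len(nrow(ms))) {
          inwin <- abs(tt - ms$time[i]) < hw
          dip <- numeric(n)
          dip[inwin] <- ms$depth[i] *
            sin(pi * (tt[inwin] - ms$time[i] + hw) / (2 * hw))^2
          y_px <- y_px + dip * ppc
          misstep_truth[[length(misstep_truth) + 1L]] <<- data.frame(
            paw = paw, view = side,
            start_frame = min(which(inwin)), end_frame = max(which(inwin)) + 1L,
            depth = ms$depth[i], stringsAsFactors = FALSE)
        }
        series[[bp]] <- noisy(bp, x_cm * ppc, y_px)
      } else {
        frac <- if (bp %in% c("back_ankle", "hip", "iliac_crest", "tail"))
          fr_back else fr_front
        h <- base_h[[bp]] + amp[[bp]] * (0.5 - 0.5 * cos(2 * pi * frac))
        series[[bp]] <- noisy(bp, (body_x + x_off[[bp]]) * ppc,
                              ground_y - h * ppc)
      }
    }
    pose_run(series, side, calibration, metadata)
  }
  left_run <- side_view("left")
  right_run <- side_view("right")

  onsets <- lapply(offs, .stance_onset_frames, params = params, n = n,
                   fps = fps)
  joint_truth <- list()
  for (side in c("left", "right")) {
    dfc <- params$deficit[[side]]
    amp <- params$joint_amplitudes * dfc
    joint_truth[[side]] <- data.frame(
      joint = names(amp),
      avg_height = unname(base_h[names(amp)] + amp / 2),
      total_vertical = unname(amp),
      stringsAsFactors = FALSE)
  }
  truth <- list(
    params = params,
    n_frames = n, fps = fps,
    stance_onsets = onsets,
    cycle_frames = T * fps,
    stride = params$stride,
    duty_cycle = duty,
    body_speed = body_speed,
    asynchrony = analytic_asynchrony(duty, params$asynchrony_offset),
    joints = joint_truth,
    max_protraction = (1 + params$toe_overshoot) * params$stride,
    max_retraction = params$toe_overshoot * params$stride,
    missteps = if (length(misstep_truth)) do.call(rbind, misstep_truth)
      else data.frame(paw = character(0), view = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      depth = numeric(0), stringsAsFactors = FALSE),
    rung_y = ground_y)
  structure(list(views = list(bottom = bottom_run, left = left_run,
                              right = right_run),
                 truth = truth, metadata = metadata),
            class = "simulated_run")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf("<simulated_run: %d frames, stride %g cm, duty %g>\n",
              x$truth$n_frames, x$truth$stride, x$truth$duty_cycle))
  invisible(x)
}

#' Simulate a labelled cohort of runs
#'
#' Each animal of each group gets an independent seed derived from the
#' master seed, and one simulated run per animal.
#'
#' @param n_per_group Animals per group (>= 1).
#' @param group_params Named list (>= 2 groups for classification
#'   fixtures) of [gait_params()]; names are the group labels.
#' @param seed Master seed.
#' @param duration Run duration in s passed to [simulate_run()].
#' @param calibration A [gait_calibration()].
#' @return Object of class `simulated_cohort`: list with `runs` (list
#'   of `simulated_run`s) and `manifest` (data frame with `animal`,
#'   `group`, `run`, `seed`; one row per run).
#' @export
simulate_cohort <- function(n_per_group, group_params, seed = 1L,
                            duration = 4, calibration = gait_calibration()) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  stopifnot(is.list(group_params), length(group_params) >= 1L,
            !is.null(names(group_params)))
  runs <- list()
  rows <- list()
  idx <- 0L
  for (g in seq_along(group_params)) {
    gp <- group_params[[g]]
    for (a in seq_len(n_per_group)) {
      idx <- idx + 1L
      sd_i <- .stream_seed(seed, g * 1000L + a)
      p <- gp
      p$seed <- sd_i
      animal <- sprintf("%s_a%02d", names(group_params)[g], a)
      md <- list(animal = animal, timepoint = names(group_params)[g],
                 run = "r1")
      runs[[idx]] <- simulate_run(p, duration, calibration, metadata = md)
      rows[[idx]] <- data.frame(animal = animal,
                                group = names(group_params)[g],
                                run = "r1", seed = sd_i,
                                stringsAsFactors = FALSE)
    }
  }
  structure(list(runs = runs, manifest = do.call(rbind, rows)),
            class = "simulated_cohort")
}

#' Write a simulated run to disk in the DLC dialect
#'
#' Emits one CSV per view (named `<prefix>_<view>.csv`) plus the ground
#' truth as JSON (`<prefix>_truth.json`).
#'
#' @param sim A [simulate_run()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, e.g. `"m01_baseline_r1"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_run <- function(sim, dir, prefix) {
  stopifnot(inherits(sim, "simulated_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (v in names(sim$views)) {
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, v))
    write_dlc_table(sim$views[[v]], p)
    paths[v] <- p
  }
  tp <- file.path(dir, sprintf("%s_truth.json", prefix))
  tr <- sim$truth
  tr$params <- unclass(tr$params)
  jsonlite::write_json(tr, tp, auto_unbox = TRUE, digits = NA)
  paths["truth"] <- tp
  invisible(paths)
}
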