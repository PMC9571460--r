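cal <- gait_calibration()

test_that("paw speed is the calibrated frame-to-frame x displacement", {
  s <- mk_series("front_toe_l", rep(100, 10))
  expect_equal(paw_speed(s, cal)[-1], rep(0, 9))
  s2 <- mk_series("front_toe_l", seq(0, 9))
  expect_equal(paw_speed(s2, cal)[-1],
               rep(60 / 37.79528, 9))  # 1 px/frame at 60 fps
  expect_error(paw_speed(mk_series("p", 1), cal), "2 frames")
})

test_that("speed is undefined next to masked frames", {
  s <- mk_series("p", 1:6, mask = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  sp <- paw_speed(s, cal)
  expect_true(is.na(sp[1]))
  expect_true(is.na(sp[3]))  # into the masked frame
  expect_true(is.na(sp[4]))  # out of the masked frame
  expect_false(anyNA(sp[c(2, 5, 6)]))
})

test_that("phase classification thresholds at 10 cm/s", {
  expect_true(all(classify_phases(rep(5, 30))$phase == "stance"))
  expect_true(all(classify_phases(rep(15, 30))$phase == "swing"))
  # square wave alternating 0 / 20 cm/s in 10-frame blocks
  sq <- rep(c(0, 20), each = 10, times = 3)
  ph <- classify_phases(sq)$phase
  expect_identical(ph, rep(c("stance", "swing"), each = 10, times = 3))
})

test_that("classification equals direct thresholding when debounce is off", {
  set.seed(3)
  for (i in 1:20) {
    sp <- runif(50, 0, 25)
    ph <- classify_phases(sp, smooth = 1, min_phase = 1)$phase
    expect_identical(ph, ifelse(sp > 10, "swing", "stance"))
  }
})

test_that("every valid frame gets exactly one phase and the threshold is monotone", {
  set.seed(4)
  sp <- abs(cumsum(rnorm(200)))
  for (thr in c(2, 5, 10)) {
    lo <- classify_phases(sp, threshold = thr, smooth = 1, min_phase = 1)$phase
    hi <- classify_phases(sp, threshold = thr + 3, smooth = 1, min_phase = 1)$phase
    expect_true(all(lo %in% c("stance", "swing")))
    # raising the threshold never converts stance to swing
    expect_false(any(lo == "stance" & hi == "swing"))
  }
})

test_that("step segmentation yields onset-to-onset cycles", {
  # 5 full square-wave periods -> 4 complete onset-to-onset cycles
  # (first stance onset to last stance onset)
  ph <- mk_phase_track(rep(rep(c("swing", "stance"), each = 10), 5))
  cyc <- segment_steps(ph)
  expect_s3_class(cyc, "step_cycles")
  expect_identical(nrow(cyc), 4L)
  expect_identical(cyc$start_frame, c(11L, 31L, 51L, 71L))
  expect_identical(cyc$end_frame - cyc$start_frame, rep(20L, 4))
  # stance + swing partition each cycle
  expect_identical((cyc$stance_end - cyc$stance_start) +
                     (cyc$swing_end - cyc$swing_start),
                   cyc$end_frame - cyc$start_frame)
  # cycles are disjoint and ordered
  expect_true(all(diff(cyc$start_frame) > 0))
  expect_true(all(cyc$end_frame[-4] <= cyc$start_frame[-1]))
})

test_that("an all-stance track has no step cycle, flagged", {
  cyc <- segment_steps(mk_phase_track(rep("stance", 50)))
  expect_identical(nrow(cyc), 0L)
  expect_match(attr(cyc, "flagged"), "no complete")
})

test_that("cycle durations convert frame counts at the video frame rate", {
  cyc <- mk_cycles(onsets = c(1, 61), stance_len = 40)
  d <- cycle_durations(cyc, cal)
  expect_equal(d$cycle, 1.0)
  expect_equal(d$stance, 40 / 60)
  expect_equal(d$swing, 20 / 60)
  expect_equal(d$stance + d$swing, d$cycle)
  expect_equal(d$duty_cycle, 2 / 3)
  empty <- segment_steps(mk_phase_track(rep("stance", 10)))
  expect_true(is.na(cycle_durations(empty, cal)$cycle))
})

test_that("stride length averages x distance between successive stance onsets", {
  x <- rep(0, 90)
  x[1:30] <- 0; x[31:60] <- 100; x[61:90] <- 200
  s <- mk_series("front_toe_l", x)
  cyc <- mk_cycles(onsets = c(1, 31, 61), stance_len = 20)
  expect_equal(stride_length(s, cyc, cal), 100 / 37.79528)
  # stationary paw: zero stride
  expect_equal(stride_length(mk_series("p", rep(5, 90)), cyc, cal), 0)
  # fewer than two onsets: undefined
  none <- segment_steps(mk_phase_track(rep("stance", 10)))
  expect_true(is.na(stride_length(s, none, cal)))
})

test_that("asynchrony tallies diagonal co-stance per the published formula", {
  stance <- function(n) rep("stance", n)
  swing <- function(n) rep("swing", n)
  # diagonal pairs always co-stance -> 0
  ph <- list(front_toe_l = mk_phase_track(stance(40), "front_toe_l"),
             back_toe_r = mk_phase_track(stance(40), "back_toe_r"),
             front_toe_r = mk_phase_track(stance(40), "front_toe_r"),
             back_toe_l = mk_phase_track(stance(40), "back_toe_l"))
  a <- asynchrony(ph)
  expect_equal(a$pooled$asynchrony, 0)
  # pair never jointly in stance -> 1
  ph$back_toe_r <- mk_phase_track(
    ifelse(ph$front_toe_l$phase == "stance", "swing", "stance"), "back_toe_r")
  ph$front_toe_l <- mk_phase_track(c(stance(20), swing(20)), "front_toe_l")
  ph$back_toe_r <- mk_phase_track(c(swing(20), stance(20)), "back_toe_r")
  expect_equal(asynchrony(ph)$lf_rb$asynchrony, 1)
  # 30 co-stance + 10 mismatched frames -> 1 - 30/40 = 0.25
  ph$front_toe_l <- mk_phase_track(c(stance(30), stance(10)), "front_toe_l")
  ph$back_toe_r <- mk_phase_track(c(stance(30), swing(10)), "back_toe_r")
  t1 <- asynchrony(ph)$lf_rb
  expect_identical(t1$total_sync, 30L)
  expect_identical(t1$total_not_sync, 10L)
  expect_equal(t1$asynchrony, 0.25)
})

test_that("asynchrony lies in [0,1] and is invariant to frame permutation", {
  set.seed(9)
  for (i in 1:10) {
    ph <- lapply(paw_names(), function(p)
      mk_phase_track(sample(c("stance", "swing"), 60, replace = TRUE), p))
    names(ph) <- paw_names()
    a <- asynchrony(ph)$pooled$asynchrony
    expect_gte(a, 0); expect_lte(a, 1)
    perm <- sample(60)
    php <- lapply(ph, function(t) mk_phase_track(t$phase[perm], t$paw))
    expect_equal(asynchrony(php)$pooled$asynchrony, a)
  }
})

test_that("paw-to-body-centre angle follows the fixed sign convention", {
  # body axis along +x: back centre (0,0), front centre (10,0); midpoint (5,0)
  cf <- mk_series("center_front", rep(10, 3), rep(0, 3))
  cb <- mk_series("center_back", rep(0, 3), rep(0, 3))
  # paw ahead of midpoint on the axis -> 0 degrees
  paw <- mk_series("front_toe_l", c(8, 5, 5), c(0, -3, 3))
  ang <- paw_body_angle(paw, cf, cb)
  expect_equal(ang[1], 0)
  # image y grows downward: y = -3 is physically left -> +90
  expect_equal(ang[2], 90)
  expect_equal(ang[3], -90)
})

test_that("paw angle matches a brute-force two-vector computation", {
  set.seed(10)
  n <- 200
  cf <- mk_series("center_front", runif(n, 200, 400), runif(n, 100, 300))
  cb <- mk_series("center_back", runif(n, 0, 180), runif(n, 100, 300))
  paw <- mk_series("front_toe_l", runif(n, 0, 400), runif(n, 0, 400))
  ang <- paw_body_angle(paw, cf, cb)
  for (i in seq_len(n)) {
    ax <- cf$x[i] - cb$x[i]; ay <- cf$y[i] - cb$y[i]
    vx <- paw$x[i] - (cf$x[i] + cb$x[i]) / 2
    vy <- paw$y[i] - (cf$y[i] + cb$y[i]) / 2
    ref <- atan2(-(ax * vy - ay * vx), ax * vx + ay * vy) * 180 / pi
    expect_equal(ang[i], ref, tolerance = 1e-12)
  }
})

test_that("degenerate body axis gives an invalid angle frame", {
  cf <- mk_series("center_front", c(5, 5), c(5, 5))
  cb <- mk_series("center_back", c(5, 0), c(5, 0))
  paw <- mk_series("front_toe_l", c(9, 9), c(9, 9))
  ang <- paw_body_angle(paw, cf, cb)
  expect_true(is.na(ang[1]))
  expect_false(is.na(ang[2]))
})
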