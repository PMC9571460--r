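cal <- gait_calibration()
ppc <- 37.79528

test_that("vertical stats recover constant and sinusoidal heights", {
  n <- 121
  cyc <- mk_cycles(onsets = c(1, 61, 121), stance_len = 40)
  # constant-height joint: zero vertical movement
  s <- mk_series("wrist", seq_len(n), rep(400 - 2 * ppc, n))
  vs <- vertical_stats(s, cyc, cal, ground_y = 400)
  expect_equal(vs$total_vertical, 0)
  expect_equal(vs$avg_height, 2)
  # sinusoid of amplitude a (in cm) around offset b: total vertical ~ 2a
  a <- 1.5; b <- 3
  y <- 400 - (b + a * sin(2 * pi * (0:(n - 1)) / 60)) * ppc
  vs2 <- vertical_stats(mk_series("wrist", seq_len(n), y), cyc, cal, 400)
  expect_equal(vs2$total_vertical, 2 * a, tolerance = 0.01)
  expect_equal(vs2$avg_height, b, tolerance = 0.01)
})

test_that("horizontal stats recover step length and match a naive max-min loop", {
  cyc <- mk_cycles(onsets = c(1, 61, 121), stance_len = 40)
  # joint advancing exactly 100 px per cycle
  x <- (0:120) * (100 / 60)
  hs <- horizontal_stats(mk_series("hip", x, rep(0, 121)), cyc, cal)
  expect_equal(hs$avg_step_length, 100 / ppc)
  expect_equal(hs$total_horizontal, 100 / ppc)
  # stationary joint
  hs0 <- horizontal_stats(mk_series("hip", rep(7, 121), rep(0, 121)), cyc, cal)
  expect_equal(hs0$avg_step_length, 0)
  expect_equal(hs0$total_horizontal, 0)
  # random walk vs brute-force per-cycle loop
  set.seed(14)
  xw <- cumsum(rnorm(121))
  hsw <- horizontal_stats(mk_series("hip", xw, rep(0, 121)), cyc, cal)
  ref <- mean(vapply(seq_len(nrow(cyc)), function(i) {
    w <- xw[cyc$start_frame[i]:cyc$end_frame[i]]
    max(w) - min(w)
  }, numeric(1))) / ppc
  expect_equal(hsw$total_horizontal, ref)
})

test_that("length outputs are invariant to coordinate translation", {
  set.seed(15)
  cyc <- mk_cycles(onsets = c(1, 61, 121), stance_len = 40)
  x <- cumsum(rnorm(121)); y <- 400 - abs(rnorm(121, 50, 10))
  s <- mk_series("wrist", x, y)
  st <- mk_series("wrist", x + 123.4, y + 55.5)
  expect_equal(horizontal_stats(st, cyc, cal)$total_horizontal,
               horizontal_stats(s, cyc, cal)$total_horizontal)
  expect_equal(vertical_stats(st, cyc, cal, max(y + 55.5))$total_vertical,
               vertical_stats(s, cyc, cal, max(y))$total_vertical)
})

test_that("protraction/retraction split on the displacement sign", {
  cyc1 <- mk_cycles(onsets = c(1, 81), stance_len = 40)
  # monotone forward sweep of 50 px then hold
  x <- c(seq(0, 50, length.out = 26), rep(50, 55))
  pr <- protraction_retraction(mk_series("front_toe", x, rep(0, 81)), cyc1, cal)
  expect_equal(pr$max_protraction, 50 / ppc)
  expect_equal(pr$max_retraction, 0)
  # triangle wave, peak-to-trough 80 px: protraction == retraction
  xt <- c(seq(0, 80, by = 4), seq(76, 0, by = -4), rep(0, 40))
  cyc2 <- mk_cycles(onsets = c(1, length(xt)), stance_len = 20)
  prt <- protraction_retraction(mk_series("front_toe", xt, rep(0, length(xt))),
                                cyc2, cal)
  expect_equal(prt$max_protraction, 80 / ppc)
  expect_equal(prt$max_retraction, 80 / ppc)
  # pure stance jitter inside the dead-band
  set.seed(16)
  xj <- cumsum(runif(81, -0.2, 0.2))
  xj <- xj - seq(0, max(abs(xj)), length.out = 81) * sign(xj[81])  # keep tiny
  prj <- protraction_retraction(mk_series("front_toe", rep(3, 81), rep(0, 81)),
                                cyc1, cal)
  expect_equal(prj$max_protraction, 0)
  expect_equal(prj$max_retraction, 0)
})

test_that("three-point joint angle follows the atan2 difference, normalized", {
  expect_equal(joint_angle(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_equal(joint_angle(c(0, 0), c(2, 2), c(2, 2)), 0)
  expect_true(is.na(joint_angle(c(0, 0), c(0, 0), c(1, 1))))
  # angles live in [0, 360)
  expect_equal(joint_angle(c(0, 0), c(0, 1), c(1, 0)), 270)
})

test_that("joint angle magnitude matches the law of cosines on random triples", {
  set.seed(17)
  for (i in 1:1000) {
    p1 <- runif(2, -10, 10); p2 <- runif(2, -10, 10); p3 <- runif(2, -10, 10)
    a <- joint_angle(p1, p2, p3)
    v1 <- p2 - p1; v2 <- p3 - p1
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ref <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    expect_equal(min(a, 360 - a), ref, tolerance = 1e-9)
    # antisymmetry: swapping the rays mirrors the angle mod 360
    b <- joint_angle(p1, p3, p2)
    expect_equal((a + b) %% 360, 0, tolerance = 1e-9)
  }
})

test_that("angles are invariant to translation and uniform scaling", {
  set.seed(18)
  for (i in 1:50) {
    p1 <- runif(2); p2 <- runif(2); p3 <- runif(2)
    sh <- runif(2, -5, 5); k <- runif(1, 0.1, 10)
    a <- joint_angle(p1, p2, p3)
    expect_equal(joint_angle(p1 + sh, p2 + sh, p3 + sh), a, tolerance = 1e-9)
    expect_equal(joint_angle(p1 * k + sh, p2 * k + sh, p3 * k + sh), a,
                 tolerance = 1e-9)
  }
})

test_that("angular variability summarizes per-cycle max/mean/min", {
  n <- 121
  cyc <- mk_cycles(onsets = c(1, 61, 121), stance_len = 40)
  run_const <- mk_run(list(
    hip = mk_series("hip", rep(0, n), rep(0, n)),
    back_ankle = mk_series("back_ankle", rep(1, n), rep(1, n)),
    back_toe = mk_series("back_toe", rep(2, n), rep(1, n))), view = "left")
  tri <- angle_triple(run_const, "back_ankle", "hip", "back_toe")
  av <- angular_variability(tri, cyc)
  expect_equal(av$max, av$mean)
  expect_equal(av$mean, av$min)
  # sinusoidal angle 120 +/- 30 degrees
  ang <- 120 + 30 * sin(2 * pi * (0:(n - 1)) / 60)
  tri2 <- structure(list(vertex = "v", from = "f", to = "t", angles = ang),
                    class = "angle_triple")
  av2 <- angular_variability(tri2, cyc)
  expect_equal(av2$max, 150, tolerance = 0.1)
  expect_equal(av2$mean, 120, tolerance = 0.1)
  expect_equal(av2$min, 90, tolerance = 0.1)
  expect_true(av2$max >= av2$mean && av2$mean >= av2$min)
})

test_that("side-view joint stats recover simulator ground truth", {
  sim <- simulate_run(gait_params(seed = 3))
  cal <- sim$views$left$calibration
  b <- normalize_direction(filter_likelihood(sim$views$bottom))
  l <- normalize_direction(filter_likelihood(sim$views$left))
  cyc <- segment_steps(classify_phases(
    paw_speed(b$series$front_toe_l, cal), paw = "front_toe_l"))
  gy <- ground_reference(l)
  truth <- sim$truth$joints$left
  for (j in c("wrist", "elbow", "shoulder")) {
    vs <- vertical_stats(l$series[[j]], cyc, cal, gy)
    tv <- truth$total_vertical[truth$joint == j]
    expect_equal(vs$total_vertical, tv, tolerance = 0.02 * max(tv, 0.5))
    expect_equal(vs$avg_height, truth$avg_height[truth$joint == j],
                 tolerance = 0.02 * truth$avg_height[truth$joint == j])
  }
  hs <- horizontal_stats(l$series$hip, cyc, cal)
  expect_equal(hs$avg_step_length, sim$truth$stride, tolerance = 0.02 * 6)
  pr <- protraction_retraction(l$series$front_toe, cyc, cal)
  expect_equal(pr$max_protraction, sim$truth$max_protraction,
               tolerance = 0.02 * sim$truth$max_protraction)
  expect_equal(pr$max_retraction, sim$truth$max_retraction,
               tolerance = 0.05 * sim$truth$max_retraction + 0.02)
})

test_that("an injected one-sided lift deficit shows up as reduced vertical movement", {
  intact <- simulate_run(gait_params(seed = 8))
  hurt <- simulate_run(gait_params(deficit = list(left = 0.7, right = 1), seed = 8))
  get_tv <- function(sim) {
    cal <- sim$views$left$calibration
    b <- normalize_direction(filter_likelihood(sim$views$bottom))
    l <- normalize_direction(filter_likelihood(sim$views$left))
    cyc <- segment_steps(classify_phases(
      paw_speed(b$series$front_toe_l, cal), paw = "front_toe_l"))
    vertical_stats(l$series$front_toe, cyc, cal,
                   ground_reference(l))$total_vertical
  }
  tv_i <- get_tv(intact); tv_h <- get_tv(hurt)
  expect_equal(tv_h / tv_i, 0.7, tolerance = 0.03)
})
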