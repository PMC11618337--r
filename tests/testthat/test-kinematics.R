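# Kinematic feature extraction: closed forms, onset, zero-crossings.

test_that("minimum-jerk closed forms hold at the sampled resolution", {
  P <- min_jerk_segment(0.3, 1, c(1, 0, 0), 100)
  expect_equal(nrow(P), 101)
  expect_equal(P[51, 1], 0.15)                       # x(tau = 0.5) = A/2
  expect_equal(P[101, 1], 0.3)
  tr <- make_minjerk_trial()
  st <- differentiate(tr, filter_spec("none"))
  expect_equal(max(st$speed), 1.875 * 0.3 / 1, tolerance = 0.01)
  expect_equal(max(st$accel_mag), (10 / sqrt(3)) * 0.3, tolerance = 0.01)
  # warped profile moves the speed peak without moving the endpoints
  Pw <- min_jerk_segment(0.3, 1, c(1, 0, 0), 100, peak_fraction = 0.3)
  expect_equal(Pw[101, 1], 0.3)
  v <- diff(Pw[, 1]) * 100
  expect_equal(which.max(v) / 100, 0.3, tolerance = 0.02)
  expect_warning(min_jerk_segment(0.3, 1, c(2, 0, 0)), "normalizing")
  expect_error(min_jerk_segment(0.3, 1, c(0, 0, 0)), "nonzero")
  expect_error(min_jerk_segment(0.3, 0.03), "at least 5 samples")
})

test_that("zero-crossing counting follows the hysteresis contract", {
  expect_equal(count_zero_crossings(c(1, -1, 1), 0), 2)
  # excursion inside the band does not count
  expect_equal(count_zero_crossings(c(1, -0.001, 1), 0.01), 0)
  # exact zeros resolve to the next signed sample
  expect_equal(count_zero_crossings(c(1, 0, -1), 0), 1)
  expect_equal(count_zero_crossings(c(1, 0, 1), 0), 0)
  # 2 Hz sinusoid over 3 s at 100 Hz crosses zero 11 times
  tt <- (0:299) / 100
  expect_equal(count_zero_crossings(sin(4 * pi * tt)), 11)
})

test_that("zero-crossing counts equal the brute-force oracle at h = 0", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    if (i %% 7 == 0) x[sample(n, 2)] <- 0   # exercise exact zeros
    expect_identical(count_zero_crossings(x, 0), zero_crossings_oracle(x))
  }
})

test_that("movement-unit RMS consolidates per-axis counts", {
  # counts (3, 4, 0) -> sqrt(25/3); (0,0,0) -> 0
  expect_equal(sqrt((3^2 + 4^2 + 0^2) / 3), 2.886751, tolerance = 1e-6)
  tr <- make_minjerk_trial()
  st <- differentiate(tr, filter_spec("none"))
  mu <- movement_units(st, c(1, 101))
  # single-axis reach: velocity never changes sign; acceleration once
  expect_equal(unname(mu["mu_type1_rms"]), 0)
  expect_equal(unname(mu["mu_type2_rms"]), 1 / sqrt(3))
})

test_that("onset detection follows the dual-threshold rule with burst-start refinement", {
  fs <- 100
  tr <- make_minjerk_trial(pre_go_s = 0.5, rt_s = 0.3)
  st <- differentiate(tr, filter_spec("none"))
  on_lit <- detect_onset(tr, st, onset_refine = "none")
  on_ref <- detect_onset(tr, st, onset_refine = "burst_start")
  expect_gt(on_lit, on_ref)   # literal rule fires mid-reach
  # refined onset within 2 samples of the true reach start (go + 0.3 s)
  true_start <- round(0.8 * fs) + 1
  expect_lte(abs(on_ref - true_start), 2)
  # reaction time recovered within 0.02 s of the known 0.30 s delay
  f <- extract_features(tr, kinematic_options(smoothing = filter_spec("none")))
  expect_equal(unname(f["reaction_time_s"]), 0.30, tolerance = 0.02)
  # motionless trial raises a no-movement error
  still <- trial("S1", "TD", 1, matrix(0, 50, 3))
  st0 <- differentiate(still, filter_spec("none"))
  expect_error(detect_onset(still, st0), "no movement")
})

test_that("summary features recover generator ground truth on noiseless reaches", {
  tr <- make_minjerk_trial(amplitude = 0.3, duration = 1)
  st <- differentiate(tr, filter_spec("none"))
  on <- detect_onset(tr, st)
  sf <- summary_features(tr, st, on)
  expect_equal(unname(sf["total_distance_m"]), 0.300, tolerance = 0.003)
  expect_equal(unname(sf["max_velocity_mps"]), 0.5625, tolerance = 0.006)
  expect_equal(unname(sf["time_to_peak_velocity_s"]), 0.50, tolerance = 0.02)
  expect_equal(unname(sf["avg_velocity_mps"]), 0.300, tolerance = 0.003)
  # one overshoot-and-return submovement of extra path 0.06 m
  set.seed(3)
  prof <- noiseless_profile(mt = 1, amp = 0.3, overshoot = 0.2)
  prof$overshoot_fraction_mean <- 0.2
  ct <- compose_trial(prof)
  # force the overshoot draw deterministic: rebuild with sd-free profile
  f <- extract_features(ct$trial, kinematic_options(smoothing = filter_spec("none")))
  expect_equal(unname(f["total_distance_m"]),
               ct$truth$path_length_m, tolerance = 0.005)
})

test_that("extracted features satisfy the structural invariants", {
  set.seed(77)
  profs <- default_profiles()
  for (g in c("TD", "ASD")) {
    ct <- compose_trial(profs[[g]])
    f <- extract_features(ct$trial)
    expect_true(all(f >= 0))
    expect_gte(f[["max_velocity_mps"]], f[["avg_velocity_mps"]])
    expect_gte(f[["max_acceleration_mps2"]], f[["avg_acceleration_mps2"]])
    expect_lte(f[["time_to_peak_velocity_s"]], f[["movement_time_s"]])
    # mu RMS times sqrt(3) squared is an integer count sum
    for (mu in c("mu_type1_rms", "mu_type2_rms", "mu_type3_rms"))
      expect_equal((f[[mu]] * sqrt(3))^2, round((f[[mu]] * sqrt(3))^2),
                   tolerance = 1e-6)
  }
})

test_that("onset error stays within 2 samples across random noiseless profiles", {
  set.seed(55)
  errs <- replicate(100, {
    mt <- runif(1, 0.8, 2.2)
    prof <- noiseless_profile(mt = mt, amp = runif(1, 0.15, 0.45),
                              rt = runif(1, 0.2, 0.7),
                              ttp = runif(1, 0.3, 0.7))
    ct <- compose_trial(prof)
    st <- differentiate(ct$trial, filter_spec("none"))
    on <- detect_onset(ct$trial, st)
    (on - 1) - ct$truth$reach_start_index
  })
  expect_lte(max(abs(errs)), 2)
})
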