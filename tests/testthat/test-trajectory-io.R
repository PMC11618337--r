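# Trial containers, CSV round-trips and common-frame registration.

test_that("trial constructor enforces its invariants", {
  disp <- matrix(0, 12, 3)
  t1 <- trial("S1", "TD", 1, disp)
  expect_s3_class(t1, "reachkin_trial")
  expect_error(trial("S1", "ASDD", 1, disp), "unknown group")
  expect_error(trial("S1", "TD", 1, disp[1:5, ]), "at least 10 samples")
  disp_bad <- disp; disp_bad[3, 2] <- NA
  expect_error(trial("S1", "TD", 1, disp_bad), "non-finite")
  expect_error(trial("S1", "TD", 1, disp, go_signal_index = 12), "go_signal_index")
})

test_that("trial_set rejects duplicate keys and inconsistent group labels", {
  disp <- matrix(0, 12, 3)
  a <- trial("S1", "TD", 1, disp)
  b <- trial("S1", "TD", 1, disp)
  expect_error(trial_set(list(a, b)), "duplicate")
  c2 <- trial("S1", "ASD", 2, disp)
  expect_error(trial_set(list(a, c2)), "more than one group")
  ts <- trial_set(list(a, trial("S1", "TD", 2, disp)), provenance = "SYNTHETIC",
                  seed = 7)
  expect_equal(length(ts), 2)
})

test_that("read_trials parses long CSV, validates labels and sample order", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(subject = "S1", group = "TD", trial = 1,
                   sample_index = 0:11, x = 0, y = 0, z = 0)
  write_trials_csv(df, f)
  ts <- read_trials(f)
  expect_equal(length(ts), 1)
  expect_equal(nrow(ts$trials[[1]]$displacement), 12)
  expect_true(all(ts$trials[[1]]$displacement == 0))
  expect_identical(ts$provenance, "FILE")

  df_bad <- df; df_bad$group <- "ASDD"
  write_trials_csv(df_bad, f)
  expect_error(read_trials(f), "unknown group label")

  df_mono <- df; df_mono$sample_index[5] <- 2
  write_trials_csv(df_mono, f)
  expect_error(read_trials(f), "non-monotone")

  names(df)[names(df) == "x"] <- "pos_x"
  write_trials_csv(df, f)
  expect_error(read_trials(f), "missing column")
  ts2 <- read_trials(f, schema = c(x = "pos_x"))
  expect_equal(length(ts2), 1)
})

test_that("millimeter input is converted to meters", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(subject = "S1", group = "TD", trial = 1,
                   sample_index = 0:11, x = 1000, y = 0, z = 0)
  write_trials_csv(df, f)
  ts <- read_trials(f, units = "mm")
  expect_equal(unname(ts$trials[[1]]$displacement[1, 1]), 1)
})

test_that("write/read trial round-trip preserves coordinates to 9 digits", {
  set.seed(31)
  trials <- lapply(1:5, function(i) {
    trial(sprintf("S%d", i), sample(c("TD", "ASD", "ADULT"), 1), 1L,
          matrix(rnorm(60, sd = 0.2), 20, 3), 100, go_signal_index = 3)
  })
  ts <- trial_set(trials, provenance = "SYNTHETIC", seed = 31)
  f <- tempfile(fileext = ".csv")
  write_trials(ts, f)
  back <- read_trials(f)
  expect_equal(length(back), 5)
  expect_identical(back$seed, 31L)
  for (i in 1:5) {
    orig <- ts$trials[[i]]
    got <- Filter(function(t) t$subject_id == orig$subject_id, back$trials)[[1]]
    expect_lt(max(abs(got$displacement - orig$displacement)), 1e-9)
    expect_equal(got$go_signal_index, orig$go_signal_index)
  }
})

test_that("feature table round-trips and enforces column order", {
  set.seed(5)
  feats <- data.frame(subject_id = sprintf("S%02d", 1:50), group = "TD",
                      trial_index = 1L)
  for (col in kinematic_feature_names()) feats[[col]] <- runif(50)
  f <- tempfile(fileext = ".csv")
  write_features(feats, f)
  back <- read_features(f)
  expect_equal(names(back), c("subject_id", "group", "trial_index",
                              kinematic_feature_names()))
  expect_equal(back[kinematic_feature_names()],
               feats[kinematic_feature_names()], tolerance = 1e-12)
  expect_error(write_features(feats[0, ], f), "non-empty")
  expect_error(write_features(feats[, -4], f), "missing column")
})

test_that("to_common_frame is rigid and aligns the principal axis with +X", {
  # pure +Y reach maps to +X with path length preserved
  tr <- make_minjerk_trial(direction = c(0, 1, 0))
  cf <- to_common_frame(tr)
  expect_equal(cf$displacement[1, ], c(x = 0, y = 0, z = 0))
  expect_gt(cf$displacement[nrow(cf$displacement), 1], 0.29)
  expect_lt(max(abs(cf$displacement[, 2:3])), 1e-9)

  # rigid: pairwise distances preserved on a noisy trajectory
  set.seed(8)
  tr2 <- trial("S1", "TD", 1, matrix(rnorm(90, sd = 0.1), 30, 3))
  cf2 <- to_common_frame(tr2)
  idx <- cbind(sample(30, 40, TRUE), sample(30, 40, TRUE))
  d0 <- sqrt(rowSums((tr2$displacement[idx[, 1], ] - tr2$displacement[idx[, 2], ])^2))
  d1 <- sqrt(rowSums((cf2$displacement[idx[, 1], ] - cf2$displacement[idx[, 2], ])^2))
  expect_equal(d1, d0, tolerance = 1e-9)

  # trial already at origin moving along +X is unchanged
  tr3 <- make_minjerk_trial(direction = c(1, 0, 0))
  cf3 <- to_common_frame(tr3)
  expect_equal(cf3$displacement, tr3$displacement, tolerance = 1e-9,
               ignore_attr = TRUE)

  # degenerate: no motion -> translated only, with warning
  tr4 <- trial("S1", "TD", 1, matrix(1, 12, 3))
  expect_warning(cf4 <- to_common_frame(tr4), "degenerate")
  expect_true(all(cf4$displacement == 0))
})

test_that("rotation-invariant features are unchanged by rigid rotation", {
  set.seed(21)
  prof <- noiseless_profile(n_corr = 2, overshoot = 0.1)
  ct <- compose_trial(prof)
  opts <- kinematic_options(smoothing = filter_spec("none"))
  f0 <- extract_features(ct$trial, opts)
  rot_inv <- setdiff(kinematic_feature_names(),
                     c("mu_type1_rms", "mu_type2_rms", "mu_type3_rms"))
  for (i in 1:3) {
    R <- random_rotation()
    f1 <- extract_features(apply_rotation(ct$trial, R), opts)
    expect_equal(f1[rot_inv], f0[rot_inv], tolerance = 1e-6)
  }
  # and the common frame itself leaves them unchanged too
  f2 <- extract_features(to_common_frame(ct$trial), opts)
  expect_equal(f2[rot_inv], f0[rot_inv], tolerance = 1e-6)
})
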