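# MLP classifier: normalization, architecture, schedule, CV, importance.
# Module tests shorten training (fewer epochs / smaller n) for speed; the
# full 200-epoch protocol runs in test-acceptance.R.

fast_spec <- function(...) mlp_spec(epochs = 40, ...)

test_that("min-max normalization maps every column to [0, 1]", {
  expect_equal(minmax_normalize(cbind(c(2, 4, 6)))[, 1], c(0, 0.5, 1))
  expect_warning(z <- minmax_normalize(cbind(c(5, 5, 5), c(0, 1, 2))),
                 "constant")
  expect_true(all(z[, 1] == 0))
  set.seed(1)
  X <- minmax_normalize(matrix(rnorm(60), 20, 3))
  expect_equal(unname(apply(X, 2, min)), c(0, 0, 0))
  expect_equal(unname(apply(X, 2, max)), c(1, 1, 1))
  expect_error(minmax_normalize(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  # external ranges are honoured (per-training-fold variant)
  r <- attr(minmax_normalize(matrix(c(0, 10), 2, 1)), "ranges")
  expect_equal(minmax_normalize(matrix(c(5, 2.5), 2, 1), ranges = r)[, 1],
               c(0.5, 0.25))
})

test_that("the built network has the stated architecture", {
  d <- make_separable(1, n = 60, shift = 2)
  m <- train_mlp(d$X[1:40, ], d$y[1:40], d$X[41:60, ], d$y[41:60],
                 mlp_spec(epochs = 2), seed = 1)
  audit <- mlp_audit(m)
  expect_identical(audit$n_linear, 4L)
  expect_identical(audit$n_batchnorm, 2L + 1L)
  expect_identical(audit$n_leaky_relu, 3L)
  expect_identical(audit$n_sigmoid, 1L)
  expect_equal(dim(m$params$W[[1]]), c(9, 64))
  expect_equal(dim(m$params$W[[4]]), c(16, 1))
})

test_that("training is deterministic and follows the learning-rate schedule", {
  d <- make_separable(2, n = 120, shift = 4)
  Xn <- minmax_normalize(d$X)
  set.seed(3); idx <- sample(120); tr <- idx[1:96]; va <- idx[97:120]
  m1 <- train_mlp(Xn[tr, ], d$y[tr], Xn[va, ], d$y[va], fast_spec(), seed = 9)
  m2 <- train_mlp(Xn[tr, ], d$y[tr], Xn[va, ], d$y[va], fast_spec(), seed = 9)
  expect_identical(m1$history, m2$history)
  m3 <- train_mlp(Xn[tr, ], d$y[tr], Xn[va, ], d$y[va], fast_spec(), seed = 10)
  expect_false(identical(m1$history$val_loss, m3$history$val_loss))
  # lr history is two-valued and non-increasing
  expect_true(all(m1$history$lr %in% c(1e-5, 1e-6)))
  expect_true(!is.unsorted(rev(m1$history$lr)))
  # best_val_loss is the minimum of the recorded validation losses
  expect_equal(m1$best_val_loss, min(m1$history$val_loss))
  expect_error(train_mlp(Xn[tr, ], rep(1, 96), Xn[va, ], d$y[va], fast_spec()),
               "both classes")
})

test_that("separable data is fit and fold partitions are valid", {
  d <- make_separable(4, n = 150, shift = 5)
  fold <- make_folds(d$y, k = 10, seed = 1)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(length(fold), 150)
  for (f in 1:10) {            # stratification keeps both classes per fold
    expect_true(all(table(d$y[fold == f]) >= 1))
  }
  cv <- cross_validate(d$X, d$y, fast_spec(), k = 5, seed = 2,
                       keep_models = FALSE)
  expect_equal(cv$k, 5)
  expect_true(all(cv$fold_accuracy >= 0 & cv$fold_accuracy <= 1))
  expect_gt(cv$mean_accuracy, 0.8)
})

test_that("subject grouping keeps subjects within one fold and reduces k", {
  y <- rep(0:1, each = 24)
  subj <- rep(sprintf("S%02d", 1:8), each = 6)
  fold <- make_folds(y, k = 10, subject_id = subj, seed = 1) |>
    suppressWarnings()
  expect_equal(attr(fold, "k"), 8)
  for (s in unique(subj))
    expect_equal(length(unique(fold[subj == s])), 1)
  expect_warning(make_folds(y, k = 10, subject_id = subj, seed = 1),
                 "reducing folds")
})

test_that("subject-grouped CV does not beat trial-level CV under subject effects", {
  # subject random effects leak across trial-level folds; grouped folds
  # remove that advantage
  accs <- vapply(1:4, function(s) {
    set.seed(s)
    n_sub <- 20; tps <- 6
    subj <- rep(sprintf("S%02d", 1:n_sub), each = tps)
    y <- rep(rep(0:1, each = n_sub / 2), each = tps)
    sub_eff <- rep(rnorm(n_sub, sd = 1.5), each = tps)
    X <- matrix(rnorm(n_sub * tps * 9, mean = sub_eff + y * 0.8),
                n_sub * tps, 9)
    cv_t <- cross_validate(X, y, fast_spec(), k = 5, seed = s,
                           keep_models = FALSE)
    cv_s <- cross_validate(X, y, fast_spec(), k = 5, grouping = "subject",
                           subject_id = subj, seed = s, keep_models = FALSE)
    cv_s$mean_accuracy - cv_t$mean_accuracy
  }, numeric(1))
  expect_lte(mean(accs), 0.02)
})

test_that("permutation importance finds the informative feature", {
  d <- make_one_informative(6, n = 160)
  Xn <- minmax_normalize(d$X)
  set.seed(7); idx <- sample(160); tr <- idx[1:128]; va <- idx[129:160]
  m <- train_mlp(Xn[tr, ], d$y[tr], Xn[va, ], d$y[va], fast_spec(), seed = 7)
  imp <- permutation_importance(m, Xn[va, ], d$y[va], n_repeats = 20, seed = 1)
  expect_s3_class(imp, "reachkin_importance")
  expect_identical(sort(imp$rank), 1:9)
  expect_identical(imp$feature[imp$rank == 1], "f1")
  # a feature constant across the dataset shuffles to itself: zero delta
  dc <- make_one_informative(16, n = 120)
  dc$X[, 5] <- 7
  Xc <- suppressWarnings(minmax_normalize(dc$X))
  set.seed(17); idx <- sample(120); tr <- idx[1:96]; va <- idx[97:120]
  mc <- train_mlp(Xc[tr, ], dc$y[tr], Xc[va, ], dc$y[va], fast_spec(), seed = 3)
  imp_c <- permutation_importance(mc, Xc[va, ], dc$y[va], n_repeats = 5, seed = 2)
  expect_lt(abs(imp_c$delta_loss[5]), 1e-6)
})

test_that("cross-validated importance aggregates over folds", {
  d <- make_one_informative(8, n = 120)
  cv <- cross_validate(d$X, d$y, fast_spec(), k = 4, seed = 3)
  imp <- cv_permutation_importance(cv, n_repeats = 10, seed = 4)
  expect_identical(imp$feature[imp$rank == 1], "f1")
  cv2 <- cross_validate(d$X, d$y, fast_spec(), k = 4, seed = 3,
                        keep_models = FALSE)
  expect_error(cv_permutation_importance(cv2), "keep_models")
})
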