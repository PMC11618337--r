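# Nonparametric tests, correlations and FDR control against independent
# oracles (exact enumeration, stats:: implementations, simulation).

test_that("Mann-Whitney exact small-sample results match enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.100)
  expect_identical(r$method, "exact")
  # identical samples: p = 1 via the midrank path
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p_value, 1)
  # a single shared value across both samples is degenerate
  r3 <- mann_whitney_u(c(2, 2), c(2, 2, 2))
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
})

test_that("Mann-Whitney agrees with wilcox.test on both branches", {
  set.seed(201)
  for (i in 1:50) {
    na <- sample(3:9, 1); nb <- sample(3:9, 1)
    a <- rnorm(na); b <- rnorm(nb, mean = runif(1, -1, 1))
    mine <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic))
    if (mine$method == "exact") expect_equal(mine$p_value, ref$p.value,
                                             tolerance = 1e-12)
  }
  # large-sample/tied branch against the normal approximation in wilcox.test
  for (i in 1:30) {
    a <- round(rnorm(18), 1); b <- round(rnorm(25, 0.4), 1)
    mine <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("exact and normal-approximation p-values agree for group sizes 6-12", {
  # exhaustive at the 6 vs 6 boundary (the largest case the exact branch
  # serves): every achievable U, enumeration vs continuity-corrected normal
  na <- 6; nb <- 6
  combos <- utils::combn(na + nb, na)
  u_all <- colSums(matrix((1:(na + nb))[combos], nrow = na)) - na * (na + 1) / 2
  exact_p <- function(U) min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
  approx_p <- function(U) {
    mu <- na * nb / 2; s2 <- na * nb * (na + nb + 1) / 12
    min(1, 2 * pnorm(-abs((U - mu - sign(U - mu) * 0.5) / sqrt(s2))))
  }
  devs <- vapply(0:(na * nb), function(U) abs(exact_p(U) - approx_p(U)),
                 numeric(1))
  expect_lt(max(devs), 0.02)
  # and the implementation's exact branch reproduces the enumeration oracle
  set.seed(77)
  a <- rnorm(6); b <- rnorm(6)
  mine <- mann_whitney_u(a, b)
  expect_identical(mine$method, "exact")
  expect_equal(mine$p_value, exact_p(mine$statistic), tolerance = 1e-12)
})

test_that("Mann-Whitney type-I error is calibrated under the null", {
  set.seed(301)
  rej <- mean(replicate(1000, mann_whitney_u(rnorm(15), rnorm(26))$p_value < 0.05))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("Levene/Brown-Forsythe matches an anova oracle and flags degeneracy", {
  set.seed(41)
  a <- rnorm(20, sd = 1); b <- rnorm(25, sd = 2.5)
  mine <- levene_test(a, b)
  z <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(1:2, c(20, 25)))
  ref <- anova(lm(z ~ g))
  expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
  same <- levene_test(c(1, 2, 3), c(1, 2, 3))   # identical groups: W = 0
  expect_equal(same$statistic, 0)
  const <- levene_test(c(1, 1, 1), c(2, 2, 2))  # zero spread: degenerate
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)
})

test_that("KS normality check behaves on conforming and heavy-tailed samples", {
  # sample placed at its own fitted normal quantiles: tiny D
  x <- qnorm(ppoints(100), mean = 5, sd = 2)
  expect_lt(ks_test(x)$statistic, 0.05)
  # heavy tails get rejected most of the time
  set.seed(61)
  rej <- mean(replicate(200, ks_test(rcauchy(100))$p_value < 0.05))
  expect_gt(rej, 0.9)
})

test_that("Pearson correlation matches hand computation and cor.test", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6))$statistic, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2))$statistic, 0.5)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$statistic, -1)
  set.seed(91)
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(length(x)) + 0.5 * x
    mine <- pearson_r(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("BH step-up matches p.adjust and is monotone", {
  expect_true(all(fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)))
  expect_false(any(fdr_bh(c(0.9, 0.8), 0.05)))
  set.seed(71)
  for (i in 1:100) {
    p <- runif(sample(3:20, 1))
    expect_identical(fdr_bh(p, 0.05), p.adjust(p, "BH") <= 0.05)
  }
  # monotone: lowering one p-value never un-rejects another
  p <- c(0.011, 0.04, 0.2, 0.9)
  before <- fdr_bh(p, 0.05)
  p2 <- p; p2[3] <- 0.001
  after <- fdr_bh(p2, 0.05)
  expect_true(all(after[before]))
})

test_that("BH controls the empirical FDR on null uniforms", {
  set.seed(81)
  fdp <- replicate(1000, {
    rej <- fdr_bh(runif(12), 0.05)
    if (any(rej)) 1 else 0   # all-null: V/R is 1 whenever anything is rejected
  })
  # all-null FDR equals q exactly in expectation; allow binomial MC error
  expect_lte(mean(fdp), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 1000))
})

test_that("compare_groups produces one calibrated row per feature and pair", {
  coh <- simulate_cohort(sim_config(n_subjects = c(TD = 6, ASD = 8), seed = 13))
  feats <- suppressMessages(extract_features_set(coh))
  gs <- compare_groups(feats, pairs = list(c("TD", "ASD")))
  expect_equal(nrow(gs), 12)
  expect_true(all(gs$p_value >= 0 & gs$p_value <= 1))
  expect_true(all(c("levene_p", "ks_normal_p") %in% names(gs)))
  # identical groups: copied data shows no effect
  dup <- feats; dup$group <- "TD"
  dup2 <- feats; dup2$group <- "ASD"; dup2$subject_id <- paste0("X", dup2$subject_id)
  gs2 <- compare_groups(rbind(dup, dup2), pairs = list(c("TD", "ASD")))
  expect_true(all(gs2$p_value >= 0.9))
  expect_error(compare_groups(feats, pairs = list(c("ADULT", "TD"))),
               "missing group")
  # subject-level aggregation drops to one row per subject
  gs3 <- compare_groups(feats, pairs = list(c("TD", "ASD")), unit = "subject")
  expect_equal(nrow(gs3), 12)
})

test_that("label-permuted cohorts reject at the nominal rate", {
  coh <- simulate_cohort(sim_config(n_subjects = c(TD = 15, ASD = 26), seed = 17))
  feats <- suppressMessages(extract_features_set(coh))
  set.seed(19)
  rejected <- replicate(60, {
    perm <- feats
    # permute group labels at the subject level to respect exchangeability
    subs <- unique(perm$subject_id)
    newg <- sample(vapply(subs, function(s) perm$group[match(s, perm$subject_id)], ""))
    perm$group <- newg[match(perm$subject_id, subs)]
    gs <- compare_groups(perm, pairs = list(c("TD", "ASD")), unit = "subject")
    sum(gs$p_value < 0.05)
  })
  expect_lt(mean(rejected), 2.5)   # ~ 12 * 0.05 = 0.6 expected, allow slack
})

test_that("correlation tables carry r, p and per-family FDR flags", {
  coh <- simulate_cohort(sim_config(n_subjects = c(TD = 10, ASD = 12), seed = 23))
  feats <- suppressMessages(extract_features_set(coh))
  sc <- simulate_adaptive_scores(coh, noise_sd = 4, seed = 5)
  ct <- correlate_features(feats, sc)
  expect_s3_class(ct, "reachkin_cortable")
  expect_equal(sort(unique(ct$covariate)),
               sort(c("communication", "daily_living", "socialization")))
  expect_true(all(abs(ct$r) <= 1))
  # flagged cells have p below the family BH threshold by construction
  for (g in unique(ct$group)) for (cv in unique(ct$covariate)) {
    fam <- ct[ct$group == g & ct$covariate == cv, ]
    expect_identical(fam$fdr_flag, fdr_bh(fam$p_value, 0.05))
  }
  md <- capture.output(format_cortable(ct))
  expect_true(any(grepl("reaction_time_s", md)))
})
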