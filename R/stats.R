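# Nonparametric group statistics, correlations and FDR control.
#
# The Mann-Whitney U, Brown-Forsythe Levene and Pearson tests are written
# out explicitly (rank sums with midranks, exact enumeration for small
# tie-free samples, normal approximation with tie and continuity correction
# otherwise); unit tests compare them against the corresponding stats::
# implementations as independent oracles.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed from rank sums with midranks for ties and reported for the
#' first sample (U_a). For tie-free data with n_a + n_b <= 12 the two-sided
#' p-value is obtained by exact enumeration of all rank assignments;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. If every value is identical across both samples the
#' test is degenerate and p = 1.
#'
#' @param a,b Numeric samples (each length >= 1).
#' @param feature Optional label carried into the result.
#' @return One-row data frame: feature, test, statistic (U_a), p_value,
#'   median_a, median_b, direction ("a>b", "a<b" or "none"), method,
#'   degenerate.
#' @export
mann_whitney_u <- function(a, b, feature = NA_character_) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  x <- c(a, b)
  r <- rank(x)                       # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(x)
  has_ties <- any(ties > 1)
  degenerate <- length(ties) == 1L
  if (degenerate) {
    p <- 1
    method <- "degenerate"
  } else if (!has_ties && N <= 12) {
    # exact: U is distribution-free; enumerate all C(N, na) rank subsets
    combos <- utils::combn(N, na)
    u_all <- colSums(matrix(rank(x)[combos], nrow = na)) - na * (na + 1) / 2
    p <- min(1, 2 * min(mean(u_all <= U), mean(u_all >= U)))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- na * nb / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1; method <- "degenerate"; degenerate <- TRUE
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
      p <- min(1, p)
      method <- "normal_approx"
    }
  }
  ma <- stats::median(a); mb <- stats::median(b)
  data.frame(feature = feature, test = "mann_whitney_u", statistic = U,
             p_value = p, median_a = ma, median_b = mb,
             direction = if (ma > mb) "a>b" else if (ma < mb) "a<b" else "none",
             method = method, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Levene's test for homogeneity of variance (Brown-Forsythe variant)
#'
#' One-way ANOVA on absolute deviations from the group medians.
#'
#' @param a,b Numeric samples (each length >= 3).
#' @param feature Optional label.
#' @return One-row data frame with statistic (W), p_value and degenerate
#'   flag (zero spread in the deviations).
#' @export
levene_test <- function(a, b, feature = NA_character_) {
  if (length(a) < 3 || length(b) < 3) stopf("each sample needs >= 3 values")
  za <- abs(a - stats::median(a)); zb <- abs(b - stats::median(b))
  N <- length(za) + length(zb); k <- 2
  zbar <- mean(c(za, zb))
  between <- length(za) * (mean(za) - zbar)^2 + length(zb) * (mean(zb) - zbar)^2
  within <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  if (within == 0) {
    W <- 0; p <- 1; degenerate <- TRUE
  } else {
    W <- (N - k) / (k - 1) * between / within
    p <- stats::pf(W, k - 1, N - k, lower.tail = FALSE)
    degenerate <- FALSE
  }
  data.frame(feature = feature, test = "levene_brown_forsythe", statistic = W,
             p_value = p, median_a = stats::median(a), median_b = stats::median(b),
             direction = NA_character_, method = "anova_abs_dev_median",
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' One-sample Kolmogorov-Smirnov test against a fitted normal
#'
#' Tests the sample against a normal distribution with the sample mean and
#' SD, using the asymptotic p-value. (With estimated parameters this is the
#' anti-conservative textbook version, matching common practice in applied
#' reports; it is used descriptively, as an assumption check.)
#'
#' @param sample Numeric vector (length >= 3).
#' @param feature Optional label.
#' @return One-row data frame with statistic (D) and p_value.
#' @export
ks_test <- function(sample, feature = NA_character_) {
  if (length(sample) < 3) stopf("sample needs >= 3 values")
  s <- stats::sd(sample)
  if (s == 0) {
    return(data.frame(feature = feature, test = "ks_normal", statistic = 0,
                      p_value = 1, median_a = stats::median(sample),
                      median_b = NA_real_, direction = NA_character_,
                      method = "degenerate", degenerate = TRUE,
                      stringsAsFactors = FALSE))
  }
  kt <- suppressWarnings(stats::ks.test(sample, "pnorm", mean(sample), s,
                                        exact = FALSE))
  data.frame(feature = feature, test = "ks_normal",
             statistic = unname(kt$statistic), p_value = kt$p.value,
             median_a = stats::median(sample), median_b = NA_real_,
             direction = NA_character_, method = "asymptotic",
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, both non-constant.
#' @param feature Optional label.
#' @return One-row data frame with statistic (r) and two-sided p_value from
#'   the t distribution with n - 2 degrees of freedom.
#' @export
pearson_r <- function(x, y, feature = NA_character_) {
  n <- length(x)
  if (n < 3 || length(y) != n) stopf("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("undefined correlation: constant input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  data.frame(feature = feature, test = "pearson", statistic = r, p_value = p,
             median_a = NA_real_, median_b = NA_real_,
             direction = if (r > 0) "positive" else if (r < 0) "negative" else "none",
             method = "t_distribution", degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR flags
#'
#' Rejects all hypotheses with p <= p_(k*), k* = max{k : p_(k) <= k q / m}.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @param q Target false discovery rate (default 0.05).
#' @return Logical vector of rejection flags, same order as the input.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  if (!m) return(logical(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  flags <- logical(m)
  if (length(ok)) flags[ord[seq_len(max(ok))]] <- TRUE
  flags[is.na(p_values)] <- NA
  flags
}

#' Between-group comparisons for every kinematic feature
#'
#' One two-sided Mann-Whitney U test per feature per requested group pair,
#' with Levene (homogeneity) and KS (normality) assumption checks attached.
#' The unit of analysis is either the trial (default, matching a pooled
#' trial-level design) or the subject mean.
#'
#' @param features Feature table from \code{\link{extract_features_set}}.
#' @param pairs List of length-2 character vectors of group labels; default
#'   ADULT vs TD and TD vs ASD (skipping pairs whose groups are absent only
#'   if other pairs remain).
#' @param unit \code{"trial"} or \code{"subject"}.
#' @param feature_names Features to compare (default all twelve).
#' @return Data frame, one row per feature x pair, with test results and
#'   assumption-check p-values.
#' @export
compare_groups <- function(features,
                           pairs = list(c("ADULT", "TD"), c("TD", "ASD")),
                           unit = c("trial", "subject"),
                           feature_names = kinematic_feature_names()) {
  unit <- match.arg(unit)
  if (unit == "subject") {
    agg <- stats::aggregate(features[feature_names],
                            by = features[c("subject_id", "group")], FUN = mean)
    features <- agg
  }
  present <- unique(features$group)
  rows <- list()
  for (pair in pairs) {
    missing <- setdiff(pair, present)
    if (length(missing))
      stopf("missing group '%s' for comparison %s vs %s",
            missing[1], pair[1], pair[2])
    fa <- features[features$group == pair[1], , drop = FALSE]
    fb <- features[features$group == pair[2], , drop = FALSE]
    if (nrow(fa) < 2 || nrow(fb) < 2)
      stopf("need >= 2 observations per group for %s vs %s", pair[1], pair[2])
    for (f in feature_names) {
      mw <- mann_whitney_u(fa[[f]], fb[[f]], feature = f)
      lv <- levene_test(fa[[f]], fb[[f]])
      ks <- ks_test(c(fa[[f]], fb[[f]]))
      mw$comparison <- paste(pair[1], "vs", pair[2])
      mw$group_a <- pair[1]; mw$group_b <- pair[2]
      mw$levene_p <- lv$p_value
      mw$ks_normal_p <- ks$p_value
      mw$unit <- unit
      rows[[length(rows) + 1L]] <- mw
    }
  }
  do.call(rbind, rows)
}

#' Correlation table of kinematic features against adaptive-functioning
#' scores
#'
#' Pearson correlations between trial-level kinematics and per-subject
#' covariate scores broadcast to the subject's trials (default, giving the
#' larger pooled n), or between subject-mean kinematics and scores. FDR
#' flags are computed by Benjamini-Hochberg within each covariate x group
#' column family.
#'
#' @param features Feature table from \code{\link{extract_features_set}}.
#' @param scores Per-subject score table from
#'   \code{\link{simulate_adaptive_scores}} (subject_id, group and one
#'   column per covariate).
#' @param covariates Score column names (default communication,
#'   daily_living, socialization).
#' @param groups Groups to correlate within (default TD and ASD).
#' @param unit \code{"trial"} (broadcast scores) or \code{"subject"}.
#' @param q FDR level (default 0.05).
#' @return Data frame of class \code{reachkin_cortable}: feature, group,
#'   covariate, r, p_value, n, fdr_flag.
#' @export
correlate_features <- function(features, scores,
                               covariates = c("communication", "daily_living",
                                              "socialization"),
                               groups = c("TD", "ASD"),
                               unit = c("trial", "subject"), q = 0.05) {
  unit <- match.arg(unit)
  feature_names <- intersect(kinematic_feature_names(), names(features))
  if (unit == "subject") {
    features <- stats::aggregate(features[feature_names],
                                 by = features[c("subject_id", "group")],
                                 FUN = mean)
  }
  merged <- merge(features, scores[, c("subject_id", covariates)],
                  by = "subject_id")
  rows <- list()
  for (g in groups) {
    sub <- merged[merged$group == g, , drop = FALSE]
    for (cv in covariates) {
      fam <- list()
      for (f in feature_names) {
        pr <- tryCatch(pearson_r(sub[[f]], sub[[cv]], feature = f),
                       error = function(e) NULL)
        if (is.null(pr)) next
        fam[[length(fam) + 1L]] <- data.frame(
          feature = f, group = g, covariate = cv, r = pr$statistic,
          p_value = pr$p_value, n = nrow(sub), stringsAsFactors = FALSE)
      }
      fam <- do.call(rbind, fam)
      fam$fdr_flag <- fdr_bh(fam$p_value, q)
      rows[[length(rows) + 1L]] <- fam
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("reachkin_cortable", class(out))
  out
}

#' Render a correlation table as Markdown
#'
#' Features as rows, covariate x group columns; significance stars
#' (* p < 0.05, ** p < 0.001) and a trailing "(F)" where the p-value
#' survived FDR correction.
#'
#' @param x A \code{\link{correlate_features}} result.
#' @param ... Unused.
#' @return Character vector of Markdown lines, invisibly; printed to the
#'   console.
#' @export
format_cortable <- function(x, ...) {
  cols <- unique(x[, c("group", "covariate")])
  feats <- unique(x$feature)
  header <- c("feature", paste(cols$group, cols$covariate, sep = "."))
  lines <- c(paste("|", paste(header, collapse = " | "), "|"),
             paste("|", paste(rep("---", length(header)), collapse = " | "), "|"))
  for (f in feats) {
    cells <- vapply(seq_len(nrow(cols)), function(i) {
      row <- x[x$feature == f & x$group == cols$group[i] &
                 x$covariate == cols$covariate[i], ]
      if (!nrow(row)) return("")
      stars <- if (row$p_value < 0.001) "**" else if (row$p_value < 0.05) "*" else ""
      sprintf("%.3f%s%s", row$r, stars, if (isTRUE(row$fdr_flag)) " (F)" else "")
    }, "")
    lines <- c(lines, paste("|", paste(c(f, cells), collapse = " | "), "|"))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
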