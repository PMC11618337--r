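# Classification protocol: feature selection, min-max normalization,
# stratified ten-fold cross-validation and permutation feature importance.

#' The nine parameters used for classification
#'
#' The subset of the twelve kinematic parameters showing significant or
#' borderline-significant child-group differences: reaction time, total
#' distance, average/maximum velocity, time to peak velocity,
#' average/maximum acceleration, time to peak acceleration and Type-2
#' movement units.
#'
#' @return Character vector of length 9.
#' @export
selected_feature_names <- function() {
  c("reaction_time_s", "total_distance_m", "avg_velocity_mps",
    "max_velocity_mps", "time_to_peak_velocity_s", "avg_acceleration_mps2",
    "max_acceleration_mps2", "time_to_peak_acceleration_s", "mu_type2_rms")
}

#' Build a labelled feature matrix for classification
#'
#' @param features Feature table from \code{\link{extract_features_set}}.
#' @param groups Length-2 character vector; the first maps to label 0, the
#'   second to label 1 (default TD = 0, ASD = 1).
#' @param feature_names Columns to use (default the nine selected
#'   parameters).
#' @return List of class \code{reachkin_fm}: \code{X} (matrix), \code{y}
#'   (0/1), \code{subject_id}, \code{feature_names}, \code{groups}.
#' @export
feature_matrix <- function(features, groups = c("TD", "ASD"),
                           feature_names = selected_feature_names()) {
  if (length(groups) != 2) stopf("groups must name exactly two classes")
  sub <- features[features$group %in% groups, , drop = FALSE]
  if (!nrow(sub)) stopf("no rows for groups %s", paste(groups, collapse = ", "))
  X <- as.matrix(sub[, feature_names, drop = FALSE])
  if (!all(is.finite(X))) stopf("feature matrix contains non-finite values")
  structure(list(X = X, y = as.integer(sub$group == groups[2]),
                 subject_id = sub$subject_id, feature_names = feature_names,
                 groups = groups),
            class = "reachkin_fm")
}

#' Min-max normalization to [0, 1] per column
#'
#' Computed over the entire matrix by default, matching the stated
#' whole-dataset protocol (a mild information leak across CV folds;
#' \code{\link{cross_validate}} offers a per-training-fold variant).
#' Constant columns map to zeros with a warning.
#'
#' @param matrix Numeric matrix, >= 2 rows, all finite.
#' @param ranges Optional list with \code{min} and \code{max} per column
#'   (e.g. from a training fold) to apply instead of the matrix's own.
#' @return Normalized matrix with a \code{"ranges"} attribute.
#' @export
minmax_normalize <- function(matrix, ranges = NULL) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stopf("need at least 2 rows")
  if (!all(is.finite(matrix))) stopf("non-finite input")
  if (is.null(ranges)) {
    ranges <- list(min = apply(matrix, 2, min), max = apply(matrix, 2, max))
  }
  span <- ranges$max - ranges$min
  const <- span == 0
  if (any(const)) {
    warnf("constant column(s) mapped to zeros: %s",
          paste(which(const), collapse = ", "))
    span[const] <- 1
  }
  out <- sweep(sweep(matrix, 2, ranges$min), 2, span, "/")
  out[, const] <- 0
  attr(out, "ranges") <- ranges
  out
}

#' Stratified k-fold assignment
#'
#' Trial-level grouping stratifies rows by class; subject-level grouping
#' assigns whole subjects to folds (stratified by the subject's class) so no
#' subject contributes to both a training and validation split.
#'
#' @param y 0/1 labels.
#' @param k Number of folds.
#' @param subject_id Optional subject ids for subject-level grouping.
#' @param seed Integer seed.
#' @return Integer fold id per row (1..k); the realized k is in the
#'   \code{"k"} attribute (reduced with a warning if there are fewer
#'   subjects than folds).
#' @export
make_folds <- function(y, k = 10, subject_id = NULL, seed = 1) {
  with_seed(seed, {
    n <- length(y)
    fold <- integer(n)
    if (is.null(subject_id)) {
      if (n < k) stopf("need at least k observations")
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(sample.int(k), length(idx))
      }
    } else {
      subs <- unique(subject_id)
      if (length(subs) < k) {
        k_new <- length(subs)
        warnf("only %d subjects; reducing folds from %d to %d",
              k_new, k, k_new)
        k <- k_new
      }
      scls <- vapply(subs, function(s) y[match(s, subject_id)], numeric(1))
      sfold <- integer(length(subs))
      for (cls in unique(scls)) {
        idx <- sample(which(scls == cls))
        sfold[idx] <- rep_len(sample.int(k), length(idx))
      }
      fold <- sfold[match(subject_id, subs)]
    }
    attr(fold, "k") <- k
    fold
  })
}

#' Stratified k-fold cross-validation of the MLP
#'
#' Trains one model per fold and reports validation accuracy at the 0.5
#' sigmoid threshold, per-fold best validation loss, and per-class
#' sensitivity/specificity (raw accuracy is optimistic under class
#' imbalance). Trial-level grouping reproduces the pooled-trials protocol;
#' subject-level grouping prevents same-subject leakage between folds.
#'
#' @param X Feature matrix (unnormalized).
#' @param y 0/1 labels.
#' @param spec A \code{\link{mlp_spec}}.
#' @param k Folds (default 10).
#' @param grouping \code{"trial"} (default) or \code{"subject"}.
#' @param subject_id Required for subject grouping.
#' @param normalize \code{"global"} (whole-dataset min-max, the stated
#'   protocol) or \code{"fold"} (ranges fit on each training fold).
#' @param seed Integer seed.
#' @param keep_models Keep per-fold models for importance analysis
#'   (default TRUE).
#' @return Object of class \code{reachkin_cv}: fold accuracies, mean
#'   accuracy, sensitivity, specificity, per-fold best validation losses,
#'   fold assignment, models and seed.
#' @export
cross_validate <- function(X, y, spec = mlp_spec(), k = 10,
                           grouping = c("trial", "subject"),
                           subject_id = NULL,
                           normalize = c("global", "fold"), seed = 1,
                           keep_models = TRUE) {
  grouping <- match.arg(grouping)
  normalize <- match.arg(normalize)
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < k) stopf("need at least k observations")
  if (grouping == "subject" && is.null(subject_id))
    stopf("subject grouping requires subject_id")
  fold <- make_folds(y, k, if (grouping == "subject") subject_id else NULL,
                     seed = seed)
  k <- attr(fold, "k")
  if (normalize == "global") Xg <- minmax_normalize(X)
  acc <- val_loss <- numeric(k)
  sens <- spec_ <- numeric(k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; va <- fold == f
    if (normalize == "global") {
      Xtr <- Xg[tr, , drop = FALSE]; Xva <- Xg[va, , drop = FALSE]
    } else {
      Xtr <- minmax_normalize(X[tr, , drop = FALSE])
      Xva <- minmax_normalize(X[va, , drop = FALSE],
                              ranges = attr(Xtr, "ranges"))
      Xva <- pmin(pmax(Xva, 0), 1)
    }
    model <- train_mlp(Xtr, y[tr], Xva, y[va], spec, seed = seed + f)
    pred <- as.integer(predict(model, Xva) > 0.5)
    yv <- y[va]
    acc[f] <- mean(pred == yv)
    sens[f] <- if (any(yv == 1)) mean(pred[yv == 1] == 1) else NA_real_
    spec_[f] <- if (any(yv == 0)) mean(pred[yv == 0] == 0) else NA_real_
    val_loss[f] <- model$best_val_loss
    if (keep_models) models[[f]] <- model
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc),
                 sensitivity = sens, specificity = spec_,
                 best_val_loss = val_loss, fold = as.integer(fold), k = k,
                 grouping = grouping, normalize = normalize, seed = seed,
                 models = if (keep_models) models else NULL,
                 X = if (keep_models) X else NULL,
                 y = if (keep_models) y else NULL),
            class = "reachkin_cv")
}

#' @export
print.reachkin_cv <- function(x, ...) {
  cat(sprintf("<reachkin_cv> %d-fold (%s-level, %s normalization): mean accuracy %.3f (folds %s)\n",
              x$k, x$grouping, x$normalize, x$mean_accuracy,
              paste(sprintf("%.2f", x$fold_accuracy), collapse = " ")))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, mean best val loss %.4f\n",
              mean(x$sensitivity, na.rm = TRUE),
              mean(x$specificity, na.rm = TRUE), mean(x$best_val_loss)))
  invisible(x)
}

#' Permutation feature importance for one trained model
#'
#' Each feature column of the validation set is shuffled
#' \code{n_repeats} times; importance is the mean permuted validation loss
#' minus the recorded best validation loss. Constant columns shuffle to
#' themselves and score (near) zero.
#'
#' @param model A \code{\link{train_mlp}} result.
#' @param X_val,y_val Validation split the model was selected on.
#' @param n_repeats Independent shuffles per feature (default 20).
#' @param seed Integer seed.
#' @return Data frame of class \code{reachkin_importance}: feature,
#'   delta_loss, rank (1 = most important).
#' @export
permutation_importance <- function(model, X_val, y_val, n_repeats = 20,
                                   seed = 1) {
  X_val <- as.matrix(X_val)
  base <- model$best_val_loss
  with_seed(seed, {
    delta <- vapply(seq_len(ncol(X_val)), function(j) {
      losses <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X_val
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        bce_loss(predict(model, Xp), y_val)
      }, numeric(1))
      mean(losses) - base
    }, numeric(1))
    nm <- colnames(X_val)
    if (is.null(nm)) nm <- paste0("feature_", seq_len(ncol(X_val)))
    out <- data.frame(feature = nm, delta_loss = delta,
                      rank = rank(-delta, ties.method = "first"),
                      stringsAsFactors = FALSE)
    class(out) <- c("reachkin_importance", class(out))
    out
  })
}

#' Permutation importance aggregated over cross-validation folds
#'
#' Applies \code{\link{permutation_importance}} to each fold's model and
#' validation split and averages the loss deltas across folds.
#'
#' @param cv A \code{\link{cross_validate}} result with kept models.
#' @param n_repeats Shuffles per feature per fold (default 20).
#' @param seed Integer seed.
#' @return Data frame of class \code{reachkin_importance}.
#' @export
cv_permutation_importance <- function(cv, n_repeats = 20, seed = 1) {
  stopifnot(inherits(cv, "reachkin_cv"))
  if (is.null(cv$models)) stopf("cross_validate was run with keep_models = FALSE")
  Xn <- if (cv$normalize == "global") minmax_normalize(cv$X) else NULL
  per_fold <- lapply(seq_len(cv$k), function(f) {
    va <- cv$fold == f
    Xva <- if (!is.null(Xn)) {
      Xn[va, , drop = FALSE]
    } else {
      tr <- minmax_normalize(cv$X[cv$fold != f, , drop = FALSE])
      pmin(pmax(minmax_normalize(cv$X[va, , drop = FALSE],
                                 ranges = attr(tr, "ranges")), 0), 1)
    }
    permutation_importance(cv$models[[f]], Xva, cv$y[va], n_repeats,
                           seed = seed + f)$delta_loss
  })
  delta <- Reduce(`+`, per_fold) / cv$k
  nm <- colnames(cv$X)
  if (is.null(nm)) nm <- paste0("feature_", seq_len(ncol(cv$X)))
  out <- data.frame(feature = nm, delta_loss = delta,
                    rank = rank(-delta, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("reachkin_importance", class(out))
  out
}
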