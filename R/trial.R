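# Trial containers and delimited-text I/O.

GROUP_LEVELS <- c("ADULT", "TD", "ASD")

#' Construct a single reach-and-place trial
#'
#' A trial is one recording of 3-axis wrist displacement for one subject,
#' together with the sample index of the go signal. Displacement is stored in
#' meters; the go signal index is zero-based (0 = first sample), matching the
#' \code{sample_index} convention of the long-format CSV files.
#'
#' @param subject_id Character scalar.
#' @param group One of \code{"ADULT"}, \code{"TD"}, \code{"ASD"}.
#' @param trial_index Integer >= 1.
#' @param displacement Numeric matrix with columns x, y, z (meters), at least
#'   10 rows, all values finite.
#' @param sampling_rate_hz Positive sampling rate, default 100.
#' @param go_signal_index Zero-based sample index of the go signal; must be
#'   smaller than the number of samples.
#' @return An object of class \code{reachkin_trial}.
#' @export
trial <- function(subject_id, group, trial_index, displacement,
                  sampling_rate_hz = 100, go_signal_index = 0) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stopf("subject_id must be a non-empty string")
  group <- as.character(group)
  if (!group %in% GROUP_LEVELS)
    stopf("unknown group label '%s' (expected one of %s)",
          group, paste(GROUP_LEVELS, collapse = ", "))
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L)
    stopf("trial_index must be an integer >= 1")
  displacement <- as.matrix(displacement)
  if (ncol(displacement) != 3L)
    stopf("displacement must have 3 columns (x, y, z)")
  if (nrow(displacement) < 10L)
    stopf("displacement must have at least 10 samples (got %d)", nrow(displacement))
  if (!all(is.finite(displacement)))
    stopf("trial %s/%d contains non-finite displacement values",
          subject_id, trial_index)
  storage.mode(displacement) <- "double"
  colnames(displacement) <- c("x", "y", "z")
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0)
    stopf("sampling_rate_hz must be a positive number")
  go_signal_index <- as.integer(go_signal_index)
  if (is.na(go_signal_index) || go_signal_index < 0L ||
      go_signal_index >= nrow(displacement))
    stopf("go_signal_index must be in [0, n_samples) for trial %s/%d",
          subject_id, trial_index)
  structure(
    list(subject_id = subject_id, group = group, trial_index = trial_index,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         go_signal_index = go_signal_index,
         displacement = displacement),
    class = "reachkin_trial")
}

#' @export
print.reachkin_trial <- function(x, ...) {
  cat(sprintf("<reachkin_trial> %s (%s) trial %d: %d samples @ %g Hz, go @ %d\n",
              x$subject_id, x$group, x$trial_index, nrow(x$displacement),
              x$sampling_rate_hz, x$go_signal_index))
  invisible(x)
}

n_samples <- function(trial) nrow(trial$displacement)

#' Construct an ordered collection of trials
#'
#' Validates that (subject_id, trial_index) pairs are unique and that each
#' subject carries exactly one group label across all of its trials.
#'
#' @param trials List of \code{\link{trial}} objects.
#' @param provenance \code{"SYNTHETIC"} or \code{"FILE"}.
#' @param seed Optional integer recorded for reproducibility (synthetic sets).
#' @return An object of class \code{reachkin_trialset} (a list with elements
#'   \code{trials}, \code{provenance}, \code{seed}).
#' @export
trial_set <- function(trials, provenance = c("SYNTHETIC", "FILE"), seed = NULL) {
  provenance <- match.arg(provenance)
  if (!length(trials)) stopf("trial_set needs at least one trial")
  ok <- vapply(trials, inherits, logical(1), what = "reachkin_trial")
  if (!all(ok)) stopf("all elements must be reachkin_trial objects")
  key <- vapply(trials, function(t) paste(t$subject_id, t$trial_index), "")
  if (anyDuplicated(key))
    stopf("duplicate subject/trial pair: %s", key[duplicated(key)][1])
  subj <- vapply(trials, `[[`, "", "subject_id")
  grp <- vapply(trials, `[[`, "", "group")
  bad <- tapply(grp, subj, function(g) length(unique(g)) > 1L)
  if (any(bad))
    stopf("subject %s has more than one group label", names(bad)[bad][1])
  structure(list(trials = trials, provenance = provenance,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "reachkin_trialset")
}

#' @export
print.reachkin_trialset <- function(x, ...) {
  grp <- vapply(x$trials, `[[`, "", "group")
  cat(sprintf("<reachkin_trialset> %d trials (%s)\n", length(x$trials),
              paste(sprintf("%s: %d", names(table(grp)), table(grp)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.reachkin_trialset <- function(x) length(x$trials)

default_trial_schema <- function() {
  c(subject = "subject", group = "group", trial = "trial",
    sample_index = "sample_index", x = "x", y = "y", z = "z")
}

#' Read trials from a long-format CSV file
#'
#' The file must be comma-delimited with a header row and one row per sample:
#' columns subject, group, trial, sample_index, x, y, z (names remappable via
#' \code{schema}). Optional columns \code{sampling_rate_hz} and
#' \code{go_signal_index} (constant within a trial) are honoured; otherwise
#' defaults of 100 Hz and go at sample 0 are used.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping canonical names
#'   (\code{subject}, \code{group}, \code{trial}, \code{sample_index},
#'   \code{x}, \code{y}, \code{z}) to the column names used in the file.
#' @param units \code{"m"} (default) or \code{"mm"}; millimeter input is
#'   divided by 1000 on load.
#' @return A \code{\link{trial_set}} with provenance \code{"FILE"}.
#' @export
read_trials <- function(path, schema = default_trial_schema(), units = c("m", "mm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stopf("file not found: %s", path)
  full <- default_trial_schema()
  full[names(schema)] <- schema
  schema <- full
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(schema), names(df))
  if (length(missing))
    stopf("schema error: missing column(s) %s in %s",
          paste(missing, collapse = ", "), path)
  get <- function(canon) df[[schema[[canon]]]]
  sub <- as.character(get("subject"))
  grp <- as.character(get("group"))
  tri <- get("trial")
  idx <- get("sample_index")
  xyz <- cbind(get("x"), get("y"), get("z"))
  if (units == "mm") xyz <- xyz / 1000
  bad_grp <- setdiff(unique(grp), GROUP_LEVELS)
  if (length(bad_grp))
    stopf("validation error: unknown group label '%s'", bad_grp[1])
  keys <- paste(sub, tri, sep = "\r")
  trials <- lapply(split(seq_len(nrow(df)), factor(keys, levels = unique(keys))),
                   function(rows) {
    si <- idx[rows]
    if (any(!is.finite(si)) || any(diff(si) <= 0))
      stopf("malformed trial: non-finite or non-monotone sample_index for subject %s trial %s",
            sub[rows[1]], tri[rows[1]])
    disp <- xyz[rows, , drop = FALSE]
    if (any(!is.finite(disp)))
      stopf("malformed trial: non-finite displacement for subject %s trial %s",
            sub[rows[1]], tri[rows[1]])
    fs <- if ("sampling_rate_hz" %in% names(df)) df$sampling_rate_hz[rows[1]] else 100
    go <- if ("go_signal_index" %in% names(df)) df$go_signal_index[rows[1]] else 0
    trial(subject_id = sub[rows[1]], group = grp[rows[1]],
          trial_index = as.integer(tri[rows[1]]), displacement = disp,
          sampling_rate_hz = fs, go_signal_index = go)
  })
  names(trials) <- NULL
  meta_path <- paste0(path, ".meta.json")
  seed <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$seed)) seed <- as.integer(meta$seed)
  }
  trial_set(trials, provenance = "FILE", seed = seed)
}

#' Write a trial set to a long-format CSV file
#'
#' Writes one row per sample (subject, group, trial, sample_index, x, y, z,
#' sampling_rate_hz, go_signal_index) with 9-digit coordinate precision, plus
#' a JSON sidecar \code{<path>.meta.json} recording provenance and seed.
#'
#' @param trialset A \code{\link{trial_set}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_trials <- function(trialset, path) {
  stopifnot(inherits(trialset, "reachkin_trialset"))
  rows <- lapply(trialset$trials, function(t) {
    n <- n_samples(t)
    data.frame(subject = t$subject_id, group = t$group, trial = t$trial_index,
               sample_index = seq_len(n) - 1L,
               x = t$displacement[, 1], y = t$displacement[, 2],
               z = t$displacement[, 3],
               sampling_rate_hz = t$sampling_rate_hz,
               go_signal_index = t$go_signal_index)
  })
  df <- do.call(rbind, rows)
  for (col in c("x", "y", "z")) df[[col]] <- formatC(df[[col]], digits = 9, format = "f")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(provenance = trialset$provenance, seed = trialset$seed,
         n_trials = length(trialset$trials)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

FEATURE_COLUMNS <- c(
  "reaction_time_s", "movement_time_s", "total_distance_m",
  "avg_velocity_mps", "max_velocity_mps", "time_to_peak_velocity_s",
  "avg_acceleration_mps2", "max_acceleration_mps2",
  "time_to_peak_acceleration_s", "mu_type1_rms", "mu_type2_rms",
  "mu_type3_rms")

#' Names of the twelve kinematic parameters
#'
#' Fixed column order used by every feature table in the package.
#' @return Character vector of length 12.
#' @export
kinematic_feature_names <- function() FEATURE_COLUMNS

#' Write a kinematic feature table to CSV
#'
#' One row per trial; key columns \code{subject_id}, \code{group},
#' \code{trial_index} followed by the twelve feature columns in the fixed
#' order of \code{\link{kinematic_feature_names}}.
#'
#' @param features Data frame as returned by \code{\link{extract_features_set}}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_features <- function(features, path) {
  if (!is.data.frame(features) || !nrow(features))
    stopf("features table must be a non-empty data frame")
  keys <- c("subject_id", "group", "trial_index")
  missing <- setdiff(c(keys, FEATURE_COLUMNS), names(features))
  if (length(missing))
    stopf("features table is missing column(s): %s", paste(missing, collapse = ", "))
  out <- features[, c(keys, FEATURE_COLUMNS)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a kinematic feature table written by \code{\link{write_features}}
#' @param path CSV path.
#' @return Data frame with key and feature columns.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "group", "trial_index", FEATURE_COLUMNS),
                     names(df))
  if (length(missing))
    stopf("feature file is missing column(s): %s", paste(missing, collapse = ", "))
  df
}

#' Register a trial in a common reference frame
#'
#' Translates the trajectory so the first sample sits at the origin and
#' rotates it so the first principal axis of the centered trajectory maps to
#' +X, with the sign chosen so net displacement along it is non-negative.
#' The transform is rigid: all pairwise inter-sample distances are preserved,
#' so every rotation-invariant kinematic feature is unchanged. Per-axis
#' movement-unit counts (before RMS consolidation) do depend on this
#' convention; their RMS consolidation is reported downstream.
#'
#' @param trial A \code{\link{trial}}.
#' @return A trial with transformed displacement.
#' @export
to_common_frame <- function(trial) {
  stopifnot(inherits(trial, "reachkin_trial"))
  X <- trial$displacement
  X0 <- sweep(X, 2, X[1, ])
  steps <- sqrt(rowSums(diff(X0)^2))
  if (sum(steps) == 0) {
    warnf("degenerate trajectory (zero path length): translated only")
    trial$displacement <- X0
    return(trial)
  }
  C <- sweep(X0, 2, colMeans(X0))
  eg <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)
  E <- eg$vectors                       # columns ordered by decreasing variance
  net <- X0[nrow(X0), ] - X0[1, ]
  if (sum(net * E[, 1]) < 0) E[, 1] <- -E[, 1]
  # fix the second axis sign deterministically, then complete a right-handed set
  j <- which.max(abs(E[, 2]))
  if (E[j, 2] < 0) E[, 2] <- -E[, 2]
  E[, 3] <- c(E[2, 1] * E[3, 2] - E[3, 1] * E[2, 2],
              E[3, 1] * E[1, 2] - E[1, 1] * E[3, 2],
              E[1, 1] * E[2, 2] - E[2, 1] * E[1, 2])
  Y <- X0 %*% E
  colnames(Y) <- c("x", "y", "z")
  trial$displacement <- Y
  trial
}
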