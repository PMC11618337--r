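# Pipeline driver: simulate -> extract -> stats -> classify -> report,
# with CSV/JSON artifacts at every stage boundary so runs are resumable and
# interoperable, plus a manifest recording seed and config hash.

#' Assemble a run configuration
#'
#' @param seed Integer master seed; every stage derives its randomness from
#'   it, so a run is reproducible from config + seed alone.
#' @param sim A \code{\link{sim_config}} (its seed is overridden by
#'   \code{seed}).
#' @param kinematics A \code{\link{kinematic_options}}.
#' @param classifier_spec A \code{\link{mlp_spec}}.
#' @param cv_k Folds for cross-validation (default 10).
#' @param cv_grouping \code{"trial"} or \code{"subject"}.
#' @param classify_groups Two group labels for classification (default
#'   TD vs ASD).
#' @param score_noise_sd Residual SD of simulated adaptive scores.
#' @return List of class \code{reachkin_run_config}.
#' @export
run_config <- function(seed = 1, sim = sim_config(seed = seed),
                       kinematics = kinematic_options(),
                       classifier_spec = mlp_spec(), cv_k = 10,
                       cv_grouping = c("trial", "subject"),
                       classify_groups = c("TD", "ASD"),
                       score_noise_sd = 8) {
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), sim = sim, kinematics = kinematics,
                 classifier_spec = classifier_spec, cv_k = cv_k,
                 cv_grouping = match.arg(cv_grouping),
                 classify_groups = classify_groups,
                 score_noise_sd = score_noise_sd),
            class = "reachkin_run_config")
}

#' Read a run configuration from a JSON file
#'
#' Recognized top-level keys: \code{seed}, \code{sim} (n_subjects,
#' trials_per_subject, sampling_rate_hz, dropout_rate), \code{kinematics}
#' (cutoff_hz, filter_order, smoothing, threshold_fraction,
#' hysteresis_fraction, end_rule, onset_refine), \code{classifier} (hidden,
#' epochs, batch_size, learning rates), \code{cv_k}, \code{cv_grouping},
#' \code{classify_groups}, \code{score_noise_sd}. Missing keys fall back to
#' package defaults.
#'
#' @param path JSON file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (!is.null(j$seed)) j$seed else 1
  sim_args <- list(seed = seed)
  if (!is.null(j$sim)) {
    for (f in c("trials_per_subject", "sampling_rate_hz", "dropout_rate"))
      if (!is.null(j$sim[[f]])) sim_args[[f]] <- j$sim[[f]]
    if (!is.null(j$sim$n_subjects))
      sim_args$n_subjects <- unlist(j$sim$n_subjects)
  }
  sim <- do.call(sim_config, sim_args)
  kin_args <- list()
  if (!is.null(j$kinematics)) {
    kj <- j$kinematics
    sm <- filter_spec(
      type = if (!is.null(kj$smoothing)) kj$smoothing else "butterworth",
      cutoff_hz = if (!is.null(kj$cutoff_hz)) kj$cutoff_hz else 10,
      order = if (!is.null(kj$filter_order)) kj$filter_order else 4)
    kin_args$smoothing <- sm
    for (f in c("threshold_fraction", "hysteresis_fraction", "end_rule",
                "onset_refine"))
      if (!is.null(kj[[f]])) kin_args[[f]] <- kj[[f]]
  }
  kin <- do.call(kinematic_options, kin_args)
  cls_args <- list()
  if (!is.null(j$classifier)) {
    for (f in c("hidden", "epochs", "batch_size", "lr_initial", "lr_reduced",
                "lr_switch_train_accuracy", "leaky_slope"))
      if (!is.null(j$classifier[[f]])) cls_args[[f]] <- j$classifier[[f]]
  }
  spec <- do.call(mlp_spec, cls_args)
  run_config(seed = seed, sim = sim, kinematics = kin, classifier_spec = spec,
             cv_k = if (!is.null(j$cv_k)) j$cv_k else 10,
             cv_grouping = if (!is.null(j$cv_grouping)) j$cv_grouping else "trial",
             classify_groups = if (!is.null(j$classify_groups))
               unlist(j$classify_groups) else c("TD", "ASD"),
             score_noise_sd = if (!is.null(j$score_noise_sd))
               j$score_noise_sd else 8)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

artifact_paths <- function(out_dir) {
  list(trials = file.path(out_dir, "trials.csv"),
       truth = file.path(out_dir, "ground_truth.csv"),
       subjects = file.path(out_dir, "subjects.csv"),
       scores = file.path(out_dir, "adaptive_scores.csv"),
       features = file.path(out_dir, "features.csv"),
       stats = file.path(out_dir, "group_stats.csv"),
       correlations = file.path(out_dir, "correlations.csv"),
       cv = file.path(out_dir, "cv_results.json"),
       cv_csv = file.path(out_dir, "cv_results.csv"),
       importance = file.path(out_dir, "importance.csv"),
       report = file.path(out_dir, "report.md"),
       manifest = file.path(out_dir, "manifest.json"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order (\code{simulate}, \code{extract},
#' \code{stats}, \code{classify}, \code{report}), persisting each stage's
#' outputs under \code{out_dir} and reading upstream artifacts from there
#' when a stage is run on its own. A manifest records the package version,
#' seed and config hash.
#'
#' @param config A \code{\link{run_config}}.
#' @param stages Subset of the five stage names (default all).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of the executed
#'   stages.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "extract", "stats",
                                    "classify", "report"),
                         out_dir = "reachkin_run") {
  stopifnot(inherits(config, "reachkin_run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- artifact_paths(out_dir)
  res <- list()

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(config$sim)
    write_trials(cohort$trials, paths$trials)
    utils::write.csv(cohort$ground_truth, paths$truth, row.names = FALSE)
    utils::write.csv(cohort$subjects, paths$subjects, row.names = FALSE)
    scores <- simulate_adaptive_scores(cohort, noise_sd = config$score_noise_sd,
                                       seed = config$seed + 1000L)
    utils::write.csv(scores, paths$scores, row.names = FALSE)
    stage_log("simulate", "seed %d: %d trials, %d subjects",
              config$seed, length(cohort$trials),
              nrow(cohort$subjects))
    res$cohort <- cohort
    res$scores <- scores
  }

  if ("extract" %in% stages) {
    trialset <- if (!is.null(res$cohort)) res$cohort$trials else {
      if (!file.exists(paths$trials))
        stopf("missing upstream artifact %s: run the 'simulate' stage first",
              paths$trials)
      read_trials(paths$trials)
    }
    features <- extract_features_set(trialset, config$kinematics)
    write_features(features, paths$features)
    stage_log("extract", "%d trials in, %d feature rows out, %d dropped",
              length(trialset), nrow(features),
              length(attr(features, "dropped")))
    res$features <- features
  }

  get_features <- function(for_stage) {
    if (!is.null(res$features)) return(res$features)
    if (!file.exists(paths$features))
      stopf("missing upstream artifact %s for stage '%s': run 'extract' first",
            paths$features, for_stage)
    read_features(paths$features)
  }

  if ("stats" %in% stages) {
    features <- get_features("stats")
    present <- unique(features$group)
    pairs <- Filter(function(p) all(p %in% present),
                    list(c("ADULT", "TD"), c("TD", "ASD")))
    if (!length(pairs)) stopf("no comparable group pair present")
    gs <- compare_groups(features, pairs = pairs)
    utils::write.csv(gs, paths$stats, row.names = FALSE)
    cors <- NULL
    scores <- if (!is.null(res$scores)) res$scores else if (file.exists(paths$scores))
      utils::read.csv(paths$scores) else NULL
    if (!is.null(scores)) {
      cors <- correlate_features(features, scores,
                                 groups = intersect(c("TD", "ASD"), present))
      utils::write.csv(cors, paths$correlations, row.names = FALSE)
    }
    stage_log("stats", "%d comparisons, %s correlation cells", nrow(gs),
              if (is.null(cors)) "no" else nrow(cors))
    res$group_stats <- gs
    res$correlations <- cors
  }

  if ("classify" %in% stages) {
    features <- get_features("classify")
    fm <- feature_matrix(features, groups = config$classify_groups)
    spec <- config$classifier_spec
    spec$input_dim <- ncol(fm$X)
    cv <- cross_validate(fm$X, fm$y, spec, k = config$cv_k,
                         grouping = config$cv_grouping,
                         subject_id = fm$subject_id, seed = config$seed)
    imp <- cv_permutation_importance(cv, seed = config$seed)
    cv_out <- list(k = cv$k, grouping = cv$grouping, normalize = cv$normalize,
                   fold_accuracy = cv$fold_accuracy,
                   mean_accuracy = cv$mean_accuracy,
                   sensitivity = cv$sensitivity, specificity = cv$specificity,
                   best_val_loss = cv$best_val_loss, seed = cv$seed)
    jsonlite::write_json(cv_out, paths$cv, auto_unbox = TRUE, digits = NA)
    utils::write.csv(data.frame(fold = seq_len(cv$k),
                                accuracy = cv$fold_accuracy,
                                best_val_loss = cv$best_val_loss),
                     paths$cv_csv, row.names = FALSE)
    utils::write.csv(imp, paths$importance, row.names = FALSE)
    stage_log("classify", "%d-fold CV mean accuracy %.3f; top feature %s",
              cv$k, cv$mean_accuracy, imp$feature[imp$rank == 1])
    res$cv <- cv
    res$importance <- imp
  }

  if ("report" %in% stages) {
    lines <- c("# reachkin run report", "",
               sprintf("- seed: %d", config$seed),
               sprintf("- generated: %s", format(Sys.time(), "%Y-%m-%d")), "")
    gs <- if (!is.null(res$group_stats)) res$group_stats else
      if (file.exists(paths$stats)) utils::read.csv(paths$stats) else NULL
    if (!is.null(gs)) {
      lines <- c(lines, "## Group comparisons (Mann-Whitney U)", "",
                 "| feature | comparison | U | p | direction |",
                 "| --- | --- | --- | --- | --- |",
                 sprintf("| %s | %s | %.1f | %.4g | %s |", gs$feature,
                         gs$comparison, gs$statistic, gs$p_value, gs$direction),
                 "")
    }
    if (file.exists(paths$correlations)) {
      ct <- utils::read.csv(paths$correlations)
      class(ct) <- c("reachkin_cortable", class(ct))
      md <- utils::capture.output(format_cortable(ct))
      lines <- c(lines, "## Correlations with adaptive functioning", "", md, "")
    }
    if (file.exists(paths$cv)) {
      cvj <- jsonlite::read_json(paths$cv, simplifyVector = TRUE)
      lines <- c(lines, "## Classification", "",
                 sprintf("- %d-fold CV (%s-level): mean accuracy %.3f",
                         cvj$k, cvj$grouping, cvj$mean_accuracy),
                 sprintf("- per-fold: %s",
                         paste(sprintf("%.2f", cvj$fold_accuracy), collapse = " ")),
                 "")
    }
    if (file.exists(paths$importance)) {
      imp <- utils::read.csv(paths$importance)
      imp <- imp[order(imp$rank), ]
      lines <- c(lines, "## Permutation feature importance", "",
                 "| rank | feature | delta loss |", "| --- | --- | --- |",
                 sprintf("| %d | %s | %.5f |", imp$rank, imp$feature,
                         imp$delta_loss), "")
    }
    writeLines(lines, paths$report)
    stage_log("report", "wrote %s", paths$report)
    res$report <- paths$report
  }

  manifest <- list(package = "reachkin",
                   version = as.character(utils::packageVersion("reachkin")),
                   seed = config$seed, stages = stages,
                   config_hash = config_hash(config),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(res)
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  # small stable FNV-1a style hash (31-bit); avoids a digest dependency
  h <- 216613626
  for (ch in utf8ToInt(s)) h <- (bitwXor(h, ch) * 16777619) %% 2147483647
  sprintf("%08x", h)
}

#' Command-line entry point
#'
#' Implements \code{reachkin <stage ...> [--config run.json] [--seed N]
#' [--out DIR]}, where stages are any of simulate, extract, stats,
#' classify, report (default all). Installed alongside the package as the
#' \code{exec/reachkin} script.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process's trailing arguments).
#' @return Invisibly, the \code{\link{run_pipeline}} result.
#' @export
reachkin_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- character()
  config_path <- NULL
  seed <- NULL
  out_dir <- "reachkin_run"
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--config") { config_path <- args[i + 1]; i <- i + 2 }
    else if (a == "--seed") { seed <- as.integer(args[i + 1]); i <- i + 2 }
    else if (a == "--out") { out_dir <- args[i + 1]; i <- i + 2 }
    else { stages <- c(stages, a); i <- i + 1 }
  }
  all_stages <- c("simulate", "extract", "stats", "classify", "report")
  if (!length(stages)) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage '%s' (expected %s)", bad[1],
                         paste(all_stages, collapse = "|"))
  config <- if (!is.null(config_path)) read_run_config(config_path) else run_config()
  if (!is.null(seed)) {
    config$seed <- seed
    config$sim$seed <- seed
  }
  invisible(run_pipeline(config, stages = stages, out_dir = out_dir))
}
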