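# Synthetic reach-and-place cohort generator.
#
# Each trial is composed from minimum-jerk building blocks: a quiescent
# pre-go baseline, a reaction-time delay, one primary reach (optionally
# time-warped so peak speed falls before or after the midpoint), an
# overshoot-and-return excursion, and a Poisson number of overlapping
# corrective submovements in perturbed directions. Additive white positional
# noise is applied last. Ground truth (true onset, submovement count,
# planned path length) is recorded for every trial so extraction can be
# validated without human data.

#' Group-level generative profile
#'
#' Describes the distribution of trial parameters for one participant group.
#' Trial-level draws use the stated means/SDs; \code{\link{simulate_cohort}}
#' additionally applies subject-level random effects on top.
#'
#' @param group \code{"ADULT"}, \code{"TD"} or \code{"ASD"}.
#' @param reaction_time_mean_s,reaction_time_sd_s Go-signal to movement-start
#'   delay (s).
#' @param movement_time_mean_s,movement_time_sd_s Primary reach duration (s).
#' @param reach_amplitude_mean_m,reach_amplitude_sd_m Primary reach amplitude
#'   (m).
#' @param overshoot_fraction_mean Extra out-and-back path length as a
#'   fraction of the amplitude (>= 0).
#' @param n_corrective_mean Poisson mean of corrective submovements per trial.
#' @param corrective_amp_fraction Corrective amplitude as a fraction of the
#'   reach amplitude.
#' @param time_to_peak_fraction Fraction of the primary movement time at
#'   which peak speed occurs, in (0, 1).
#' @param noise_sd_m SD of additive white positional noise (m).
#' @param corrective_duration_s Duration of one corrective submovement (s).
#' @param pre_go_s Quiescent baseline before the go signal (s).
#' @param tail_s Quiescent hold after the last submovement (s).
#' @return A list of class \code{reachkin_profile}.
#' @export
group_profile <- function(group, reaction_time_mean_s, reaction_time_sd_s,
                          movement_time_mean_s, movement_time_sd_s,
                          reach_amplitude_mean_m, reach_amplitude_sd_m,
                          overshoot_fraction_mean, n_corrective_mean,
                          corrective_amp_fraction, time_to_peak_fraction,
                          noise_sd_m, corrective_duration_s = 0.45,
                          pre_go_s = 0.5, tail_s = 0.25) {
  group <- match.arg(group, GROUP_LEVELS)
  p <- list(group = group,
            reaction_time_mean_s = reaction_time_mean_s,
            reaction_time_sd_s = reaction_time_sd_s,
            movement_time_mean_s = movement_time_mean_s,
            movement_time_sd_s = movement_time_sd_s,
            reach_amplitude_mean_m = reach_amplitude_mean_m,
            reach_amplitude_sd_m = reach_amplitude_sd_m,
            overshoot_fraction_mean = overshoot_fraction_mean,
            n_corrective_mean = n_corrective_mean,
            corrective_amp_fraction = corrective_amp_fraction,
            time_to_peak_fraction = time_to_peak_fraction,
            noise_sd_m = noise_sd_m,
            corrective_duration_s = corrective_duration_s,
            pre_go_s = pre_go_s, tail_s = tail_s)
  means <- c("reaction_time_mean_s", "movement_time_mean_s",
             "reach_amplitude_mean_m", "n_corrective_mean",
             "corrective_amp_fraction", "noise_sd_m")
  for (f in means) if (p[[f]] < 0) stopf("%s must be >= 0", f)
  if (p$reaction_time_mean_s <= 0 || p$movement_time_mean_s <= 0 ||
      p$reach_amplitude_mean_m <= 0)
    stopf("reaction time, movement time and amplitude means must be > 0")
  if (p$overshoot_fraction_mean < 0) stopf("overshoot_fraction_mean must be >= 0")
  for (f in c("reaction_time_sd_s", "movement_time_sd_s", "reach_amplitude_sd_m"))
    if (p[[f]] < 0) stopf("%s must be >= 0", f)
  if (p$time_to_peak_fraction <= 0 || p$time_to_peak_fraction >= 1)
    stopf("time_to_peak_fraction must lie in (0, 1)")
  structure(p, class = "reachkin_profile")
}

#' Default generative profiles for the three groups
#'
#' Effect directions, not any study's group means, are the calibration
#' targets: relative to TD children, the ASD profile has larger reach
#' amplitude and overshoot, more corrective submovements, a later speed peak
#' and a borderline-longer reaction time; adults reach farther and longer
#' but react faster and peak earlier.
#'
#' @return Named list of \code{\link{group_profile}} objects.
#' @export
default_profiles <- function() {
  list(
    ADULT = group_profile("ADULT",
      reaction_time_mean_s = 0.35, reaction_time_sd_s = 0.06,
      movement_time_mean_s = 2.0, movement_time_sd_s = 0.20,
      reach_amplitude_mean_m = 0.45, reach_amplitude_sd_m = 0.05,
      overshoot_fraction_mean = 0.04, n_corrective_mean = 0.6,
      corrective_amp_fraction = 0.06, time_to_peak_fraction = 0.30,
      noise_sd_m = 5e-6),
    TD = group_profile("TD",
      reaction_time_mean_s = 0.45, reaction_time_sd_s = 0.08,
      movement_time_mean_s = 1.6, movement_time_sd_s = 0.15,
      reach_amplitude_mean_m = 0.23, reach_amplitude_sd_m = 0.025,
      overshoot_fraction_mean = 0.06, n_corrective_mean = 1.0,
      corrective_amp_fraction = 0.06, time_to_peak_fraction = 0.42,
      noise_sd_m = 5e-6),
    ASD = group_profile("ASD",
      reaction_time_mean_s = 0.50, reaction_time_sd_s = 0.10,
      movement_time_mean_s = 1.7, movement_time_sd_s = 0.18,
      reach_amplitude_mean_m = 0.36, reach_amplitude_sd_m = 0.04,
      overshoot_fraction_mean = 0.20, n_corrective_mean = 4.0,
      corrective_amp_fraction = 0.12, time_to_peak_fraction = 0.50,
      noise_sd_m = 5e-6))
}

#' Simulation configuration
#'
#' @param n_subjects Named integer vector of subjects per group; default
#'   10 adults, 15 TD and 26 ASD children, which puts the child trial mix at
#'   156/246 (about 65\% ASD).
#' @param trials_per_subject Trials per subject (default 6).
#' @param sampling_rate_hz Sampling rate (default 100).
#' @param seed Integer seed; a fixed seed makes the cohort byte-identical.
#' @param profiles Named list of \code{\link{group_profile}}s covering every
#'   requested group.
#' @param dropout_rate Probability that a trial is dropped at random
#'   (default 0; the generator's world keeps all trials).
#' @return A list of class \code{reachkin_sim_config}.
#' @export
sim_config <- function(n_subjects = c(ADULT = 10, TD = 15, ASD = 26),
                       trials_per_subject = 6, sampling_rate_hz = 100,
                       seed = 1, profiles = default_profiles(),
                       dropout_rate = 0) {
  if (is.null(names(n_subjects)) || any(!nzchar(names(n_subjects))))
    stopf("n_subjects must be a named vector")
  bad <- setdiff(names(n_subjects), GROUP_LEVELS)
  if (length(bad)) stopf("unknown group in config: %s", bad[1])
  if (any(n_subjects < 1)) stopf("each requested group needs >= 1 subject")
  missing_prof <- setdiff(names(n_subjects), names(profiles))
  if (length(missing_prof))
    stopf("no profile supplied for group %s", missing_prof[1])
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must lie in [0, 1)")
  structure(list(n_subjects = n_subjects,
                 trials_per_subject = as.integer(trials_per_subject),
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed), profiles = profiles,
                 dropout_rate = dropout_rate),
            class = "reachkin_sim_config")
}

rtrunc_norm <- function(mean, sd, lo) max(lo, mean + sd * stats::rnorm(1))

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  while (sum(v^2) < 1e-12) v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Component of a random direction orthogonal to `d` (unit vectors).
random_perp <- function(d) {
  e <- stats::rnorm(3)
  e <- e - sum(e * d) * d
  n <- sqrt(sum(e^2))
  if (n < 1e-9) return(random_perp(d))
  e / n
}

#' Compose one synthetic trial from a group profile
#'
#' Draws trial parameters from the profile and superposes minimum-jerk
#' submovements (primary reach, overshoot-and-return, correctives) on a
#' quiescent baseline; adds white positional noise last. Uses the caller's
#' RNG state, so wrap in \code{set.seed()} for reproducibility.
#'
#' @param profile A \code{\link{group_profile}}.
#' @param sampling_rate_hz Sampling rate (default 100).
#' @param subject_id,trial_index Identification for the produced trial.
#' @return List with elements \code{trial} (a \code{\link{trial}}) and
#'   \code{truth} (one-row data frame: go index, true reach-start sample,
#'   true reaction/movement time, amplitude, corrective count, overshoot
#'   fraction and planned path length).
#' @export
compose_trial <- function(profile, sampling_rate_hz = 100,
                          subject_id = "S1", trial_index = 1L) {
  stopifnot(inherits(profile, "reachkin_profile"))
  fs <- sampling_rate_hz
  rt <- rtrunc_norm(profile$reaction_time_mean_s, profile$reaction_time_sd_s, 0.08)
  mt <- rtrunc_norm(profile$movement_time_mean_s, profile$movement_time_sd_s, 0.40)
  amp <- rtrunc_norm(profile$reach_amplitude_mean_m, profile$reach_amplitude_sd_m, 0.05)
  o <- if (profile$overshoot_fraction_mean > 0) {
    rtrunc_norm(profile$overshoot_fraction_mean,
                0.25 * profile$overshoot_fraction_mean, 0)
  } else 0
  k <- if (profile$n_corrective_mean > 0) stats::rpois(1, profile$n_corrective_mean) else 0L
  dir <- random_unit_vector()
  cd <- profile$corrective_duration_s

  # submovements: list of (start_s after reach start, displacement matrix)
  segs <- list(list(start = 0, P = min_jerk_segment(
    amp, mt, dir, fs, peak_fraction = profile$time_to_peak_fraction)))
  t_cursor <- mt
  if (o > 0) {
    half <- o * amp / 2            # out-and-back, extra path = o * amp
    segs <- c(segs, list(
      list(start = 0.97 * mt, P = min_jerk_segment(half, 0.35, dir, fs)),
      list(start = 0.97 * mt + 0.28, P = min_jerk_segment(half, 0.35, -dir, fs))))
    t_cursor <- 0.97 * mt + 0.28 + 0.35
  }
  corrective_path <- 0
  if (k > 0) {
    for (j in seq_len(k)) {
      ca <- profile$corrective_amp_fraction * amp * stats::runif(1, 0.7, 1.3)
      cdir <- (-1)^j * 0.8 * dir + 0.6 * random_perp(dir)
      cdir <- cdir / sqrt(sum(cdir^2))
      start <- t_cursor - 0.4 * cd + (j - 1) * 0.6 * cd
      segs <- c(segs, list(list(start = start, P = min_jerk_segment(ca, cd, cdir, fs))))
      corrective_path <- corrective_path + ca
    }
    t_cursor <- start + cd
  }

  total_s <- profile$pre_go_s + rt + t_cursor + profile$tail_s
  n <- round(total_s * fs) + 1L
  pos <- matrix(0, n, 3)
  reach_start0 <- round((profile$pre_go_s + rt) * fs)   # 0-based
  for (seg in segs) {
    s0 <- reach_start0 + round(seg$start * fs)          # 0-based
    P <- seg$P
    ni <- nrow(P)
    last <- pmin(s0 + ni, n)                            # 1-based end row
    if (s0 + 1 < last)
      pos[(s0 + 1):last, ] <- pos[(s0 + 1):last, ] + P[seq_len(last - s0), ]
    if (last < n)
      pos[(last + 1):n, ] <- sweep(pos[(last + 1):n, , drop = FALSE], 2, P[ni, ], "+")
  }
  if (profile$noise_sd_m > 0)
    pos <- pos + matrix(stats::rnorm(3 * n, 0, profile$noise_sd_m), n, 3)

  tr <- trial(subject_id = subject_id, group = profile$group,
              trial_index = trial_index, displacement = pos,
              sampling_rate_hz = fs,
              go_signal_index = round(profile$pre_go_s * fs))
  truth <- data.frame(
    subject_id = subject_id, group = profile$group, trial_index = trial_index,
    go_index = tr$go_signal_index, reach_start_index = reach_start0,
    reaction_time_s = rt, movement_time_s = mt, amplitude_m = amp,
    overshoot_fraction = o, n_corrective = k,
    path_length_m = amp + o * amp + corrective_path,
    time_to_peak_fraction = profile$time_to_peak_fraction)
  list(trial = tr, truth = truth)
}

# Subject-level random effects: multiplicative on timing/amplitude means,
# additive on the peak-time fraction. Returns the perturbed profile and the
# subject's latent parameters.
subject_profile <- function(profile) {
  p <- profile
  p$reaction_time_mean_s <- profile$reaction_time_mean_s * exp(stats::rnorm(1, 0, 0.10))
  p$movement_time_mean_s <- profile$movement_time_mean_s * exp(stats::rnorm(1, 0, 0.08))
  p$reach_amplitude_mean_m <- profile$reach_amplitude_mean_m * exp(stats::rnorm(1, 0, 0.10))
  p$n_corrective_mean <- profile$n_corrective_mean * exp(stats::rnorm(1, 0, 0.25))
  ttp <- profile$time_to_peak_fraction + stats::rnorm(1, 0, 0.03)
  p$time_to_peak_fraction <- min(0.95, max(0.05, ttp))
  p
}

#' Simulate a full cohort of reach-and-place trials
#'
#' Subject-level generative parameters are drawn once per subject (so trials
#' within a subject are correlated, reproducing the subject-leakage issue of
#' trial-level cross-validation), then each trial adds trial-level jitter.
#' Fully deterministic under the config seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List of class \code{reachkin_cohort}: \code{trials} (a
#'   \code{\link{trial_set}}), \code{ground_truth} (per-trial data frame) and
#'   \code{subjects} (per-subject latent parameters).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "reachkin_sim_config"))
  with_seed(config$seed, {
    trials <- list()
    truths <- list()
    subjects <- list()
    for (grp in names(config$n_subjects)) {
      prof <- config$profiles[[grp]]
      for (i in seq_len(config$n_subjects[[grp]])) {
        sid <- sprintf("%s%02d", grp, i)
        sp <- subject_profile(prof)
        subjects[[sid]] <- data.frame(
          subject_id = sid, group = grp,
          rt_mean_subject = sp$reaction_time_mean_s,
          mt_mean_subject = sp$movement_time_mean_s,
          amp_mean_subject = sp$reach_amplitude_mean_m,
          n_corrective_mean_subject = sp$n_corrective_mean,
          time_to_peak_subject = sp$time_to_peak_fraction)
        for (j in seq_len(config$trials_per_subject)) {
          if (config$dropout_rate > 0 && stats::runif(1) < config$dropout_rate) next
          ct <- compose_trial(sp, config$sampling_rate_hz, sid, j)
          trials[[length(trials) + 1L]] <- ct$trial
          truths[[length(truths) + 1L]] <- ct$truth
        }
      }
    }
    structure(list(
      trials = trial_set(trials, provenance = "SYNTHETIC", seed = config$seed),
      ground_truth = do.call(rbind, truths),
      subjects = do.call(rbind, c(subjects, list(make.row.names = FALSE)))),
      class = "reachkin_cohort")
  })
}

#' Default loadings linking latent kinematics to adaptive-functioning scores
#'
#' TD scores load negatively on the subject's latent movement time (slower
#' movers score lower on daily-living/socialization); ASD scores load
#' positively on latent reach amplitude.
#'
#' @return Named list with per-group \code{feature} and per-score loadings.
#' @export
default_score_loadings <- function() {
  list(
    TD = list(feature = "mt_mean_subject",
              loading = c(communication = -0.30, daily_living = -0.60,
                          socialization = -0.50)),
    ASD = list(feature = "amp_mean_subject",
               loading = c(communication = 0.50, daily_living = 0.15,
                           socialization = 0.50)))
}

#' Simulate per-subject adaptive-functioning scores
#'
#' Generates three standard scores (communication, daily living,
#' socialization) per child as linear functions of a latent kinematic
#' parameter plus Gaussian noise. Group intercepts are anchored near typical
#' standard-score levels (TD about 101, ASD about 79); loadings are applied
#' to the within-group z-score of the chosen latent feature with a 10-point
#' scale.
#'
#' @param cohort A \code{\link{simulate_cohort}} result.
#' @param loadings See \code{\link{default_score_loadings}}.
#' @param noise_sd Residual SD of each score (default 8; 0 gives exact
#'   linear dependence).
#' @param seed Optional seed.
#' @return Data frame: subject_id, group, communication, daily_living,
#'   socialization.
#' @export
simulate_adaptive_scores <- function(cohort, loadings = default_score_loadings(),
                                     noise_sd = 8, seed = NULL) {
  stopifnot(inherits(cohort, "reachkin_cohort"))
  base <- list(TD = c(communication = 103, daily_living = 101, socialization = 100),
               ASD = c(communication = 83, daily_living = 80, socialization = 73))
  with_seed(seed, {
    subs <- cohort$subjects[cohort$subjects$group %in% names(loadings), ]
    rows <- lapply(split(subs, subs$group), function(g) {
      grp <- g$group[1]
      ld <- loadings[[grp]]
      x <- g[[ld$feature]]
      z <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
      out <- data.frame(subject_id = g$subject_id, group = grp)
      for (sc in c("communication", "daily_living", "socialization")) {
        out[[sc]] <- base[[grp]][[sc]] + ld$loading[[sc]] * 10 * z +
          stats::rnorm(nrow(g), 0, noise_sd)
      }
      out
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
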