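# Extraction of the twelve kinematic parameters per trial.

#' Extraction options
#'
#' @param smoothing A \code{\link{filter_spec}} applied before
#'   differentiation.
#' @param threshold_fraction Onset thresholds as a fraction of the search
#'   window maxima of relative distance and acceleration magnitude
#'   (default 0.2).
#' @param onset_refine \code{"burst_start"} (default) walks the detected
#'   onset back to the local minimum of acceleration magnitude at the start
#'   of the triggering acceleration burst, dating initiation where motion
#'   actually begins; \code{"none"} keeps the literal first sample at which
#'   both thresholds are exceeded simultaneously (which on a smooth reach is
#'   only reached once a fifth of the distance is covered).
#' @param hysteresis_fraction Zero-crossing hysteresis band as a fraction of
#'   the signal RMS (default 0.01; 0 reproduces the literal crossing rule).
#' @param end_rule \code{"recording_end"} (default; trials are
#'   experimenter-terminated, so the recording end delimits the movement) or
#'   \code{"speed_threshold"} (first sample after the last time speed
#'   exceeds 5\% of its peak; for single-reach analysis).
#' @return A list of class \code{reachkin_options}.
#' @export
kinematic_options <- function(smoothing = filter_spec(),
                              threshold_fraction = 0.2,
                              onset_refine = c("burst_start", "none"),
                              hysteresis_fraction = 0.01,
                              end_rule = c("recording_end", "speed_threshold")) {
  structure(list(smoothing = smoothing,
                 threshold_fraction = threshold_fraction,
                 onset_refine = match.arg(onset_refine),
                 hysteresis_fraction = hysteresis_fraction,
                 end_rule = match.arg(end_rule)),
            class = "reachkin_options")
}

#' Detect movement onset after the go signal
#'
#' Within the search window (go signal to recording end), computes the
#' relative distance d(t) from the position at the go signal and takes the
#' first sample at which both d(t) and the acceleration magnitude reach
#' \code{threshold_fraction} (default 20\%) of their window maxima
#' simultaneously. With \code{onset_refine = "burst_start"} the onset is
#' then walked back to the start of the triggering acceleration burst (the
#' preceding local minimum of |a|), so that reaction time, movement time and
#' path are measured from where motion begins rather than from a fifth of
#' the way through the reach.
#'
#' @param trial A \code{\link{trial}}.
#' @param stack A \code{\link{differentiate}} result for the trial.
#' @param threshold_fraction Threshold fraction (default 0.2).
#' @param onset_refine See \code{\link{kinematic_options}}.
#' @return One-based onset sample index.
#' @export
detect_onset <- function(trial, stack, threshold_fraction = 0.2,
                         onset_refine = c("burst_start", "none")) {
  onset_refine <- match.arg(onset_refine)
  w0 <- trial$go_signal_index + 1L         # 1-based window start
  n <- n_samples(trial)
  pos <- stack$position
  d <- sqrt(rowSums(sweep(pos[w0:n, , drop = FALSE], 2, pos[w0, ])^2))
  a <- stack$accel_mag[w0:n]
  thr_d <- threshold_fraction * max(d)
  thr_a <- threshold_fraction * max(a)
  hit <- which(d >= thr_d & a >= thr_a)
  if (!length(hit) || max(d) == 0)
    stopf("no movement detected in trial %s/%d (no sample reaches both onset thresholds)",
          trial$subject_id, trial$trial_index)
  s <- hit[1]
  if (onset_refine == "burst_start") {
    # walk back along the monotone rise of the distance excursion to the
    # sample where motion begins
    while (s > 1 && d[s - 1] < d[s]) s <- s - 1
  }
  w0 + s - 1L
}

#' Count zero-crossings of a one-axis signal with hysteresis
#'
#' A crossing is a move from above +h to below -h (or vice versa), with
#' h = \code{hysteresis_fraction} * RMS(series). Samples inside the band do
#' not accumulate crossings; exact zeros resolve to the next signed sample.
#' \code{hysteresis_fraction = 0} reproduces the literal sign-change rule.
#'
#' @param series Finite numeric vector.
#' @param hysteresis_fraction Band half-width as a fraction of the signal
#'   RMS (default 0.01).
#' @return Non-negative integer crossing count.
#' @export
count_zero_crossings <- function(series, hysteresis_fraction = 0.01) {
  if (!all(is.finite(series))) stopf("series must be finite")
  h <- hysteresis_fraction * sqrt(mean(series^2))
  s <- sign(series)
  s[abs(series) <= h] <- 0
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' RMS movement-unit counts from per-axis zero-crossings
#'
#' For each derivative order (velocity = Type 1, acceleration = Type 2,
#' jerk = Type 3), counts zero-crossings independently on the x, y and z
#' component series inside the movement window and consolidates the three
#' counts as RMS = sqrt((nx^2 + ny^2 + nz^2) / 3).
#'
#' @param stack A \code{\link{differentiate}} result.
#' @param window Integer vector \code{c(start, end)} (1-based, inclusive).
#' @param hysteresis_fraction Passed to \code{\link{count_zero_crossings}}.
#' @return Named numeric vector \code{mu_type1_rms}, \code{mu_type2_rms},
#'   \code{mu_type3_rms}.
#' @export
movement_units <- function(stack, window, hysteresis_fraction = 0.01) {
  idx <- window[1]:window[2]
  rms3 <- function(M) {
    counts <- apply(M[idx, , drop = FALSE], 2, count_zero_crossings,
                    hysteresis_fraction = hysteresis_fraction)
    sqrt(sum(counts^2) / 3)
  }
  c(mu_type1_rms = rms3(stack$velocity),
    mu_type2_rms = rms3(stack$acceleration),
    mu_type3_rms = rms3(stack$jerk))
}

#' Summary kinematics over the movement window
#'
#' Movement window is [onset, movement end]; by default the movement end is
#' the recording end. Total distance sums Euclidean inter-sample steps;
#' velocity summaries use the speed series, acceleration summaries the
#' acceleration-vector magnitude; time-to-peak values are measured from the
#' onset to the first occurrence of the maximum.
#'
#' @param trial A \code{\link{trial}}.
#' @param stack A \code{\link{differentiate}} result.
#' @param onset One-based onset index from \code{\link{detect_onset}}.
#' @param end_rule See \code{\link{kinematic_options}}.
#' @return Named numeric vector of the seven summary parameters plus the
#'   attribute-free \code{movement_end} index in the \code{"window"}
#'   attribute.
#' @export
summary_features <- function(trial, stack, onset,
                             end_rule = c("recording_end", "speed_threshold")) {
  end_rule <- match.arg(end_rule)
  n <- n_samples(trial)
  fs <- trial$sampling_rate_hz
  m_end <- n
  if (end_rule == "speed_threshold") {
    sp <- stack$speed[onset:n]
    above <- which(sp > 0.05 * max(sp))
    if (length(above)) m_end <- min(n, onset + max(above))  # first sample after
  }
  if (m_end - onset + 1 < 3) stopf("movement window shorter than 3 samples")
  idx <- onset:m_end
  P <- stack$position[idx, , drop = FALSE]
  speed <- stack$speed[idx]
  accel <- stack$accel_mag[idx]
  # trapezoidal time average: mean over the window duration without the
  # half-sample endpoint bias of a plain sample mean
  tmean <- function(x) (sum(x) - (x[1] + x[length(x)]) / 2) / (length(x) - 1)
  out <- c(
    movement_time_s = (m_end - onset) / fs,
    total_distance_m = sum(sqrt(rowSums(diff(P)^2))),
    avg_velocity_mps = tmean(speed),
    max_velocity_mps = max(speed),
    time_to_peak_velocity_s = (which.max(speed) - 1) / fs,
    avg_acceleration_mps2 = tmean(accel),
    max_acceleration_mps2 = max(accel),
    time_to_peak_acceleration_s = (which.max(accel) - 1) / fs)
  attr(out, "window") <- c(onset, m_end)
  out
}

#' Extract the twelve kinematic parameters from one trial
#'
#' Composition of \code{\link{differentiate}}, \code{\link{detect_onset}},
#' \code{\link{summary_features}} and \code{\link{movement_units}}:
#' reaction time, movement time, total distance, average/maximum velocity,
#' time to peak velocity, average/maximum acceleration, time to peak
#' acceleration, and the three RMS movement-unit counts.
#'
#' @param trial A \code{\link{trial}}.
#' @param options A \code{\link{kinematic_options}}.
#' @return Named numeric vector of length 12 in the order of
#'   \code{\link{kinematic_feature_names}}.
#' @export
extract_features <- function(trial, options = kinematic_options()) {
  stack <- differentiate(trial, options$smoothing)
  onset <- detect_onset(trial, stack, options$threshold_fraction,
                        options$onset_refine)
  sumf <- summary_features(trial, stack, onset, options$end_rule)
  win <- attr(sumf, "window")
  mus <- movement_units(stack, win, options$hysteresis_fraction)
  out <- c(reaction_time_s = (onset - 1 - trial$go_signal_index) /
             trial$sampling_rate_hz,
           sumf[FEATURE_COLUMNS[2:9]], mus)
  out[FEATURE_COLUMNS]
}

#' Extract features for every trial in a trial set
#'
#' Trials in which no movement is detected are dropped with a message; the
#' dropped keys are recorded in the \code{"dropped"} attribute.
#'
#' @param trialset A \code{\link{trial_set}} or \code{reachkin_cohort}.
#' @param options A \code{\link{kinematic_options}}.
#' @return Data frame: subject_id, group, trial_index plus the twelve
#'   feature columns.
#' @export
extract_features_set <- function(trialset, options = kinematic_options()) {
  if (inherits(trialset, "reachkin_cohort")) trialset <- trialset$trials
  stopifnot(inherits(trialset, "reachkin_trialset"))
  rows <- list()
  dropped <- character()
  for (t in trialset$trials) {
    feats <- tryCatch(extract_features(t, options), error = function(e) e)
    if (inherits(feats, "error")) {
      dropped <- c(dropped, sprintf("%s/%d: %s", t$subject_id, t$trial_index,
                                    conditionMessage(feats)))
      next
    }
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(subject_id = t$subject_id, group = t$group,
                 trial_index = t$trial_index),
      as.data.frame(as.list(feats)))
  }
  if (!length(rows)) stopf("no extractable trials in the set")
  if (length(dropped))
    message(sprintf("dropped %d trial(s) with no detectable movement", length(dropped)))
  out <- do.call(rbind, rows)
  attr(out, "dropped") <- dropped
  out
}
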