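# Fixtures built in code; no stored data.

# A bare noiseless minimum-jerk reach packaged as a trial: optional
# quiescent pre-go and tail segments, go signal at the end of the pre-go
# period, reach begins after `rt_s`.
make_minjerk_trial <- function(amplitude = 0.3, duration = 1, fs = 100,
                               direction = c(1, 0, 0), pre_go_s = 0,
                               rt_s = 0, tail_s = 0, peak_fraction = 0.5,
                               subject_id = "S1", group = "TD") {
  P <- min_jerk_segment(amplitude, duration, direction, fs, peak_fraction)
  n_pre <- round((pre_go_s + rt_s) * fs)
  n_tail <- round(tail_s * fs)
  tail_block <- if (n_tail > 0) matrix(P[nrow(P), ], n_tail, 3, byrow = TRUE)
  disp <- rbind(matrix(0, n_pre, 3), P, tail_block)
  trial(subject_id, group, 1L, disp, fs, go_signal_index = round(pre_go_s * fs))
}

# Uniformly random proper rotation matrix (QR with sign fix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rotation <- function(tr, R) {
  tr$displacement <- tr$displacement %*% t(R)
  tr
}

# Two well-separated 9-feature Gaussian clusters (class 0 / class 1).
make_separable <- function(seed, n = 400, shift = 5, d = 9) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(stats::rnorm(n * d, mean = rep(y * shift, d)), n, d)
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y)
}

# One informative feature among noise: feature 1 carries the class mean
# shift, the rest are pure N(0,1) noise.
make_one_informative <- function(seed, n = 160, d = 9, shift = 4) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(stats::rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + y * shift
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y)
}

# Independent brute-force zero-crossing oracle for h = 0: drop exact zeros,
# count adjacent sign changes with an explicit loop.
zero_crossings_oracle <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  n <- 0L
  for (i in 2:length(s)) if (s[i] != s[i - 1]) n <- n + 1L
  n
}

# Noise-free single-reach profile for parameter-recovery tests.
noiseless_profile <- function(group = "TD", mt = 1.2, amp = 0.3,
                              rt = 0.3, ttp = 0.5, n_corr = 0,
                              overshoot = 0) {
  group_profile(group,
    reaction_time_mean_s = rt, reaction_time_sd_s = 0,
    movement_time_mean_s = mt, movement_time_sd_s = 0,
    reach_amplitude_mean_m = amp, reach_amplitude_sd_m = 0,
    overshoot_fraction_mean = overshoot, n_corrective_mean = n_corr,
    corrective_amp_fraction = 0.1, time_to_peak_fraction = ttp,
    noise_sd_m = 0)
}

write_trials_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
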