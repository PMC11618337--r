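# Low-pass filtering and numerical differentiation.
#
# A digital Butterworth low-pass is designed from the analog prototype via
# the bilinear transform and applied forward-backward (zero phase) with
# odd-reflection edge padding, so filtering adds no group delay to onset or
# time-to-peak estimates.

# Digital Butterworth low-pass coefficients (b, a), order n, cutoff in Hz.
butter_lowpass <- function(order, cutoff_hz, fs) {
  if (order < 1 || cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stopf("cutoff must lie in (0, fs/2); got %g Hz at fs = %g", cutoff_hz, fs)
  # prewarped analog cutoff
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  # analog prototype poles on the unit circle, scaled by wc
  k <- seq_len(order)
  p <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform: s = 2*fs*(z-1)/(z+1)
  fs2 <- 2 * fs
  pz <- (1 + p / fs2) / (1 - p / fs2)
  gain <- Re(prod(wc / (fs2 * (1 - p / fs2))))
  # numerator: wc^n * (z+1)^n / prod(...); zeros all at z = -1
  b <- gain * choose(order, 0:order)
  a <- Re(poly_from_roots(pz))
  list(b = as.numeric(b), a = as.numeric(a))
}

poly_from_roots <- function(r) {
  coef <- 1
  for (root in r) coef <- c(coef, 0) - c(0, coef * root)
  coef
}

# Direct-form-II-transposed IIR filter with initial state zi (length
# max(length(a), length(b)) - 1). Returns the filtered signal.
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial conditions for a unit step input (lfilter_zi analog):
# scaled by the first padded sample to suppress edge transients.
iir_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  # companion matrix of a, transposed
  A <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2), rep(0, n - 2)))
  if (n == 2) A <- matrix(-a[2], 1, 1)
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# Zero-phase forward-backward filtering with odd-reflection padding.
filtfilt_zero_phase <- function(b, a, x) {
  ntaps <- max(length(a), length(b))
  padlen <- 3 * ntaps
  if (length(x) <= padlen)
    stopf("signal too short for zero-phase filtering (need > %d samples); use smoothing = \"none\"",
          padlen)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- iir_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}

#' Filter specification for position smoothing
#'
#' Describes the low-pass applied to displacement before differentiation.
#' The default is a zero-phase (forward-backward) 4th-order Butterworth with
#' a 10 Hz cutoff: reaching energy lives well below 10 Hz and repeated
#' differentiation amplifies high-frequency noise, which would otherwise
#' dominate zero-crossing counts. Use \code{type = "none"} for analytic
#' fixtures.
#'
#' @param type \code{"butterworth"} or \code{"none"}.
#' @param cutoff_hz Low-pass cutoff in Hz (default 10).
#' @param order Filter order before the forward-backward pass (default 4).
#' @return A list of class \code{reachkin_filter_spec}.
#' @export
filter_spec <- function(type = c("butterworth", "none"), cutoff_hz = 10, order = 4) {
  type <- match.arg(type)
  structure(list(type = type, cutoff_hz = cutoff_hz, order = as.integer(order)),
            class = "reachkin_filter_spec")
}

smooth_positions <- function(X, fs, spec) {
  if (spec$type == "none") return(X)
  coefs <- butter_lowpass(spec$order, spec$cutoff_hz, fs)
  apply(X, 2, function(col) filtfilt_zero_phase(coefs$b, coefs$a, col))
}

# Central differences, one-sided at the boundaries; output length == input.
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

#' Differentiate a trial into velocity, acceleration and jerk series
#'
#' Positions are optionally low-pass filtered (see \code{\link{filter_spec}}),
#' then differentiated by central differences (one-sided at the boundaries)
#' to per-axis velocity, acceleration and jerk. Speed is the Euclidean norm
#' of the velocity vector; \code{accel_mag} the norm of the acceleration
#' vector. All series have the same length as the input.
#'
#' @param trial A \code{\link{trial}}.
#' @param smoothing A \code{\link{filter_spec}}.
#' @return An object of class \code{reachkin_derivatives} with elements
#'   \code{position} (smoothed), \code{velocity}, \code{acceleration},
#'   \code{jerk} (n x 3 matrices), \code{speed}, \code{accel_mag} (vectors),
#'   and \code{smoothing}.
#' @export
differentiate <- function(trial, smoothing = filter_spec()) {
  stopifnot(inherits(trial, "reachkin_trial"))
  if (n_samples(trial) < 10L) stopf("trial must have at least 10 samples")
  fs <- trial$sampling_rate_hz
  dt <- 1 / fs
  P <- smooth_positions(trial$displacement, fs, smoothing)
  V <- apply(P, 2, central_diff, dt = dt)
  A <- apply(V, 2, central_diff, dt = dt)
  J <- apply(A, 2, central_diff, dt = dt)
  structure(list(position = P, velocity = V, acceleration = A, jerk = J,
                 speed = sqrt(rowSums(V^2)), accel_mag = sqrt(rowSums(A^2)),
                 smoothing = smoothing),
            class = "reachkin_derivatives")
}
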