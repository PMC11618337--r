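# Minimum-jerk primitives: the smooth point-to-point reach used by the
# synthetic generator. Position along the movement direction follows
#   x(tau) = A * (10 tau^3 - 15 tau^4 + 6 tau^5),  tau = t/T,
# which starts and ends at rest, peaks in speed at tau = 1/2 with
# v_max = 1.875 A/T, and peaks in |acceleration| at tau = (1 - 1/sqrt(3))/2
# with a_max = (10/sqrt(3)) A/T^2.

min_jerk_profile <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Piecewise-linear time warp mapping normalized time s in [0,1] to tau so
# that tau(peak_fraction) = 1/2: shifts the speed peak to s = peak_fraction
# while preserving both endpoint rest constraints.
warp_tau <- function(s, peak_fraction = 0.5) {
  p <- peak_fraction
  ifelse(s <= p, 0.5 * s / p, 0.5 + 0.5 * (s - p) / (1 - p))
}

#' Generate a minimum-jerk displacement segment
#'
#' Returns sampled 3-D displacement (starting at the origin) for a smooth
#' reach of given amplitude and duration along a direction vector. With
#' \code{peak_fraction != 0.5} the profile is time-warped piecewise linearly
#' so the speed peak occurs at that fraction of the duration; endpoints stay
#' at rest.
#'
#' @param amplitude_m Reach amplitude in meters (> 0).
#' @param duration_s Duration in seconds; must span at least 5 samples.
#' @param direction Length-3 direction vector; normalized with a warning if
#'   not unit length. Must be nonzero.
#' @param sampling_rate_hz Sampling rate (default 100).
#' @param peak_fraction Fraction of the duration at which peak speed occurs,
#'   in (0, 1); default 0.5 (symmetric profile).
#' @return An (n x 3) displacement matrix, n = round(duration * fs) + 1,
#'   running from the origin to \code{amplitude_m * direction}.
#' @export
min_jerk_segment <- function(amplitude_m, duration_s, direction = c(1, 0, 0),
                             sampling_rate_hz = 100, peak_fraction = 0.5) {
  if (!is_scalar_number(amplitude_m) || amplitude_m <= 0)
    stopf("amplitude_m must be > 0")
  if (!is_scalar_number(duration_s) || duration_s <= 0)
    stopf("duration_s must be > 0")
  n <- round(duration_s * sampling_rate_hz) + 1L
  if (n < 5L) stopf("duration must span at least 5 samples")
  if (length(direction) != 3L || !all(is.finite(direction)))
    stopf("direction must be a finite length-3 vector")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stopf("direction must be nonzero")
  if (abs(nrm - 1) > 1e-8) {
    warnf("direction is not unit length; normalizing")
  }
  direction <- direction / nrm
  if (!is_scalar_number(peak_fraction) || peak_fraction <= 0 || peak_fraction >= 1)
    stopf("peak_fraction must be in (0, 1)")
  s <- seq(0, 1, length.out = n)
  prof <- amplitude_m * min_jerk_profile(warp_tau(s, peak_fraction))
  outer(prof, direction)
}

# Closed-form peak speed and |acceleration| of the symmetric profile.
min_jerk_peak_speed <- function(amplitude_m, duration_s)
  1.875 * amplitude_m / duration_s
min_jerk_peak_accel <- function(amplitude_m, duration_s)
  (10 / sqrt(3)) * amplitude_m / duration_s^2
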