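# N-shaped photoacoustic source pulse of a spherical absorber under
# Gaussian pulsed laser illumination.

#' Construct a sampled pressure signal
#'
#' @param samples Real pressure samples (Pa or arbitrary linear units).
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, s.
#' @return Object of class `pa_signal`; the time axis is `t0 + k/fs`.
#' @export
pa_signal <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1, fs > 0)
  if (anyNA(samples)) stop("signal samples must not contain NA/NaN")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "pa_signal")
}

#' @export
print.pa_signal <- function(x, ...) {
  cat(sprintf("<pa_signal> %d samples @ %g MHz, t0 = %g us, peak |p| = %g\n",
              length(x$samples), x$fs / 1e6, x$t0 * 1e6,
              max(abs(x$samples))))
  invisible(x)
}

#' Time axis of a signal
#' @param x A `pa_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_time <- function(x) {
  stopifnot(inherits(x, "pa_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Photoacoustic source parameters
#'
#' Parameters of a uniformly illuminated spherical absorber. The
#' characteristic times are \eqn{\tau_a = r_0/c_0} (half the acoustic
#' transit time across the sphere) and
#' \eqn{\tau_e = \sqrt{\tau_a^2 + \tau_l^2}} (transit time broadened by the
#' laser pulse duration).
#'
#' @param r0 Absorber radius, m.
#' @param c0 Sound speed of the host tissue, m/s.
#' @param tau_l Laser pulse duration, s (default 7 ns, a typical Q-switched
#'   Nd:YAG pulse).
#' @param beta Thermal expansion coefficient, 1/K.
#' @param Cp Specific heat capacity, J/(kg K).
#' @param Ea Absorbed optical energy, J.
#' @return List of class `pa_source_params` including derived `tau_a`,
#'   `tau_e`.
#' @details `beta`, `Cp` and `Ea` only set the absolute pressure scale; all
#'   distortion metrics are ratios, times or bandwidths, so they default
#'   to 1.
#' @export
source_params <- function(r0, c0, tau_l = 7e-9, beta = 1, Cp = 1, Ea = 1) {
  stopifnot(r0 > 0, c0 > 0, tau_l >= 0)
  tau_a <- r0 / c0
  tau_e <- sqrt(tau_a^2 + tau_l^2)
  structure(list(r0 = r0, c0 = c0, tau_l = tau_l, beta = beta, Cp = Cp,
                 Ea = Ea, tau_a = tau_a, tau_e = tau_e),
            class = "pa_source_params")
}

#' N-shaped photoacoustic pressure waveform
#'
#' Bipolar pressure pulse observed at distance `r` from the center of a
#' spherical absorber:
#' \deqn{p(r,t) = -\frac{\beta E_a}{2\pi^{3/2} C_p \tau_e^2\, r}
#'   \frac{t-\tau}{\tau_e} e^{-\frac{1}{2}\left(\frac{t-\tau}{\tau_e}\right)^2}}
#' with \eqn{\tau = r/c_0}. The waveform is antisymmetric about
#' \eqn{t = \tau} with extrema at \eqn{t = \tau \pm \tau_e} and decays as
#' \eqn{1/r}.
#'
#' @param params A [source_params()] object.
#' @param r Observation distance, m (>= `r0`); default the absorber surface,
#'   which is where the ray engine launches rays.
#' @param fs Sampling rate, Hz (should resolve `tau_e`; >= 10/tau_e
#'   recommended).
#' @param duration Record length, s; default `16 tau_e` centered on the
#'   pulse.
#' @param t0 Time of the first sample, s; default `tau - 8 tau_e` (possibly
#'   negative) so the record holds the whole bipolar pulse — at the absorber
#'   surface the arrival time equals `tau_a`, so a record starting at 0
#'   would truncate the leading lobe.
#' @return A [pa_signal()].
#' @export
pa_waveform <- function(params, r = params$r0, fs, duration = NULL,
                        t0 = NULL) {
  stopifnot(inherits(params, "pa_source_params"), fs > 0)
  if (r < params$r0) stop("observation distance r must be >= absorber radius r0")
  tau <- r / params$c0
  te <- params$tau_e
  if (is.null(t0)) t0 <- tau - 8 * te
  if (is.null(duration)) duration <- tau + 8 * te - t0
  if (t0 > tau - 5 * te || t0 + duration < tau + 5 * te)
    warning("record does not contain tau +/- 5*tau_e; the pulse is truncated")
  if (fs < 10 / te)
    warning("sampling rate under-resolves tau_e (fs < 10/tau_e)")
  n <- max(1L, ceiling(duration * fs))
  t <- t0 + (seq_len(n) - 1) / fs
  u <- (t - tau) / te
  K <- params$beta * params$Ea / (2 * pi^1.5 * params$Cp * te^2)
  pa_signal(-K / r * u * exp(-u^2 / 2), fs = fs, t0 = t0)
}
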