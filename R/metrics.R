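# Distortion and validation metrics: normalized standard deviation,
# transmission-coefficient errors, peak attenuation, envelope broadening,
# time shift and 3-dB bandwidth.

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

as_samples <- function(x) if (inherits(x, "pa_signal")) x$samples else x

#' Normalized standard deviation between two signals
#'
#' \eqn{\mathrm{NSD} = 100\,\sigma(|x| - |x_{ref}|)/\sigma(|x_{ref}|)} where
#' \eqn{\sigma} is the population standard deviation (divide by N; set
#' `population = FALSE` for the sample convention).
#'
#' @param test,reference Signals ([pa_signal()]) or numeric vectors of equal
#'   length (and equal sampling rate when signals).
#' @param population Use the population standard deviation (default).
#' @return NSD in percent.
#' @export
nsd <- function(test, reference, population = TRUE) {
  if (inherits(test, "pa_signal") && inherits(reference, "pa_signal") &&
      abs(test$fs - reference$fs) > 1e-9)
    stop("signals have different sampling rates")
  a <- abs(as_samples(test)); b <- abs(as_samples(reference))
  if (length(a) != length(b)) stop("signals have different lengths")
  s <- if (population) sd_pop else stats::sd
  denom <- s(b)
  if (denom == 0) stop("reference signal has zero standard deviation")
  100 * s(a - b) / denom
}

#' Signed relative error between numeric and analytic coefficients
#'
#' \eqn{100 (x_{num} - x_{anl}) / x_{anl}}.
#'
#' @param numeric_value,analytic_value Coefficient values; vectorized.
#' @return Signed percent error.
#' @export
transmission_error <- function(numeric_value, analytic_value) {
  if (any(analytic_value == 0))
    stop("relative error undefined for a zero analytic coefficient")
  100 * (numeric_value - analytic_value) / analytic_value
}

#' Peak-amplitude attenuation percentage
#'
#' \eqn{100\,(\max|x_{without}| - \max|x_{with}|)/\max|x_{without}|}.
#'
#' @param with_skull,without_skull Signals or numeric vectors.
#' @return Attenuation in percent (<= 100 for passive media).
#' @export
attenuation_pct <- function(with_skull, without_skull) {
  pw <- max(abs(as_samples(with_skull)))
  p0 <- max(abs(as_samples(without_skull)))
  if (p0 == 0) stop("reference signal has zero peak")
  100 * (p0 - pw) / p0
}

#' Signal envelope (analytic-signal magnitude)
#'
#' Magnitude of the analytic signal computed by the FFT quadrature (Hilbert)
#' construction.
#'
#' @param x A signal or numeric vector.
#' @return Numeric envelope, same length.
#' @export
signal_envelope <- function(x) {
  v <- as_samples(x)
  n <- length(v)
  if (n < 2) return(abs(v))
  sp <- stats::fft(v)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(sp * h, inverse = TRUE) / n)
}

envelope_span <- function(x, threshold) {
  env <- signal_envelope(x)
  thr <- threshold * max(env)
  idx <- which(env >= thr)
  if (length(idx) < 1) stop("envelope never crosses the threshold")
  c(first = idx[1], last = idx[length(idx)])
}

#' Relative signal broadening
#'
#' Signal duration is the span between the first and last crossing of the
#' envelope above `threshold` times its peak (the incidence and suppression
#' times); broadening is the relative increase of that duration:
#' \eqn{100\,(\mathrm{dur}_{with} - \mathrm{dur}_{without})/\mathrm{dur}_{without}}.
#'
#' @param with_skull,without_skull [pa_signal()] objects with equal `fs`.
#' @param threshold Envelope fraction defining incidence/suppression
#'   (default 0.1).
#' @return Broadening in percent.
#' @export
broadening_pct <- function(with_skull, without_skull, threshold = 0.1) {
  stopifnot(threshold > 0, threshold < 1)
  sw <- envelope_span(with_skull, threshold)
  s0 <- envelope_span(without_skull, threshold)
  fs_w <- if (inherits(with_skull, "pa_signal")) with_skull$fs else 1
  fs_0 <- if (inherits(without_skull, "pa_signal")) without_skull$fs else 1
  dw <- (sw["last"] - sw["first"]) / fs_w
  d0 <- (s0["last"] - s0["first"]) / fs_0
  if (d0 == 0) stop("reference duration is zero")
  unname(100 * (dw - d0) / d0)
}

#' Analytic skull-induced time shift
#'
#' \eqn{\Delta t = h/c_0 - h/c_{skull}}: the arrival advance caused by
#' replacing a thickness `h` of soft tissue with faster bone. Positive when
#' the skull wave arrives earlier.
#'
#' @param h Skull thickness, m.
#' @param c0 Soft-tissue sound speed, m/s.
#' @param c_skull Longitudinal skull sound speed, m/s.
#' @return Time shift in seconds.
#' @export
time_shift_analytic <- function(h, c0, c_skull) {
  stopifnot(c0 > 0, c_skull > 0, h >= 0)
  h / c0 - h / c_skull
}

#' Measured time shift between two recorded signals
#'
#' Lag of the cross-correlation maximum of the two signal envelopes,
#' refined by parabolic interpolation; reported positive when the
#' with-skull signal arrives earlier than the reference.
#'
#' @param with_skull,without_skull [pa_signal()] objects with equal `fs`.
#' @return Time shift in seconds.
#' @export
time_shift_measured <- function(with_skull, without_skull) {
  stopifnot(inherits(with_skull, "pa_signal"),
            inherits(without_skull, "pa_signal"))
  if (abs(with_skull$fs - without_skull$fs) > 1e-9)
    stop("signals have different sampling rates")
  fs <- with_skull$fs
  a <- signal_envelope(without_skull)   # reference
  b <- signal_envelope(with_skull)
  if (max(a) == 0 || max(b) == 0) stop("flat signal: no envelope")
  n <- max(length(a), length(b))
  nf <- stats::nextn(2 * n, 2)
  A <- stats::fft(c(a, rep(0, nf - length(a))))
  B <- stats::fft(c(b, rep(0, nf - length(b))))
  # R(k) = sum_n a[n] b[n - k]; with-skull earlier => peak at positive k
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / nf
  lags <- c(0:(nf / 2 - 1), -(nf / 2):-1)
  i <- which.max(cc)
  # parabolic sub-sample refinement around the peak
  im <- if (i == 1) nf else i - 1
  ip <- if (i == nf) 1 else i + 1
  denom <- cc[im] - 2 * cc[i] + cc[ip]
  delta <- if (denom != 0) 0.5 * (cc[im] - cc[ip]) / denom else 0
  offset0 <- (with_skull$t0 - without_skull$t0)
  (lags[i] + delta) / fs - offset0
}

#' 3-dB bandwidth of a signal's magnitude spectrum
#'
#' Width of the contiguous frequency region around the spectrum peak where
#' the magnitude stays at or above peak/sqrt(2), with linear interpolation
#' of the crossing frequencies. The spectrum is zero-padded for sub-bin
#' resolution.
#'
#' @param x A [pa_signal()].
#' @param pad Zero-padding factor for spectral interpolation (default 8).
#' @return Bandwidth in Hz.
#' @export
bandwidth_3db <- function(x, pad = 8) {
  stopifnot(inherits(x, "pa_signal"))
  v <- x$samples
  if (max(abs(v)) == 0) stop("zero signal has no bandwidth")
  nf <- stats::nextn(pad * length(v), 2)
  sp <- Mod(stats::fft(c(v, rep(0, nf - length(v)))))[1:(nf / 2 + 1)]
  fr <- (0:(nf / 2)) * x$fs / nf
  ip <- which.max(sp[-1]) + 1L          # exclude DC from the peak search
  thr <- sp[ip] / sqrt(2)
  lo <- ip
  while (lo > 1 && sp[lo - 1] >= thr) lo <- lo - 1
  hi <- ip
  while (hi < length(sp) && sp[hi + 1] >= thr) hi <- hi + 1
  if (lo == 1 && sp[1] >= thr && hi == length(sp))
    stop("spectrum never drops below peak/sqrt(2) inside the Nyquist band")
  f_lo <- if (lo == 1) fr[1] else {
    w <- (sp[lo] - thr) / (sp[lo] - sp[lo - 1])
    fr[lo] - w * (fr[lo] - fr[lo - 1])
  }
  f_hi <- if (hi == length(sp)) fr[hi] else {
    w <- (sp[hi] - thr) / (sp[hi] - sp[hi + 1])
    fr[hi] + w * (fr[hi + 1] - fr[hi])
  }
  f_hi - f_lo
}

#' Skull-induced distortion report
#'
#' Bundles the standard distortion metrics for a with/without-skull signal
#' pair.
#'
#' @param with_skull,without_skull [pa_signal()] objects.
#' @param threshold Envelope threshold for the duration measure.
#' @param include_nsd Also report the NSD of the pair (requires equal
#'   lengths).
#' @return One-row data frame with `attenuation_pct`, `broadening_pct`,
#'   `time_shift` (s), `bw3db_with`, `bw3db_without` (Hz) and optionally
#'   `nsd_pct`.
#' @export
distortion_report <- function(with_skull, without_skull, threshold = 0.1,
                              include_nsd = FALSE) {
  out <- data.frame(
    attenuation_pct = attenuation_pct(with_skull, without_skull),
    broadening_pct = broadening_pct(with_skull, without_skull, threshold),
    time_shift = time_shift_measured(with_skull, without_skull),
    bw3db_with = bandwidth_3db(with_skull),
    bw3db_without = bandwidth_3db(without_skull))
  if (include_nsd) {
    n <- min(length(with_skull$samples), length(without_skull$samples))
    out$nsd_pct <- nsd(pa_signal(with_skull$samples[1:n], with_skull$fs),
                       pa_signal(without_skull$samples[1:n], without_skull$fs))
  }
  out
}
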