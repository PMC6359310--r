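# Short-time Fourier analysis/synthesis and per-frequency impulse-response
# convolution. Periodic Hann analysis window at 50% overlap satisfies the
# constant-overlap-add condition exactly, giving perfect reconstruction.

hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Short-time Fourier transform
#'
#' Frames of length `2 * n_bins` are extracted at hop `hop`, windowed with a
#' periodic Hann window and transformed; the non-negative-frequency rows
#' (bins 0..`n_bins`, i.e. DC through Nyquist) are stored. Bin `b` maps to
#' frequency `b * fs / (2 * n_bins)`. The signal is zero-padded by one hop
#' in front and to a whole number of frames behind so that every original
#' sample receives full overlap-add weight; [istft()] undoes the padding.
#'
#' @param signal A [pa_signal()] (length >= `2 * n_bins`).
#' @param n_bins Number of positive-frequency bins (window length / 2).
#' @param hop Samples between frames; must divide the window length. The
#'   periodic Hann window satisfies constant overlap-add exactly for any
#'   such hop (the constant is `window/(2*hop)`); default `n_bins` (50%
#'   overlap). Smaller hops resolve arrival delays more finely when an
#'   impulse response is applied.
#' @return Object of class `pa_tfmatrix`: complex matrix `values` of
#'   dimension `(n_bins + 1) x n_frames` plus window/hop metadata.
#' @export
stft <- function(signal, n_bins = 64, hop = n_bins) {
  stopifnot(inherits(signal, "pa_signal"), n_bins >= 1)
  win <- 2L * as.integer(n_bins)
  if (length(signal$samples) < win)
    stop("signal shorter than the analysis window")
  if (win %% hop != 0)
    warning("hop does not divide the window length; overlap-add is not exact")
  if (log2(n_bins) %% 1 != 0)
    message("n_bins is not a power of two; transforms may be slower")
  w <- hann_periodic(win)
  pad_front <- win - as.integer(hop)   # every sample gets full overlap-add weight
  x <- c(rep(0, pad_front), signal$samples, rep(0, win))
  n_frames <- ceiling((length(x) - win) / hop) + 1L
  x <- c(x, rep(0, (n_frames - 1L) * hop + win - length(x)))
  vals <- matrix(0 + 0i, nrow = n_bins + 1L, ncol = n_frames)
  for (m in seq_len(n_frames)) {
    fr <- x[((m - 1L) * hop + 1L):((m - 1L) * hop + win)] * w
    sp <- stats::fft(fr)
    vals[, m] <- sp[seq_len(n_bins + 1L)]
  }
  structure(list(values = vals, window = w, hop = as.integer(hop),
                 fs = signal$fs, n_bins = as.integer(n_bins),
                 t0 = signal$t0, pad_front = pad_front,
                 orig_len = length(signal$samples)),
            class = "pa_tfmatrix")
}

#' Frequencies of the TF-matrix rows
#' @param tf A `pa_tfmatrix`.
#' @return Row frequencies in Hz (DC through Nyquist).
#' @export
tf_freqs <- function(tf) {
  stopifnot(inherits(tf, "pa_tfmatrix"))
  (seq_len(tf$n_bins + 1L) - 1L) * tf$fs / (2 * tf$n_bins)
}

#' @export
print.pa_tfmatrix <- function(x, ...) {
  cat(sprintf("<pa_tfmatrix> %d bins x %d frames, window %d, hop %d, fs %g MHz\n",
              nrow(x$values), ncol(x$values), length(x$window), x$hop,
              x$fs / 1e6))
  invisible(x)
}

#' Inverse short-time Fourier transform
#'
#' Overlap-add synthesis; the stored non-negative spectrum is mirrored by
#' conjugate symmetry before the inverse transform, so real signals are
#' reconstructed exactly (`istft(stft(x))` reproduces `x` to machine
#' precision).
#'
#' @param tf A `pa_tfmatrix`.
#' @param trim Trim the output to the original analyzed length when known
#'   (disabled automatically after [apply_response()], which extends the
#'   signal).
#' @return A [pa_signal()].
#' @export
istft <- function(tf, trim = !is.na(tf$orig_len)) {
  stopifnot(inherits(tf, "pa_tfmatrix"))
  win <- length(tf$window)
  nb <- tf$n_bins
  if (nrow(tf$values) != nb + 1L)
    stop("TF matrix dimension inconsistent with n_bins metadata")
  n_frames <- ncol(tf$values)
  out <- numeric((n_frames - 1L) * tf$hop + win)
  for (m in seq_len(n_frames)) {
    sp <- tf$values[, m]
    full <- c(sp, Conj(sp[nb:2]))
    fr <- Re(stats::fft(full, inverse = TRUE)) / win
    idx <- ((m - 1L) * tf$hop + 1L):((m - 1L) * tf$hop + win)
    out[idx] <- out[idx] + fr
  }
  out <- out / (win / (2 * tf$hop))   # periodic-Hann overlap-add constant
  out <- out[-seq_len(tf$pad_front)]
  if (isTRUE(trim) && !is.na(tf$orig_len)) out <- out[seq_len(tf$orig_len)]
  pa_signal(out, fs = tf$fs, t0 = tf$t0)
}

#' Apply a per-frequency impulse response to a TF matrix
#'
#' For every frequency row, the frame sequence is convolved (complex) with
#' the row's impulse-response sequence resampled onto the frame grid: an
#' arrival at time `t` with amplitude `A` lands on the two frame slots
#' bracketing `t/hop_dt` with linear weights, each carrying the phase factor
#' \eqn{e^{-i 2\pi f (t - k\,\mathrm{hop}/f_s)}} so that sub-hop delays are
#' preserved as carrier phase. Rows whose frequency is absent from the
#' impulse response (e.g. the Nyquist row) reuse the nearest modeled
#' frequency's arrivals, re-phased at the row frequency.
#'
#' @param tf A `pa_tfmatrix` (e.g. of the source waveform).
#' @param ir A `pa_impulse_response` from [impulse_response()].
#' @param transducer Optional per-frequency detector responsivity: a
#'   function of frequency (Hz) or a numeric vector of length
#'   `n_bins + 1`, applied multiplicatively after the response.
#' @return A `pa_tfmatrix` with frames extended to hold the latest arrival.
#' @export
apply_response <- function(tf, ir, transducer = NULL) {
  stopifnot(inherits(tf, "pa_tfmatrix"), inherits(ir, "pa_impulse_response"))
  if (abs(tf$fs - ir$fs) > 1e-6)
    stop("TF matrix and impulse response have different sampling rates")
  freqs <- tf_freqs(tf)
  hop_dt <- tf$hop / tf$fs
  gain <- if (is.null(transducer)) rep(1, length(freqs))
          else if (is.function(transducer)) transducer(freqs)
          else if (length(transducer) == length(freqs)) transducer
          else stop("transducer must be a function or a vector of length n_bins + 1")

  nfr <- ncol(tf$values)
  # frame-grid response per row
  gs <- vector("list", length(freqs))
  kmax <- 0L
  for (r in seq_along(freqs)) {
    j <- which.min(abs(ir$freqs - freqs[r]))
    tb <- ir$bins[[j]] / ir$fs
    ab <- ir$amps[[j]]
    if (length(tb) == 0) { gs[[r]] <- complex(0); next }
    kf <- tb / hop_dt
    k0 <- floor(kf)
    frac <- kf - k0
    kk <- c(k0, k0 + 1L)
    ww <- c(1 - frac, frac)
    ph <- exp(-2i * pi * freqs[r] * (rep(tb, 2) - kk * hop_dt))
    g <- rowsum(cbind(Re(rep(ab, 2) * ww * ph), Im(rep(ab, 2) * ww * ph)),
                group = kk)
    kidx <- as.integer(rownames(g))
    gv <- complex(real = g[, 1], imaginary = g[, 2])
    gfull <- rep(0 + 0i, max(kidx) + 1L)
    gfull[kidx + 1L] <- gv
    gs[[r]] <- gfull
    kmax <- max(kmax, length(gfull) - 1L)
  }
  out <- matrix(0 + 0i, nrow = length(freqs), ncol = nfr + kmax)
  for (r in seq_along(freqs)) {
    g <- gs[[r]]
    if (length(g) == 0) next
    row <- tf$values[r, ]
    acc <- rep(0 + 0i, nfr + kmax)
    for (k in seq_along(g)) {
      if (g[k] == 0) next
      acc[(k):(k + nfr - 1L)] <- acc[(k):(k + nfr - 1L)] + g[k] * row
    }
    out[r, ] <- gain[r] * acc
  }
  res <- tf
  res$values <- out
  res$orig_len <- NA_integer_
  res
}

#' Gaussian transducer band response
#'
#' Detector responsivity model: unit gain at the center frequency with a
#' Gaussian rolloff whose -6 dB full width equals
#' `frac_bandwidth * center` (the convention used for commercial immersion
#' probes, e.g. 5 MHz with 36% fractional bandwidth).
#'
#' @param center Center frequency, Hz.
#' @param frac_bandwidth Fractional -6 dB bandwidth (0-1 scale).
#' @return A function of frequency (Hz) usable as the `transducer` argument
#'   of [apply_response()].
#' @export
transducer_gaussian <- function(center, frac_bandwidth) {
  stopifnot(center > 0, frac_bandwidth > 0)
  halfw <- frac_bandwidth * center / 2
  sigma <- halfw / sqrt(2 * log(2))
  function(f) exp(-(f - center)^2 / (2 * sigma^2))
}
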