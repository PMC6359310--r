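# Deterministic ray engine: detector mesh, Snell-consistent path finding
# through the layered stack (Fermat construction), per-frequency ray
# propagation with attenuation/dispersion/mode conversion and reverberation,
# and assembly of per-frequency impulse responses.

#' Build the detector mesh
#'
#' A `mesh_n` x `mesh_n` square grid of cell centers circumscribing the
#' circular transducer aperture; centers outside the aperture radius are
#' discarded. Rays are launched from the target to every retained center.
#'
#' @param sc A `pa_scenario`.
#' @return Two-column matrix of cell-center coordinates (m) on the
#'   transducer plane, with attribute `"pitch"` (cell side length).
#' @export
build_mesh <- function(sc) {
  stopifnot(inherits(sc, "pa_scenario"))
  n <- sc$mesh_n
  pitch <- 2 * sc$rd / n
  u <- -sc$rd + (seq_len(n) - 0.5) * pitch
  g <- expand.grid(x = u, y = u)
  keep <- g$x^2 + g$y^2 <= sc$rd^2
  if (!any(keep)) {           # pinhole meshes: keep the center cell
    g <- data.frame(x = 0, y = 0)
    keep <- TRUE
  }
  m <- as.matrix(g[keep, , drop = FALSE])
  dimnames(m) <- list(NULL, c("x", "y"))
  attr(m, "pitch") <- pitch
  m
}

# Layer stack from the target upward. Each row: thickness and medium role.
# The middle (skull) layer is dropped when h = 0.
layer_stack <- function(sc) {
  if (sc$h > 0) {
    list(thickness = c(sc$d, sc$h, sc$k),
         media = list(sc$media$tissue, sc$media$skull, sc$media$water),
         mid = 2L)
  } else {
    list(thickness = c(sc$d, sc$k),
         media = list(sc$media$tissue, sc$media$water),
         mid = NA_integer_)
  }
}

# Speed/absorption of layer i for the path mode, at frequency f. The skull
# layer uses the shear parameters on shear paths; the fluids are always
# longitudinal. f = 0 is the lossless non-dispersive zero-frequency limit
# (the Kramers-Kronig relation is singular there for y < 1).
layer_mode <- function(stack, i, path_mode) {
  if (!is.na(stack$mid) && i == stack$mid && path_mode == "shear")
    "shear" else "longitudinal"
}
layer_speed <- function(stack, i, path_mode, f, f_ref) {
  md <- layer_mode(stack, i, path_mode)
  if (f <= 0) mode_params(stack$media[[i]], md)$c_ref
  else phase_speed(stack$media[[i]], f, md, f_ref)
}
layer_alpha <- function(stack, i, path_mode, f) {
  if (f <= 0) return(0)
  absorption(stack$media[[i]], f, layer_mode(stack, i, path_mode))
}

#' Find Snell-consistent ray paths to every mesh cell
#'
#' For each detector cell the three-segment (tissue, skull, coupling) path
#' from the target is found by a Fermat construction: the ray parameter
#' \eqn{p = \sin\theta_i/c_i} shared by all layers (Snell's law) is solved by
#' bisection so the accumulated lateral offset
#' \eqn{\sum_i d_i \tan\theta_i} matches the cell's lateral distance. Paths
#' are computed at the reference frequency and reused across frequencies
#' (dispersion perturbs speeds by a few percent; the path correction is
#' second order).
#'
#' @param sc A `pa_scenario`.
#' @param mode_in_skull `"longitudinal"` or `"shear"` branch inside the
#'   skull layer.
#' @param mesh Optional precomputed [build_mesh()] matrix.
#' @return List with per-cell vectors: `R` (lateral distance), `p` (ray
#'   parameter), per-layer matrices `sin_theta`, `cos_theta`, `lengths`,
#'   and `total_length`.
#' @export
find_paths <- function(sc, mode_in_skull = c("longitudinal", "shear"),
                       mesh = NULL) {
  stopifnot(inherits(sc, "pa_scenario"))
  mode_in_skull <- match.arg(mode_in_skull)
  stack <- layer_stack(sc)
  if (mode_in_skull == "shear" && (is.na(stack$mid) ||
                                   is_fluid(stack$media[[stack$mid]])))
    stop("shear path requested but the middle layer is absent or fluid")
  if (is.null(mesh)) mesh <- build_mesh(sc)
  R <- sqrt((mesh[, 1] - sc$offset)^2 + mesh[, 2]^2)
  nl <- length(stack$thickness)
  cvec <- vapply(seq_len(nl), function(i)
    layer_speed(stack, i, mode_in_skull, sc$f_ref, sc$f_ref), numeric(1))
  dvec <- stack$thickness

  lateral <- function(p) {   # total lateral run for ray parameter p (vector)
    out <- 0
    for (i in seq_len(nl)) {
      s <- p * cvec[i]
      out <- out + dvec[i] * s / sqrt(pmax(1 - s^2, 1e-300))
    }
    out
  }
  lo <- rep(0, length(R))
  hi <- rep((1 - 1e-12) / max(cvec), length(R))
  for (it in 1:90) {
    mid <- (lo + hi) / 2
    too_small <- lateral(mid) < R
    lo <- ifelse(too_small, mid, lo)
    hi <- ifelse(too_small, hi, mid)
  }
  p <- (lo + hi) / 2
  sin_t <- outer(p, cvec)
  sin_t <- pmin(sin_t, 1 - 1e-15)
  cos_t <- sqrt(1 - sin_t^2)
  lens <- sweep(1 / cos_t, 2, dvec, `*`)
  list(mode = mode_in_skull, R = R, p = p,
       sin_theta = sin_t, cos_theta = cos_t, lengths = lens,
       total_length = rowSums(lens), mesh = mesh)
}

# Arrivals (time, complex amplitude, reflection count) for one path family
# at one frequency. Returns a data.frame; vectorized over cells.
path_arrivals <- function(sc, paths, freq, amplitude = 1) {
  stack <- layer_stack(sc)
  mode <- paths$mode
  nl <- length(stack$thickness)
  ncell <- length(paths$R)
  cf <- vapply(seq_len(nl), function(i)
    layer_speed(stack, i, mode, freq, sc$f_ref), numeric(1))
  af <- vapply(seq_len(nl), function(i)
    layer_alpha(stack, i, mode, freq), numeric(1))

  t0 <- as.vector(paths$lengths %*% (1 / cf))
  attn <- exp(-as.vector(paths$lengths %*% af))
  theta1 <- asin(paths$sin_theta[, 1])
  fq <- if (freq <= 0) NULL else freq   # NULL -> reference speeds in coeffs

  mid <- stack$mid
  if (!is.na(mid) && !is_fluid(stack$media[[mid]])) {
    theta2 <- asin(paths$sin_theta[, mid])
    inner <- fluid_solid_core(stack$media[[1]], stack$media[[mid]], theta1,
                              fq, sc$f_ref)
    T_in <- if (mode == "shear") inner$TS else inner$TL
    outer <- solid_fluid_transmission(stack$media[[mid]], stack$media[[3]],
                                      mode, theta2, fq, sc$f_ref)
    T_out <- outer$T
    R_out <- outer$R_same
    R_in <- solid_fluid_transmission(stack$media[[mid]], stack$media[[1]],
                                     mode, theta2, fq, sc$f_ref)$R_same
  } else if (!is.na(mid)) {            # fluid middle layer (reference stack)
    theta2 <- asin(paths$sin_theta[, mid])
    T_in <- fluid_fluid_coeffs(stack$media[[1]], stack$media[[mid]], theta1,
                               fq, sc$f_ref)$T + 0i
    out2 <- fluid_fluid_coeffs(stack$media[[mid]], stack$media[[3]], theta2,
                               fq, sc$f_ref)
    T_out <- out2$T + 0i
    R_out <- out2$R + 0i
    R_in <- fluid_fluid_coeffs(stack$media[[mid]], stack$media[[1]], theta2,
                               fq, sc$f_ref)$R + 0i
  } else {                             # no middle layer at all
    T_in <- fluid_fluid_coeffs(stack$media[[1]], stack$media[[2]], theta1,
                               fq, sc$f_ref)$T + 0i
    T_out <- 1 + 0i
    R_out <- R_in <- rep(0 + 0i, ncell)
    theta2 <- NULL
  }

  amp0 <- amplitude * T_in * T_out * attn * sc$r0 / paths$total_length
  res_t <- list(t0)
  res_a <- list(amp0)
  res_o <- list(rep(0L, ncell))
  res_c <- list(seq_len(ncell))

  # same-mode reverberations inside the middle layer: each double bounce
  # multiplies by R_out * R_in, adds two skull chords of delay/absorption,
  # lengthens the spreading path, and costs 2 reflections
  if (!is.na(mid)) {
    Lm <- paths$lengths[, mid]
    cm <- cf[mid]; am <- af[mid]
    sinm <- paths$sin_theta[, mid]
    echo_fac <- R_out * R_in * exp(-2 * am * Lm)
    m <- 1L
    keep <- rep(TRUE, ncell)
    while (2L * m <= sc$max_reflections) {
      amp_m <- amplitude * T_in * T_out * attn * echo_fac^m *
        sc$r0 / (paths$total_length + 2 * m * Lm)
      drift <- 2 * m * Lm * sinm
      keep <- Mod(amp_m) >= sc$amp_floor &
        (paths$R + drift) <= sc$extent_halfwidth
      if (!any(keep)) break
      res_t <- c(res_t, list((t0 + 2 * m * Lm / cm)[keep]))
      res_a <- c(res_a, list(amp_m[keep]))
      res_o <- c(res_o, list(rep(2L * m, sum(keep))))
      res_c <- c(res_c, list(which(keep)))
      m <- m + 1L
    }
  }

  # optional: rays reflected off the rigid transducer face make round trips
  # in the coupling layer before being received again
  if (isTRUE(sc$transducer_reflections)) {
    ncl <- nl                           # coupling layer index (topmost)
    Lc <- paths$lengths[, ncl]
    cc <- cf[ncl]
    sinc_ <- paths$sin_theta[, ncl]
    thc <- asin(paths$sin_theta[, ncl])
    below <- stack$media[[if (!is.na(mid)) mid else 1L]]
    R_back <- if (!is.na(mid) && !is_fluid(below))
      fluid_solid_core(stack$media[[ncl]], below, thc, fq, sc$f_ref)$R
    else fluid_fluid_coeffs(stack$media[[ncl]],
                            if (!is.na(mid)) below else stack$media[[1]],
                            thc, fq, sc$f_ref)$R + 0i
    q <- 1L
    while (2L * q <= sc$max_reflections) {
      amp_q <- amplitude * T_in * T_out * attn * R_back^q *
        sc$r0 / (paths$total_length + 2 * q * Lc)
      drift <- 2 * q * Lc * sinc_
      keep <- Mod(amp_q) >= sc$amp_floor &
        (paths$R + drift) <= sc$extent_halfwidth
      if (!any(keep)) break
      res_t <- c(res_t, list((t0 + 2 * q * Lc / cc)[keep]))
      res_a <- c(res_a, list(amp_q[keep]))
      res_o <- c(res_o, list(rep(2L * q, sum(keep))))
      res_c <- c(res_c, list(which(keep)))
      q <- q + 1L
    }
  }

  data.frame(cell = unlist(res_c), mode = mode,
             order = unlist(res_o), time = unlist(res_t),
             amp = unlist(res_a))
}

#' Enumerate every ray arrival at the detector for one frequency
#'
#' The full ray table before time binning: one row per surviving ray
#' (mesh cell x skull mode x reverberation order) with its arrival time and
#' complex amplitude relative to a unit launch at the absorber surface.
#'
#' @param sc A `pa_scenario`.
#' @param freq Frequency in Hz (0 uses the lossless non-dispersive limit).
#' @param paths Optional list of precomputed [find_paths()] results (one per
#'   mode branch) to avoid re-solving geometry.
#' @param amplitude Launch amplitude (default 1).
#' @return Data frame with columns `cell`, `mode`, `order` (reflection
#'   count), `time` (s) and complex `amp`.
#' @export
ray_arrivals <- function(sc, freq, paths = NULL, amplitude = 1) {
  stopifnot(inherits(sc, "pa_scenario"))
  if (is.null(paths)) paths <- scenario_paths(sc)
  do.call(rbind, lapply(paths, path_arrivals, sc = sc, freq = freq,
                        amplitude = amplitude))
}

# Solve the path geometry once for every mode branch of a scenario.
scenario_paths <- function(sc) {
  mesh <- build_mesh(sc)
  stack <- layer_stack(sc)
  modes <- "longitudinal"
  if (!is.na(stack$mid) && !is_fluid(stack$media[[stack$mid]]))
    modes <- c(modes, "shear")
  lapply(modes, function(m) find_paths(sc, m, mesh = mesh))
}

#' Trace one frequency into an impulse-response row
#'
#' Launches unit rays from the target toward every mesh cell (both skull
#' modes), applies per-segment absorption/dispersion, interface transmission
#' with mode conversion, spherical spreading and reverberation, and
#' accumulates the complex arrival amplitudes into time bins of width
#' `1/fs`; coincident arrivals add coherently.
#'
#' @inheritParams ray_arrivals
#' @return List with integer `bins` (arrival-time bin indices, time =
#'   bin/fs) and complex `amps`.
#' @export
trace_frequency <- function(sc, freq, paths = NULL, amplitude = 1) {
  arr <- ray_arrivals(sc, freq, paths, amplitude)
  bin_arrivals(arr, sc$fs)
}

bin_arrivals <- function(arr, fs) {
  bins <- as.integer(round(arr$time * fs))
  agg <- rowsum(cbind(Re(arr$amp), Im(arr$amp)), group = bins)
  b <- as.integer(rownames(agg))
  o <- order(b)
  list(bins = b[o], amps = complex(real = agg[o, 1], imaginary = agg[o, 2]))
}

#' Impulse response of a scenario at all modeled frequencies
#'
#' For each of the `n_freqs` frequency bins spanning 0 to `fs/2`, the
#' detector-side pattern of arrival times and accumulated complex
#' amplitudes produced by a unit-amplitude single-frequency ray ensemble
#' launched at t = 0. Fully deterministic.
#'
#' @param sc A `pa_scenario`.
#' @param freqs Optional frequency vector in Hz; default
#'   `(0:(n_freqs-1)) * fs / (2 * n_freqs)`.
#' @return Object of class `pa_impulse_response`: list with `freqs`, `fs`,
#'   and per-frequency `bins`/`amps` lists. Attributes `n_launched` and
#'   `n_received` count rays at the first frequency.
#' @export
impulse_response <- function(sc, freqs = NULL) {
  stopifnot(inherits(sc, "pa_scenario"))
  if (is.null(freqs))
    freqs <- (seq_len(sc$n_freqs) - 1) * sc$fs / (2 * sc$n_freqs)
  paths <- scenario_paths(sc)
  n_launched <- length(paths) * length(paths[[1]]$R)
  rows <- lapply(freqs, function(f) trace_frequency(sc, f, paths = paths))
  out <- structure(list(freqs = freqs, fs = sc$fs,
                        bins = lapply(rows, `[[`, "bins"),
                        amps = lapply(rows, `[[`, "amps")),
                   class = "pa_impulse_response")
  attr(out, "n_launched") <- n_launched
  attr(out, "n_received") <- nrow(ray_arrivals(sc, freqs[length(freqs)],
                                               paths = paths))
  out
}

#' @export
print.pa_impulse_response <- function(x, ...) {
  nb <- vapply(x$bins, length, integer(1))
  cat(sprintf(paste0("<pa_impulse_response> %d frequencies (%.3g-%.3g MHz), ",
                     "%d-%d occupied time bins @ fs = %g MHz\n"),
              length(x$freqs), min(x$freqs) / 1e6, max(x$freqs) / 1e6,
              min(nb), max(nb), x$fs / 1e6))
  invisible(x)
}
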