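# Acoustic media: power-law absorption and Kramers-Kronig dispersion.

#' Define an acoustic medium
#'
#' A medium is a fluid (longitudinal waves only) or an isotropic solid
#' (longitudinal and shear waves). Absorption follows the tissue-acoustics
#' power law \eqn{\alpha = \alpha_0 f^y} with \eqn{\alpha_0} in Np/cm at
#' 1 MHz and frequency expressed in MHz, and phase speed disperses according
#' to the Kramers-Kronig relation tied to that power law.
#'
#' @param name Text label.
#' @param density Mass density in kg/m^3.
#' @param c_long Longitudinal sound speed at the reference frequency, m/s.
#' @param c_shear Shear speed at the reference frequency, m/s, or `NULL` for
#'   a fluid.
#' @param alpha0_long Longitudinal power-law prefactor, Np/cm (at 1 MHz).
#' @param y_long Longitudinal power-law exponent (dimensionless), or `NULL`
#'   when the medium is lossless (`alpha0_long = 0`).
#' @param alpha0_shear,y_shear Shear-mode power-law parameters; `NULL` for
#'   fluids.
#' @return An object of class `pa_medium`.
#' @examples
#' skull <- medium("skull", 1800, 2900, c_shear = 1444,
#'                 alpha0_long = 1.70, y_long = 0.93,
#'                 alpha0_shear = 3.41, y_shear = 0.93)
#' absorption(skull, 1e6)                     # 170 Np/m at 1 MHz
#' phase_speed(skull, 5e6, f_ref = 1e6)       # faster at higher frequency
#' @export
medium <- function(name, density, c_long, c_shear = NULL,
                   alpha0_long = 0, y_long = NULL,
                   alpha0_shear = NULL, y_shear = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(c_long) || c_long <= 0) stop("c_long must be > 0")
  if (!is.null(c_shear)) {
    if (c_shear <= 0) stop("c_shear must be > 0")
    if (is.null(alpha0_shear)) stop("a solid medium needs alpha0_shear")
    if (alpha0_shear > 0 && is.null(y_shear))
      stop("y_shear required when alpha0_shear > 0")
  } else if (!is.null(alpha0_shear) || !is.null(y_shear)) {
    stop("shear loss parameters given for a fluid (no c_shear)")
  }
  if (alpha0_long < 0) stop("alpha0_long must be >= 0")
  if (alpha0_long > 0 && is.null(y_long))
    stop("y_long required when alpha0_long > 0")
  structure(list(name = name, density = density,
                 c_long_ref = c_long, c_shear_ref = c_shear,
                 alpha0_long = alpha0_long, y_long = y_long,
                 alpha0_shear = alpha0_shear, y_shear = y_shear),
            class = "pa_medium")
}

#' @export
print.pa_medium <- function(x, ...) {
  kind <- if (is_fluid(x)) "fluid" else "solid"
  cat(sprintf("<pa_medium> %s (%s): rho=%g kg/m^3, cL=%g m/s", x$name, kind,
              x$density, x$c_long_ref))
  if (!is_fluid(x)) cat(sprintf(", cS=%g m/s", x$c_shear_ref))
  cat("\n")
  invisible(x)
}

#' Is a medium a fluid?
#'
#' A medium is a fluid iff it carries no shear-mode fields.
#' @param m A `pa_medium`.
#' @return Logical scalar.
#' @export
is_fluid <- function(m) {
  stopifnot(inherits(m, "pa_medium"))
  is.null(m$c_shear_ref)
}

# Resolve (alpha0 [Np/cm], y, c_ref) for a mode; hard error on shear-in-fluid
# so geometry bugs surface instead of silently propagating zeros.
mode_params <- function(m, mode = c("longitudinal", "shear")) {
  stopifnot(inherits(m, "pa_medium"))
  mode <- match.arg(mode)
  if (mode == "shear") {
    if (is_fluid(m))
      stop(sprintf("shear mode requested on fluid medium '%s'", m$name))
    list(alpha0 = m$alpha0_shear, y = m$y_shear, c_ref = m$c_shear_ref)
  } else {
    list(alpha0 = m$alpha0_long, y = m$y_long, c_ref = m$c_long_ref)
  }
}

#' Power-law absorption coefficient
#'
#' \eqn{\alpha(f) = \alpha_0 (f/1\,\mathrm{MHz})^y}, returned in Np/m
#' (the Np/cm prefactor is scaled by 100).
#'
#' @param m A `pa_medium`.
#' @param freq Temporal frequency in Hz (> 0); vectorized.
#' @param mode `"longitudinal"` or `"shear"`.
#' @return Attenuation coefficient(s) in Np/m.
#' @export
absorption <- function(m, freq, mode = c("longitudinal", "shear")) {
  p <- mode_params(m, mode)
  if (any(freq <= 0)) stop("freq must be > 0")
  if (p$alpha0 == 0) return(rep(0, length(freq)))
  p$alpha0 * (freq / 1e6)^p$y * 100
}

# alpha0 converted from Np/cm at 1 MHz (frequency in MHz) to
# Np/m per (rad/s)^y so Kramers-Kronig formulas run in SI angular frequency.
alpha0_si <- function(alpha0_npcm, y) alpha0_npcm * 100 / (2 * pi * 1e6)^y

# Sign of the dispersion right-hand side as printed; pinned by a test so the
# convention (higher frequencies faster for y < 1) cannot silently regress.
.kk_sign <- +1

#' Dispersive phase speed from the Kramers-Kronig relation
#'
#' For power-law absorption with exponent \eqn{0 < y < 3}, \eqn{y \ne 1}:
#' \deqn{1/c_2 - 1/c_1 = \alpha_0 \tan(\pi y/2) (\omega_2^{y-1} - \omega_1^{y-1})}
#' with \eqn{c_1} the reference speed at \eqn{\omega_1 = 2\pi f_{ref}} and
#' \eqn{\alpha_0} in Np/m per (rad/s)^y. Lossless media
#' (\eqn{\alpha_0 = 0}) are non-dispersive.
#'
#' @param m A `pa_medium`.
#' @param freq Frequency in Hz (> 0); vectorized.
#' @param mode `"longitudinal"` or `"shear"`.
#' @param f_ref Reference frequency in Hz at which the tabulated speed holds.
#' @return Phase speed(s) in m/s.
#' @export
phase_speed <- function(m, freq, mode = c("longitudinal", "shear"),
                        f_ref = 1e6) {
  p <- mode_params(m, mode)
  if (any(freq <= 0) || f_ref <= 0) stop("freq and f_ref must be > 0")
  if (p$alpha0 == 0) return(rep(p$c_ref, length(freq)))
  y <- p$y
  if (y == 1) stop("Kramers-Kronig dispersion undefined for y = 1")
  if (y <= 0 || y >= 3) stop("power-law exponent must satisfy 0 < y < 3")
  a0 <- alpha0_si(p$alpha0, y)
  w1 <- 2 * pi * f_ref
  w2 <- 2 * pi * freq
  inv_c2 <- 1 / p$c_ref + .kk_sign * a0 * tan(pi * y / 2) * (w2^(y - 1) - w1^(y - 1))
  if (any(inv_c2 <= 0))
    stop("degenerate dispersion: non-positive 1/c at requested frequency")
  1 / inv_c2
}

#' Absorption and dispersion proportionality coefficients
#'
#' The loss-operator coefficients of the fractional-Laplacian lossy wave
#' equation, \eqn{\tau = -2\alpha_0 c_0^{y-1}} and
#' \eqn{\eta = 2\alpha_0 c_0^{y} \tan(\pi y/2)}, with \eqn{\alpha_0} in the
#' converted SI unit system. Diagnostic only; the ray engine applies
#' absorption and dispersion directly along ray segments.
#'
#' @param m A `pa_medium`.
#' @param mode `"longitudinal"` or `"shear"`.
#' @return Named list with elements `tau` and `eta`.
#' @export
loss_operator_coeffs <- function(m, mode = c("longitudinal", "shear")) {
  p <- mode_params(m, mode)
  if (p$alpha0 == 0) return(list(tau = 0, eta = 0))
  y <- p$y
  if (y == 1) stop("eta undefined for y = 1 (tan(pi/2) singular)")
  a0 <- alpha0_si(p$alpha0, y)
  list(tau = -2 * a0 * p$c_ref^(y - 1),
       eta = 2 * a0 * p$c_ref^y * tan(pi * y / 2))
}
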