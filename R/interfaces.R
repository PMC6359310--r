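# Plane-wave physics at flat fluid-solid and fluid-fluid interfaces:
# Snell refraction, pressure transmission with mode conversion, intensity
# coefficients, and ray direction-vector reflection/refraction.

#' Snell refraction angles at a flat interface
#'
#' \eqn{\sin\theta_t = (c_{out}/c_{in}) \sin\theta_i} per outgoing mode. An
#' evanescent flag is raised when the sine exceeds 1 (beyond the critical
#' angle for that mode).
#'
#' @param c_in Sound speed on the incidence side, m/s.
#' @param c_long_out Longitudinal speed on the transmission side, m/s.
#' @param c_shear_out Shear speed on the transmission side, m/s, or `NULL`
#'   when the outgoing medium is a fluid.
#' @param theta_i Incidence angle(s) in radians, `0 <= theta_i < pi/2`.
#' @return List with `theta_L`, `theta_S` (radians, `NA` where evanescent or
#'   absent) and logical `long_evanescent`, `shear_evanescent`.
#' @export
refraction_angles <- function(c_in, c_long_out, c_shear_out = NULL, theta_i) {
  stopifnot(c_in > 0, c_long_out > 0, all(theta_i >= 0), all(theta_i < pi / 2))
  sL <- (c_long_out / c_in) * sin(theta_i)
  long_ev <- sL > 1
  theta_L <- ifelse(long_ev, NA_real_, asin(pmin(sL, 1)))
  if (is.null(c_shear_out)) {
    theta_S <- rep(NA_real_, length(theta_i))
    shear_ev <- rep(FALSE, length(theta_i))
  } else {
    sS <- (c_shear_out / c_in) * sin(theta_i)
    shear_ev <- sS > 1
    theta_S <- ifelse(shear_ev, NA_real_, asin(pmin(sS, 1)))
  }
  list(theta_L = theta_L, theta_S = theta_S,
       long_evanescent = long_ev, shear_evanescent = shear_ev)
}

# Core fluid->solid plane-wave coefficients (White's convention).
# Vectorized over theta_i. Speeds are evaluated at `freq` through the
# Kramers-Kronig dispersion of each medium; at freq = f_ref they reduce to
# the tabulated reference speeds.
fluid_solid_core <- function(fluid, solid, theta_i, freq = NULL, f_ref = 1e6) {
  stopifnot(inherits(fluid, "pa_medium"), inherits(solid, "pa_medium"))
  if (!is_fluid(fluid)) stop("first medium must be a fluid")
  if (is_fluid(solid)) stop("second medium must be a solid")
  stopifnot(all(theta_i >= 0), all(theta_i < pi / 2))
  if (is.null(freq)) freq <- f_ref
  cf <- phase_speed(fluid, freq, "longitudinal", f_ref)
  cL <- phase_speed(solid, freq, "longitudinal", f_ref)
  cS <- phase_speed(solid, freq, "shear", f_ref)
  rf <- fluid$density; rs <- solid$density

  sinL <- (cL / cf) * sin(theta_i)
  sinS <- (cS / cf) * sin(theta_i)
  long_ev <- sinL > 1
  shear_ev <- sinS > 1
  # complex cosines carry the evanescent branch (decaying into the solid)
  cosL <- sqrt(as.complex(1 - sinL^2))
  cosS <- sqrt(as.complex(1 - sinS^2))
  ZL <- rs * cL / cosL
  ZS <- rs * cS / cosS
  Zf <- rf * cf / cos(theta_i)
  cos2S <- 1 - 2 * sinS^2            # cos(2*theta_S), valid for complex branch
  sin2S <- 2 * sinS * cosS
  denom <- ZL * cos2S^2 + ZS * sin2S^2 + Zf
  TL <- (rf / rs) * 2 * ZL * cos2S / denom
  TS <- -(rf / rs) * 2 * ZS * sin2S / denom
  R  <- (ZL * cos2S^2 + ZS * sin2S^2 - Zf) / denom
  TL[long_ev] <- 0 + 0i              # no complex evanescent tracking of
  TS[shear_ev] <- 0 + 0i             # transmitted modes: coefficient zeroed

  # intensity coefficients; the 0/0 tangent ratio at normal incidence is
  # resolved as exactly 1 (the printed-table convention)
  tanL <- Re(sinL / cosL)
  tanS <- Re(sinS / cosS)
  ratL <- ifelse(theta_i == 0, 1, tan(theta_i) / tanL)
  ratS <- ifelse(theta_i == 0, 0, tan(theta_i) / tanS)   # TS = 0 there anyway
  IL <- ifelse(long_ev, 0, (rf / rs) * ratL * Mod(TL)^2)
  IS <- ifelse(shear_ev | theta_i == 0, 0, (rf / rs) * ratS * Mod(TS)^2)
  Ir <- 1 - (IL + IS)

  list(theta_i = theta_i,
       theta_L = ifelse(long_ev, NA_real_, asin(pmin(sinL, 1))),
       theta_S = ifelse(shear_ev, NA_real_, asin(pmin(sinS, 1))),
       TL = TL, TS = TS, R = R, IL = IL, IS = IS, Ir = Ir,
       long_evanescent = long_ev, shear_evanescent = shear_ev)
}

as_interface_df <- function(res) {
  out <- data.frame(theta_i = res$theta_i, theta_L = res$theta_L,
                    theta_S = res$theta_S,
                    TL = Re(res$TL), TS = Re(res$TS), R = Re(res$R),
                    IL = res$IL, IS = res$IS, Ir = res$Ir,
                    long_evanescent = res$long_evanescent,
                    shear_evanescent = res$shear_evanescent)
  if (any(abs(Im(res$TL)) > 1e-12) || any(abs(Im(res$TS)) > 1e-12)) {
    out$TL_im <- Im(res$TL); out$TS_im <- Im(res$TS); out$R_im <- Im(res$R)
  }
  out
}

#' Pressure transmission coefficients at a fluid-solid interface
#'
#' Transmitted longitudinal (`TL`) and shear (`TS`) pressure coefficients
#' for a plane wave incident from the fluid:
#' \deqn{T_L = (\rho_f/\rho_s) \, 2 Z_L \cos 2\theta_S / D, \quad
#'       T_S = -(\rho_f/\rho_s) \, 2 Z_S \sin 2\theta_S / D}
#' with \eqn{D = Z_L \cos^2 2\theta_S + Z_S \sin^2 2\theta_S + Z_f},
#' \eqn{Z_L = \rho_s c_L/\cos\theta_L}, \eqn{Z_S = \rho_s c_S/\cos\theta_S},
#' \eqn{Z_f = \rho_f c_f/\cos\theta_i}. An evanescent mode gets coefficient 0
#' and its flag set. The fluid-side pressure reflection coefficient from the
#' same boundary problem is returned as `R`.
#'
#' @param fluid Incidence-side `pa_medium` (must be fluid).
#' @param solid Transmission-side `pa_medium` (must be solid).
#' @param theta_i Incidence angle(s), radians; vectorized.
#' @param freq Frequency in Hz at which dispersive speeds are evaluated;
#'   defaults to `f_ref`.
#' @param f_ref Reference frequency for the tabulated speeds, Hz.
#' @return Data frame with angles, `TL`, `TS`, `R`, intensity coefficients
#'   and evanescence flags.
#' @examples
#' m <- table1_media()
#' pressure_transmission(m$tissue, m$skull, c(0, 15, 30) * pi / 180)
#' @export
pressure_transmission <- function(fluid, solid, theta_i, freq = NULL,
                                  f_ref = 1e6) {
  as_interface_df(fluid_solid_core(fluid, solid, theta_i, freq, f_ref))
}

#' Intensity transmission and reflection coefficients
#'
#' \deqn{I_L = \frac{\rho_f \tan\theta_i}{\rho_s \tan\theta_L} |T_L|^2,\quad
#'       I_S = \frac{\rho_f \tan\theta_i}{\rho_s \tan\theta_S} |T_S|^2,\quad
#'       I_r = 1 - (I_L + I_S)}
#' At normal incidence the 0/0 tangent ratio is resolved as exactly 1, which
#' is the convention under which the printed reference values (e.g.
#' \eqn{I_L = 0.414} for the soft-tissue/skull pair) are reproduced; the
#' small-angle limit of the ratio is \eqn{c_f/c_L}, so \eqn{I_L(\theta_i)} is
#' deliberately discontinuous at exactly 0.
#'
#' @inheritParams pressure_transmission
#' @return Data frame as [pressure_transmission()], with `IL`, `IS`, `Ir`.
#' @export
intensity_coefficients <- function(fluid, solid, theta_i, freq = NULL,
                                   f_ref = 1e6) {
  as_interface_df(fluid_solid_core(fluid, solid, theta_i, freq, f_ref))
}

#' Transmission from a solid into a fluid (with mode conversion)
#'
#' Solves the flat-interface boundary-value problem (continuity of normal
#' displacement and normal stress, vanishing shear stress) for a longitudinal
#' or shear plane wave incident from the solid. Only a longitudinal wave is
#' transmitted into the fluid. The transmitted pressure coefficient follows
#' the same displacement-potential amplitude convention as
#' [pressure_transmission()]; at normal incidence with longitudinal incidence
#' it reduces to the two-impedance form \eqn{2 Z_f/(Z_L + Z_f)}.
#'
#' @param solid Incidence-side `pa_medium` (solid).
#' @param fluid Transmission-side `pa_medium` (fluid).
#' @param mode_in Incident mode, `"longitudinal"` or `"shear"`.
#' @param theta_i Incidence angle(s) in the solid, radians; vectorized.
#' @param freq Frequency in Hz (dispersive speeds); defaults to `f_ref`.
#' @param f_ref Reference frequency, Hz.
#' @return List with complex `T` (transmitted pressure coefficient, zero
#'   where the fluid wave is evanescent), `R_same` and `R_conv` (reflection
#'   coefficients of the same-mode and mode-converted solid waves),
#'   `theta_t` (refraction angle in the fluid) and `evanescent` flag.
#' @examples
#' m <- table1_media()
#' solid_fluid_transmission(m$skull, m$water, "longitudinal", 0)$T  # 2Zf/(ZL+Zf)
#' @export
solid_fluid_transmission <- function(solid, fluid,
                                     mode_in = c("longitudinal", "shear"),
                                     theta_i, freq = NULL, f_ref = 1e6) {
  mode_in <- match.arg(mode_in)
  stopifnot(inherits(solid, "pa_medium"), inherits(fluid, "pa_medium"))
  if (is_fluid(solid)) stop("first medium must be a solid")
  if (!is_fluid(fluid)) stop("second medium must be a fluid")
  stopifnot(all(theta_i >= 0), all(theta_i < pi / 2))
  if (is.null(freq)) freq <- f_ref
  cL <- phase_speed(solid, freq, "longitudinal", f_ref)
  cS <- phase_speed(solid, freq, "shear", f_ref)
  cf <- phase_speed(fluid, freq, "longitudinal", f_ref)
  rs <- solid$density; rf <- fluid$density
  w <- 2 * pi * max(freq, f_ref)           # scale only; coefficients are
  kL <- w / cL; kS <- w / cS; kf <- w / cf # homogeneous of degree 0 in omega
  lam <- rs * (cL^2 - 2 * cS^2)
  mu <- rs * cS^2
  kx <- if (mode_in == "longitudinal") kL * sin(theta_i) else kS * sin(theta_i)
  a <- sqrt(as.complex(kL^2 - kx^2))   # principal branch: decaying evanescent
  b <- sqrt(as.complex(kS^2 - kx^2))
  g <- sqrt(as.complex(kf^2 - kx^2))

  # unknowns (RL, RS, Tf); rows: uz continuity, sigma_zz continuity,
  # sigma_xz = 0, all evaluated at z = 0
  m11 <- -1i * a;  m12 <- 1i * kx;  m13 <- -1i * g
  m21 <- -lam * kL^2 - 2 * mu * a^2
  m22 <- 2 * mu * kx * b
  m23 <- rf * w^2 + 0i
  if (mode_in == "longitudinal") {
    m31 <- 2 * kx * a; m32 <- b^2 - kx^2
    r1 <- -1i * a
    r2 <- (lam * kL^2 + 2 * mu * a^2) + 0i
    r3 <- 2 * kx * a + 0i
  } else {
    m31 <- 2 * kx * a; m32 <- b^2 - kx^2
    r1 <- -1i * kx
    r2 <- 2 * mu * kx * b + 0i
    r3 <- -(b^2 - kx^2) + 0i
  }
  # Cramer's rule on the 3x3 system (m33 = 0)
  det3 <- function(a1, a2, a3, b1, b2, b3, c1, c2, c3)
    a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
      a3 * (b1 * c2 - b2 * c1)
  m33 <- rep(0 + 0i, length(kx))
  D  <- det3(m11, m12, m13, m21, m22, m23, m31, m32, m33)
  RL <- det3(r1, m12, m13, r2, m22, m23, r3, m32, m33) / D
  RS <- det3(m11, r1, m13, m21, r2, m23, m31, r3, m33) / D
  Tf <- det3(m11, m12, r1, m21, m22, r2, m31, m32, r3) / D

  c_in <- if (mode_in == "longitudinal") cL else cS
  sin_t <- (cf / c_in) * sin(theta_i)
  ev <- sin_t > 1
  Tp <- (rf / rs) * Tf
  Tp[ev] <- 0 + 0i
  list(T = Tp,
       R_same = if (mode_in == "longitudinal") RL else RS,
       R_conv = if (mode_in == "longitudinal") RS else RL,
       theta_t = ifelse(ev, NA_real_, asin(pmin(sin_t, 1))),
       evanescent = ev)
}

# Fluid-fluid pressure transmission/reflection at oblique incidence
# (used for the skull-replaced-by-tissue reference stack and the
# coupling-layer interfaces). Vectorized over theta_i.
fluid_fluid_coeffs <- function(med1, med2, theta_i, freq = NULL, f_ref = 1e6) {
  if (is.null(freq)) freq <- f_ref
  c1 <- phase_speed(med1, freq, "longitudinal", f_ref)
  c2 <- phase_speed(med2, freq, "longitudinal", f_ref)
  sin_t <- (c2 / c1) * sin(theta_i)
  ev <- sin_t > 1
  cos_t <- sqrt(pmax(1 - sin_t^2, 0))
  Z1 <- med1$density * c1 / cos(theta_i)
  Z2 <- med2$density * c2 / ifelse(ev, NA_real_, cos_t)
  Tp <- ifelse(ev, 0, 2 * Z2 / (Z1 + Z2))
  Rp <- ifelse(ev, 1, (Z2 - Z1) / (Z1 + Z2))
  list(T = Tp, R = Rp, theta_t = ifelse(ev, NA_real_, asin(pmin(sin_t, 1))),
       evanescent = ev)
}

#' Reflect a ray direction vector at a flat interface
#'
#' \eqn{r = i + 2\cos\theta_i\, n} with \eqn{\cos\theta_i = -i\cdot n}; the
#' normal must point into the incidence medium.
#'
#' @param i Unit incident direction (length-3 numeric).
#' @param n Unit interface normal pointing toward the incidence side.
#' @return Unit reflected direction.
#' @export
reflect_direction <- function(i, n) {
  stopifnot(length(i) == 3, length(n) == 3)
  if (abs(sum(i^2) - 1) > 1e-10 || abs(sum(n^2) - 1) > 1e-10)
    stop("i and n must be unit vectors")
  ci <- -sum(i * n)
  if (ci < -1e-12) stop("normal must oppose the incident direction (cos(theta_i) >= 0)")
  r <- i + 2 * max(ci, 0) * n
  r / sqrt(sum(r^2))
}

#' Refract a ray direction vector at a flat interface
#'
#' \eqn{t = (n_1/n_2) i + ((n_1/n_2)\cos\theta_i - \sqrt{1-\sin^2\theta_t})\,n}
#' with the acoustic index ratio \eqn{n_1/n_2 = c_2/c_1}, so that
#' \eqn{\sin\theta_t = (c_2/c_1)\sin\theta_i} (Snell-consistent).
#'
#' @param i Unit incident direction.
#' @param n Unit normal pointing toward the incidence side.
#' @param n1_over_n2 Index ratio \eqn{c_2/c_1}.
#' @return Unit transmitted direction; errors with class
#'   `"total_internal_reflection"` when the transmitted wave is evanescent
#'   (the caller should reflect instead).
#' @export
refract_direction <- function(i, n, n1_over_n2) {
  stopifnot(length(i) == 3, length(n) == 3, n1_over_n2 > 0)
  if (abs(sum(i^2) - 1) > 1e-10 || abs(sum(n^2) - 1) > 1e-10)
    stop("i and n must be unit vectors")
  eta <- n1_over_n2
  ci <- -sum(i * n)
  if (ci < -1e-12) stop("normal must oppose the incident direction")
  ci <- max(ci, 0)
  sin2t <- eta^2 * (1 - ci^2)
  if (sin2t > 1)
    stop(structure(class = c("total_internal_reflection", "error", "condition"),
                   list(message = "transmitted wave is evanescent",
                        call = sys.call())))
  t <- eta * i + (eta * ci - sqrt(1 - sin2t)) * n
  t / sqrt(sum(t^2))
}
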