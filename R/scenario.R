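# Layered simulation scenarios: geometry, media assignment, discretization
# and engine settings.

#' Reference media set (soft tissue / skull / water)
#'
#' The acoustic constants used throughout: soft tissue
#' (\eqn{\rho}=1000, \eqn{c_L}=1500, \eqn{\alpha_{0L}}=0.05 Np/cm,
#' \eqn{y_L}=1.18), cranial bone (\eqn{\rho}=1800, \eqn{c_L}=2900,
#' \eqn{c_S}=1444, \eqn{\alpha_{0L}}=1.70, \eqn{\alpha_{0S}}=3.41,
#' \eqn{y}=0.93) and water coupling (\eqn{\rho}=1000, \eqn{c_L}=1486,
#' lossless).
#'
#' @return Named list of `pa_medium`: `tissue`, `skull`, `water`.
#' @export
table1_media <- function() {
  list(
    tissue = medium("soft tissue", density = 1000, c_long = 1500,
                    alpha0_long = 0.05, y_long = 1.18),
    skull = medium("skull", density = 1800, c_long = 2900, c_shear = 1444,
                   alpha0_long = 1.70, y_long = 0.93,
                   alpha0_shear = 3.41, y_shear = 0.93),
    water = medium("water", density = 1000, c_long = 1486)
  )
}

#' Define a layered transcranial scenario
#'
#' Geometry (all lengths in meters): a spherical absorber of radius `r0`
#' sits at depth `d` below the inner-skull surface inside a brain layer of
#' thickness `T`; the skull layer has thickness `h`; a coupling layer of
#' thickness `k` separates the outer-skull surface from a flat circular
#' transducer of radius `rd`.
#'
#' @param h Skull thickness, m (0 removes the layer).
#' @param d Target depth below the inner-skull surface, m.
#' @param k Coupling-layer thickness, m.
#' @param T Brain-layer thickness, m (`d <= T`).
#' @param r0 Absorber radius, m.
#' @param rd Transducer element radius, m.
#' @param offset Target lateral offset from the transducer axis, m.
#' @param media Named list with `tissue`, `skull`, `water` `pa_medium`
#'   entries; default [table1_media()].
#' @param fs Sampling rate, Hz.
#' @param n_freqs Number of modeled frequency bins spanning 0 to `fs/2`.
#' @param mesh_n Mesh cells per side of the square grid circumscribing the
#'   transducer aperture.
#' @param max_reflections Reflection budget per ray.
#' @param f_ref Reference frequency at which tabulated speeds hold, Hz.
#' @param extent_halfwidth Lateral half-width of the simulation area, m;
#'   rays drifting beyond it die. Default `4 * rd`.
#' @param transducer_reflections Keep rays reflected off the (rigid)
#'   transducer face alive for one more round trip in the coupling layer.
#' @param amp_floor Relative amplitude below which a reverberating ray dies.
#' @return Object of class `pa_scenario`.
#' @export
scenario <- function(h, d, k = 10e-3, T = 50e-3, r0 = 1e-3, rd,
                     offset = 0, media = table1_media(),
                     fs = 50e6, n_freqs = 64, mesh_n = 100,
                     max_reflections = 20, f_ref = 1e6,
                     extent_halfwidth = 4 * rd,
                     transducer_reflections = FALSE,
                     amp_floor = 1e-10) {
  stopifnot(h >= 0, d > 0, k > 0, T > 0, r0 > 0, rd > 0,
            fs > 0, n_freqs >= 1, mesh_n >= 1, max_reflections >= 0,
            f_ref > 0, extent_halfwidth > 0)
  if (d > T) stop("target depth d must not exceed brain-layer thickness T")
  stopifnot(is.list(media), all(c("tissue", "skull", "water") %in% names(media)))
  for (nm in c("tissue", "skull", "water"))
    if (!inherits(media[[nm]], "pa_medium"))
      stop(sprintf("media$%s is not a pa_medium", nm))
  if (!is_fluid(media$tissue) || !is_fluid(media$water))
    stop("tissue and water (coupling) media must be fluids")
  pitch <- 2 * rd / mesh_n
  lam_ref <- min(media$tissue$c_long_ref,
                 if (!is_fluid(media$skull)) media$skull$c_shear_ref else
                   media$skull$c_long_ref,
                 media$water$c_long_ref) / f_ref
  if (pitch > lam_ref)
    warning(sprintf(paste("mesh pitch %.3g m exceeds the acoustic wavelength",
                          "%.3g m at the reference frequency; increase",
                          "mesh_n"),
                    pitch, lam_ref))
  structure(list(h = h, d = d, k = k, T = T, r0 = r0, rd = rd,
                 offset = offset, media = media, fs = fs,
                 n_freqs = as.integer(n_freqs), mesh_n = as.integer(mesh_n),
                 max_reflections = as.integer(max_reflections),
                 f_ref = f_ref, extent_halfwidth = extent_halfwidth,
                 transducer_reflections = transducer_reflections,
                 amp_floor = amp_floor),
            class = "pa_scenario")
}

#' @export
print.pa_scenario <- function(x, ...) {
  cat(sprintf(paste0("<pa_scenario> h=%g mm, d=%g cm, k=%g mm, T=%g cm, ",
                     "r0=%g mm, rd=%g mm\n  fs=%g MHz, %d freqs, mesh %dx%d, ",
                     "max %d reflections\n"),
              x$h * 1e3, x$d * 1e2, x$k * 1e3, x$T * 1e2, x$r0 * 1e3,
              x$rd * 1e3, x$fs / 1e6, x$n_freqs, x$mesh_n, x$mesh_n,
              x$max_reflections))
  invisible(x)
}

#' Built-in scenario presets
#'
#' `"fig2-min"`: h = 7 mm, d = 1.7 cm, k = 10 mm, r0 = 1 mm,
#' rd = 0.025 inch, T = 5 cm. `"fig6"`: same geometry with d = 2.7 cm and
#' rd = 0.25 inch.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [scenario()].
#' @return A `pa_scenario`.
#' @export
scenario_preset <- function(name = c("fig2-min", "fig6"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    "fig2-min" = list(h = 7e-3, d = 1.7e-2, k = 10e-3, r0 = 1e-3,
                      rd = 0.025 * 0.0254, T = 5e-2),
    "fig6" = list(h = 7e-3, d = 2.7e-2, k = 10e-3, r0 = 1e-3,
                  rd = 0.25 * 0.0254, T = 5e-2))
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario, args)
}

#' Matched skull-free reference scenario
#'
#' Replaces the skull medium by the brain-tissue medium while keeping all
#' thicknesses, so the reference signal travels the identical geometry with
#' the skull layer acoustically transparent (interfaces become
#' tissue/tissue). This is the reference against which skull-induced
#' attenuation, broadening and time shift are measured.
#'
#' @param sc A `pa_scenario`.
#' @return A `pa_scenario` with `media$skull = media$tissue`.
#' @export
without_skull <- function(sc) {
  stopifnot(inherits(sc, "pa_scenario"))
  sc$media$skull <- sc$media$tissue
  sc
}
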