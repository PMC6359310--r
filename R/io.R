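# Configuration files, signal serialization and bulk impulse-response
# export: the engineering shell around the physics core.

unit_table <- local({
  u <- list(
    m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6,
    inch = 0.0254, "in" = 0.0254,
    s = 1, ms = 1e-3, us = 1e-6, ns = 1e-9,
    hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)
  u[[paste0("\u00b5", "m")]] <- 1e-6   # micro-sign variants
  u[[paste0("\u00b5", "s")]] <- 1e-6
  u
})

#' Parse a quantity string with explicit units
#'
#' Scenario files state every physical quantity with an explicit unit
#' (e.g. `"7 mm"`, `"0.25 inch"`, `"50 MHz"`) because published geometry
#' mixes mm, cm and inches; bare numerics are taken as SI.
#'
#' @param x A string like `"7 mm"` or a numeric (returned as-is).
#' @param key Name used in error messages.
#' @return Value in SI base units.
#' @export
parse_quantity <- function(x, key = "value") {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1)
    stop(sprintf("'%s': expected a number or a \"<number> <unit>\" string", key))
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-z\u00b5]*)\\s*$", x))[[1]]
  if (length(m) != 3 || m[2] == "")
    stop(sprintf("'%s': cannot parse quantity '%s'", key, x))
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val)) stop(sprintf("'%s': cannot parse number in '%s'", key, x))
  if (m[3] == "") return(val)
  u <- unit_table[[tolower(m[3])]]
  if (is.null(u)) stop(sprintf("'%s': unknown unit '%s'", key, m[3]))
  val * u
}

scenario_keys <- c("preset", "h", "d", "k", "T", "r0", "rd", "offset",
                   "fs", "n_freqs", "mesh_n", "max_reflections", "f_ref",
                   "extent_halfwidth", "transducer_reflections", "amp_floor",
                   "media", "transducer", "seed")
media_keys <- c("name", "density", "c_long", "c_shear", "alpha0_long",
                "y_long", "alpha0_shear", "y_shear")

#' Load a scenario from a YAML/JSON configuration file
#'
#' Recognized keys: `preset` (`"fig2-min"` or `"fig6"`), the geometry and
#' engine fields of [scenario()] (lengths/frequencies as unit strings),
#' `media` (either the string `"table1"` or a named mapping of
#' tissue/skull/water definitions), `transducer`
#' (`center`/`frac_bandwidth`), and a reserved `seed` (the engine is
#' deterministic; the field is accepted and ignored). Unknown keys are
#' rejected with the offending key path.
#'
#' @param path Configuration file path.
#' @return A `pa_scenario`; any transducer spec is attached as attribute
#'   `"transducer"` (a function for [apply_response()]).
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a mapping")
  bad <- setdiff(names(cfg), scenario_keys)
  if (length(bad))
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))

  args <- list()
  if (!is.null(cfg$preset)) {
    base <- scenario_preset(cfg$preset)
    args <- base[c("h", "d", "k", "T", "r0", "rd")]
  }
  qty_keys <- c("h", "d", "k", "T", "r0", "rd", "offset", "fs", "f_ref",
                "extent_halfwidth")
  for (kk in qty_keys)
    if (!is.null(cfg[[kk]])) args[[kk]] <- parse_quantity(cfg[[kk]], kk)
  for (kk in c("n_freqs", "mesh_n", "max_reflections"))
    if (!is.null(cfg[[kk]])) args[[kk]] <- as.integer(cfg[[kk]])
  for (kk in c("transducer_reflections"))
    if (!is.null(cfg[[kk]])) args[[kk]] <- isTRUE(cfg[[kk]])
  if (!is.null(cfg$amp_floor)) args$amp_floor <- as.numeric(cfg$amp_floor)

  if (!is.null(cfg$media)) {
    if (identical(cfg$media, "table1")) {
      args$media <- table1_media()
    } else if (is.list(cfg$media)) {
      args$media <- lapply(names(cfg$media), function(nm) {
        md <- cfg$media[[nm]]
        bad <- setdiff(names(md), media_keys)
        if (length(bad))
          stop(sprintf("unknown media key(s) under media$%s: %s", nm,
                       paste(bad, collapse = ", ")))
        ma <- list(name = if (is.null(md$name)) nm else md$name)
        for (kk in setdiff(media_keys, "name"))
          if (!is.null(md[[kk]]))
            ma[[kk]] <- parse_quantity(md[[kk]], paste0("media$", nm, "$", kk))
        do.call(medium, ma)
      })
      names(args$media) <- names(cfg$media)
    } else stop("media must be \"table1\" or a mapping")
  }
  sc <- do.call(scenario, args)
  if (!is.null(cfg$transducer)) {
    tr <- cfg$transducer
    bad <- setdiff(names(tr), c("center", "frac_bandwidth"))
    if (length(bad))
      stop(sprintf("unknown transducer key(s): %s", paste(bad, collapse = ", ")))
    attr(sc, "transducer") <- transducer_gaussian(
      parse_quantity(tr$center, "transducer$center"), tr$frac_bandwidth)
  }
  sc
}

#' Write / read a signal as two-column delimited text
#'
#' Column format: `time_s,pressure` with a one-line header, full double
#' precision (round trips losslessly through the decimal representation).
#'
#' @param signal A [pa_signal()].
#' @param path Output file.
#' @return `write_signal` returns the path invisibly; `read_signal` returns
#'   a [pa_signal()].
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "pa_signal"))
  df <- data.frame(time_s = signal_time(signal), pressure = signal$samples)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop(sprintf("signal file '%s' not found", path))
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) stop(sprintf("cannot parse '%s': %s",
                                                  path, conditionMessage(e))))
  if (!all(c("time_s", "pressure") %in% names(df)))
    stop("signal file must have columns time_s,pressure")
  if (nrow(df) == 0) stop("signal file contains a header but no samples")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$pressure))
  if (length(bad))
    stop(sprintf("non-finite sample at line %d of '%s'", bad[1] + 1L, path))
  if (nrow(df) == 1) return(pa_signal(df$pressure, fs = 1, t0 = df$time_s[1]))
  dt <- diff(df$time_s)
  if (max(abs(dt - dt[1])) > 1e-9 * abs(dt[1]))
    stop("time axis is not uniformly sampled")
  pa_signal(df$pressure, fs = 1 / dt[1], t0 = df$time_s[1])
}

#' Export an impulse response as delimited text
#'
#' Long-format table (`freq_hz`, `time_s`, `re`, `im`), one row per
#' occupied arrival-time bin per frequency.
#'
#' @param ir A `pa_impulse_response`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_impulse_response <- function(ir, path) {
  stopifnot(inherits(ir, "pa_impulse_response"))
  rows <- lapply(seq_along(ir$freqs), function(j)
    if (length(ir$bins[[j]]))
      data.frame(freq_hz = ir$freqs[j], time_s = ir$bins[[j]] / ir$fs,
                 re = Re(ir$amps[[j]]), im = Im(ir$amps[[j]])))
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Short content hash of a scenario for run logging (md5 of its serialized
# bytes via a temp file; R ships no in-memory digest).
scenario_hash <- function(sc) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(sc, f)
  unname(tools::md5sum(f))
}
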