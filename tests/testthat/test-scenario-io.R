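test_that("reference media presets carry the tabulated constants", {
  m <- table1_media()
  expect_equal(m$skull$density, 1800)
  expect_equal(m$skull$c_long_ref, 2900)
  expect_equal(m$skull$c_shear_ref, 1444)
  expect_equal(m$skull$alpha0_long, 1.70)
  expect_equal(m$skull$y_long, 0.93)
  expect_equal(m$skull$alpha0_shear, 3.41)
  expect_equal(m$skull$y_shear, 0.93)
  expect_equal(m$tissue$c_long_ref, 1500)
  expect_true(is_fluid(m$water))
})

test_that("geometry presets match their published captions", {
  s1 <- scenario_preset("fig2-min")
  expect_equal(s1$h, 7e-3)
  expect_equal(s1$d, 1.7e-2)
  expect_equal(s1$rd, 0.025 * 0.0254)
  s2 <- scenario_preset("fig6")
  expect_equal(s2$h, 7e-3)
  expect_equal(s2$d, 2.7e-2)
  expect_equal(s2$k, 1e-2)
  expect_equal(s2$rd, 0.25 * 0.0254)
  expect_equal(s2$T, 5e-2)
  # defaults fixed by the study conditions
  expect_equal(s2$fs, 50e6)
  expect_equal(s2$n_freqs, 64L)
  expect_equal(s2$mesh_n, 100L)
  expect_equal(s2$max_reflections, 20L)
})

test_that("scenario validation catches inconsistent geometry", {
  expect_error(scenario(h = 7e-3, d = 6e-2, T = 5e-2, rd = 6e-3), "d must not exceed")
  expect_error(scenario(h = -1e-3, d = 1e-2, rd = 6e-3))
  expect_warning(scenario(h = 7e-3, d = 1.7e-2, rd = 0.1, mesh_n = 10),
                 "mesh pitch")
})

test_that("unit strings parse to SI and malformed units are named", {
  expect_equal(parse_quantity("7 mm"), 7e-3)
  expect_equal(parse_quantity("1.7 cm"), 1.7e-2)
  expect_equal(parse_quantity("0.25 inch"), 6.35e-3)
  expect_equal(parse_quantity("50 MHz"), 50e6)
  expect_equal(parse_quantity("7 ns"), 7e-9)
  expect_equal(parse_quantity(3.5), 3.5)
  expect_error(parse_quantity("7 furlongs", key = "h"), "'h'.*unknown unit")
  expect_error(parse_quantity("abc mm", key = "d"), "'d'")
})

test_that("scenario configs load, validate and reject unknown keys", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "preset: fig6",
    "h: 4.5 mm",
    "mesh_n: 20",
    "n_freqs: 16",
    "media: table1",
    "transducer:",
    "  center: 5 MHz",
    "  frac_bandwidth: 0.36"), cfg)
  sc <- load_scenario(cfg)
  expect_equal(sc$h, 4.5e-3)
  expect_equal(sc$d, 2.7e-2)          # inherited from the preset
  expect_equal(sc$mesh_n, 20L)
  tr <- attr(sc, "transducer")
  expect_equal(tr(5e6), 1)

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("preset: fig6", "skull_thickness: 3 mm"), bad)
  expect_error(load_scenario(bad), "skull_thickness")

  badm <- tempfile(fileext = ".yaml")
  writeLines(c("preset: fig6", "media:", "  tissue:", "    rho: 1000"), badm)
  expect_error(load_scenario(badm), "media\\$tissue.*rho")

  badu <- tempfile(fileext = ".yaml")
  writeLines(c("preset: fig6", "h: 3 lightyears"), badu)
  expect_error(load_scenario(badu), "'h'")
})

test_that("custom media definitions round-trip through config files", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "h: 2 mm", "d: 1 cm", "rd: 3 mm", "mesh_n: 5", "n_freqs: 4",
    "media:",
    "  tissue: {density: 1000, c_long: 1540}",
    "  skull: {density: 1900, c_long: 3000, c_shear: 1400,",
    "          alpha0_long: 1.2, y_long: 0.9, alpha0_shear: 2.0, y_shear: 0.9}",
    "  water: {density: 1000, c_long: 1480}"), cfg)
  sc <- load_scenario(cfg)
  expect_equal(sc$media$skull$c_long_ref, 3000)
  expect_equal(sc$media$tissue$c_long_ref, 1540)
  expect_false(is_fluid(sc$media$skull))
})

test_that("signals serialize losslessly and bad files are rejected", {
  sig <- pa_waveform(source_params(1e-3, 1500), fs = 50e6)
  f <- tempfile(fileext = ".csv")
  write_signal(sig, f)
  back <- read_signal(f)
  expect_equal(back$samples, sig$samples)
  expect_equal(back$fs, sig$fs, tolerance = 1e-9)
  expect_equal(back$t0, sig$t0, tolerance = 1e-12)

  nan_file <- tempfile(fileext = ".csv")
  writeLines(c("time_s,pressure", "0,1", "2e-8,NaN"), nan_file)
  expect_error(read_signal(nan_file), "non-finite.*line 3")

  hdr <- tempfile(fileext = ".csv")
  writeLines("time_s,pressure", hdr)
  expect_error(read_signal(hdr), "no samples")
})

test_that("impulse responses export to long-format text", {
  sc <- tiny_scenario(mesh_n = 3, n_freqs = 4)
  ir <- impulse_response(sc)
  f <- tempfile(fileext = ".csv")
  write_impulse_response(ir, f)
  df <- utils::read.csv(f)
  expect_equal(sort(unique(df$freq_hz)), ir$freqs)
  j <- which(ir$freqs == max(ir$freqs))
  sub <- df[df$freq_hz == max(ir$freqs), ]
  expect_equal(sub$time_s, ir$bins[[j]] / ir$fs, tolerance = 1e-12)
  expect_equal(complex(real = sub$re, imaginary = sub$im), ir$amps[[j]],
               tolerance = 1e-12)
})

test_that("sweeps run the pipeline per value with matched references", {
  empty <- sweep_scenario(tiny_scenario(), "h", numeric(0))
  expect_equal(nrow(empty), 0)
  sc <- tiny_scenario(mesh_n = 7, n_freqs = 8)
  sw <- sweep_scenario(sc, "h", c(1e-3, 5e-3))
  expect_equal(nrow(sw), 2)
  expect_true(all(c("attenuation_pct", "broadening_pct", "time_shift",
                    "bw3db_with", "bw3db_without") %in% names(sw)))
  expect_lt(sw$attenuation_pct[1], sw$attenuation_pct[2])
})

test_that("identical configurations reproduce identical outputs", {
  sc <- tiny_scenario(mesh_n = 5, n_freqs = 8)
  y1 <- simulate_scenario(sc)
  y2 <- simulate_scenario(sc)
  expect_identical(y1$samples, y2$samples)
})
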