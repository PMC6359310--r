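test_that("detector mesh circumscribes the aperture disk", {
  sc <- tiny_scenario(mesh_n = 100)
  mesh <- build_mesh(sc)
  expect_lte(nrow(mesh), 100^2)
  expect_true(all(mesh[, 1]^2 + mesh[, 2]^2 <= sc$rd^2))
  # disk-in-square area ratio ~ pi/4 for large meshes
  expect_equal(nrow(mesh) / 100^2, pi / 4, tolerance = 0.01)
  # single-cell mesh sits on the axis
  m1 <- build_mesh(tiny_scenario(mesh_n = 1))
  expect_equal(nrow(m1), 1L)
  expect_equal(unname(m1[1, ]), c(0, 0))
})

test_that("paths satisfy Snell's law and the on-axis travel time", {
  sc <- tiny_scenario()
  p <- find_paths(sc, "longitudinal")
  # on-axis cell: straight vertical path, time = sum of thickness/speed
  i <- which.min(p$R)
  expect_equal(p$R[i], 0, tolerance = 1e-12)
  tt <- sum(p$lengths[i, ] / c(1500, 2900, 1486))
  expect_equal(tt, 0.017 / 1500 + 0.007 / 2900 + 0.010 / 1486,
               tolerance = 1e-12)
  expect_equal(tt, 20.4766e-6, tolerance = 1e-4)
  # Snell consistency: sin(theta_i)/c_i identical across layers
  ratio1 <- p$sin_theta[, 1] / 1500
  expect_equal(p$sin_theta[, 2] / 2900, ratio1, tolerance = 1e-9)
  expect_equal(p$sin_theta[, 3] / 1486, ratio1, tolerance = 1e-9)
  # the lateral offset is actually reached
  lat <- rowSums(sweep(p$sin_theta / p$cos_theta, 2,
                       c(sc$d, sc$h, sc$k), `*`))
  expect_equal(lat, p$R, tolerance = 1e-9 * max(p$R))
  # shear branch obeys Snell with the shear speed
  ps <- find_paths(sc, "shear")
  expect_equal(ps$sin_theta[, 2] / 1444, ps$sin_theta[, 1] / 1500,
               tolerance = 1e-9)
})

test_that("homogeneous fluid stack yields pure 1/r arrivals", {
  sc <- homogeneous_scenario()
  arr <- ray_arrivals(sc, 1e6)
  mesh <- build_mesh(sc)
  dist <- sqrt(mesh[, 1]^2 + mesh[, 2]^2 + (sc$d + sc$k)^2)
  expect_equal(nrow(arr), nrow(mesh))      # no echoes, single mode
  expect_equal(arr$time, dist / 1500, tolerance = 1e-9)
  expect_equal(Re(arr$amp), sc$r0 / dist, tolerance = 1e-9)
  expect_equal(Im(arr$amp), rep(0, nrow(arr)))
})

test_that("tracing is deterministic and linear in the launch amplitude", {
  sc <- tiny_scenario()
  ir1 <- impulse_response(sc)
  ir2 <- impulse_response(sc)
  expect_identical(ir1$bins, ir2$bins)
  expect_identical(ir1$amps, ir2$amps)
  a1 <- trace_frequency(sc, 2e6, amplitude = 1)
  a3 <- trace_frequency(sc, 2e6, amplitude = 3)
  expect_identical(a1$bins, a3$bins)
  expect_equal(a3$amps, 3 * a1$amps, tolerance = 1e-12)
})

test_that("impulse response is invariant under lateral mirror symmetry", {
  scp <- tiny_scenario(offset = 0.3e-3)
  scm <- tiny_scenario(offset = -0.3e-3)
  rp <- trace_frequency(scp, 1e6)
  rm <- trace_frequency(scm, 1e6)
  expect_identical(rp$bins, rm$bins)
  expect_equal(rp$amps, rm$amps, tolerance = 1e-12)
})

test_that("no mode conversion on the axis: pinhole mesh has no shear energy", {
  sc <- tiny_scenario(mesh_n = 1)
  arr <- ray_arrivals(sc, 1e6)
  shear <- arr[arr$mode == "shear", ]
  long <- arr[arr$mode == "longitudinal", ]
  expect_true(all(Mod(shear$amp) < 1e-15))
  expect_true(all(Mod(long$amp) > 0))
})

test_that("raising the reflection budget only appends later arrivals", {
  sc0 <- tiny_scenario(max_reflections = 2)
  sc1 <- tiny_scenario(max_reflections = 20)
  r0 <- trace_frequency(sc0, 0.5e6)
  r1 <- trace_frequency(sc1, 0.5e6)
  expect_true(all(r0$bins %in% r1$bins))
  shared <- match(r0$bins, r1$bins)
  expect_equal(r1$amps[shared], r0$amps, tolerance = 1e-12)
  expect_gte(length(r1$bins), length(r0$bins))
  if (length(r1$bins) > length(r0$bins))
    expect_gt(min(setdiff(r1$bins, r0$bins)), min(r0$bins))
})

test_that("the skull only removes energy: passivity at every frequency", {
  sc <- tiny_scenario()
  ref <- without_skull(sc)
  freqs <- (0:7) * sc$fs / 16
  for (f in freqs) {
    with_amp <- sum(Mod(trace_frequency(sc, f)$amps))
    ref_amp <- sum(Mod(trace_frequency(ref, f)$amps))
    expect_lt(with_amp, ref_amp)
  }
})

test_that("reverberation lag matches the double skull transit", {
  sc <- tiny_scenario(mesh_n = 1)
  arr <- ray_arrivals(sc, 1e6)
  lg <- arr[arr$mode == "longitudinal", ]
  lg <- lg[order(lg$order), ]
  expect_gte(nrow(lg), 2)
  expect_equal(diff(lg$time)[1], 2 * sc$h / 2900, tolerance = 1e-3)
  # echo amplitude ratio = R_out * R_in * absorption over the double chord
  m <- sc$media
  Rout <- solid_fluid_transmission(m$skull, m$water, "longitudinal", 0)$R_same
  Rin <- solid_fluid_transmission(m$skull, m$tissue, "longitudinal", 0)$R_same
  expect_equal(Mod(lg$amp[2] / lg$amp[1]),
               Mod(Rout * Rin) * exp(-2 * absorption(m$skull, 1e6) * sc$h) *
                 (sc$d + sc$h + sc$k) / (sc$d + 3 * sc$h + sc$k),
               tolerance = 1e-9)
})

test_that("first arrival advances by the analytic shift when bone replaces tissue", {
  sc <- tiny_scenario(mesh_n = 1)
  ref <- without_skull(sc)
  t_with <- min(ray_arrivals(sc, sc$f_ref)$time)
  t_ref <- min(ray_arrivals(ref, sc$f_ref)$time)
  expect_equal(t_ref - t_with, time_shift_analytic(sc$h, 1500, 2900),
               tolerance = 1e-6)
})
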