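m <- table1_media()
deg <- pi / 180

test_that("Snell refraction angles and critical angles", {
  r0 <- refraction_angles(1500, 2900, 1444, 0)
  expect_equal(r0$theta_L, 0)
  expect_equal(r0$theta_S, 0)
  expect_false(r0$long_evanescent)
  r15 <- refraction_angles(1500, 2900, 1444, 15 * deg)
  expect_equal(r15$theta_L / deg, asin(2900 / 1500 * sin(15 * deg)) / deg,
               tolerance = 1e-12)
  expect_equal(round(r15$theta_L / deg, 1), 30.0)
  # beyond the longitudinal critical angle only shear propagates
  crit <- asin(1500 / 2900)
  expect_equal(crit / deg, 31.17, tolerance = 1e-3)
  rpost <- refraction_angles(1500, 2900, 1444, crit + 0.01)
  expect_true(rpost$long_evanescent)
  expect_false(rpost$shear_evanescent)
  # fluid outgoing medium has no shear branch
  rf <- refraction_angles(1500, 1486, NULL, 10 * deg)
  expect_true(is.na(rf$theta_S))
})

test_that("pressure transmission coefficients match the scalar oracle", {
  tr <- pressure_transmission(m$tissue, m$skull, c(0, 15, 30) * deg)
  expect_equal(tr$TL[1], 0.8631, tolerance = 1e-4)
  expect_equal(tr$TS[1], 0)
  expect_equal(tr$TL[2], 0.8625, tolerance = 1e-4)
  expect_equal(tr$TS[2], -0.2115, tolerance = 1e-3)
  # impedance-matched fluid-like limit: TL -> 1
  soft <- medium("soft solid", 1000, 1500, c_shear = 1e-3,
                 alpha0_shear = 0)
  expect_equal(pressure_transmission(m$tissue, soft, 0)$TL, 1,
               tolerance = 1e-6)
  expect_error(pressure_transmission(m$skull, m$water, 0), "fluid")
})

test_that("intensity coefficients reproduce the reference table", {
  ic <- intensity_coefficients(m$tissue, m$skull, c(0, 15, 30) * deg)
  expect_equal(ic$IL, c(0.414, 0.192, 0.133), tolerance = 2.5e-3)
  expect_equal(ic$IS, c(0.000, 0.026, 0.048), tolerance = 2e-2)
  expect_equal(abs(ic$IL - c(0.414, 0.192, 0.133)) < 0.001,
               c(TRUE, TRUE, TRUE))
  expect_equal(abs(ic$IS - c(0.000, 0.026, 0.048)) < 0.001,
               c(TRUE, TRUE, TRUE))
})

test_that("normal-incidence convention is discontinuous by design", {
  # at exactly 0 the tangent ratio is defined as 1 -> IL = (rho_f/rho_s) TL^2
  at0 <- intensity_coefficients(m$tissue, m$skull, 0)
  expect_equal(at0$IL, 0.414, tolerance = 1e-3)
  # the theta -> 0 limit of the ratio is cf/cL, a different value (~0.214);
  # assert the documented discontinuity so the convention cannot regress
  near0 <- intensity_coefficients(m$tissue, m$skull, 1e-7)
  expect_equal(near0$IL, 0.414 * 1500 / 2900, tolerance = 1e-3)
  expect_gt(abs(near0$IL - at0$IL), 0.15)
})

test_that("energy closure holds on a fine subcritical angle grid", {
  th <- seq(0, asin(1500 / 2900) - 1e-3, length.out = 1000)
  ic <- intensity_coefficients(m$tissue, m$skull, th)
  expect_true(all(ic$IL >= 0))
  expect_true(all(ic$IS >= 0))
  expect_true(all(ic$IL + ic$IS <= 1))
  expect_equal(ic$Ir, 1 - (ic$IL + ic$IS))   # definitional identity, exact
  # independent energy-flux closure: the transmission coefficients carry the
  # rho_f/rho_s amplitude convention, so the true pressure ratios are
  # (rho_s/rho_f) * T and the reflected plus transmitted flux closes as
  # R^2 + (rho_s/rho_f)^2 (IL + IS) = 1 at every oblique angle
  tr <- pressure_transmission(m$tissue, m$skull, th[-1])
  closure <- tr$R^2 + (1800 / 1000)^2 * (ic$IL[-1] + ic$IS[-1])
  expect_equal(closure, rep(1, length(closure)), tolerance = 1e-10)
})

test_that("solid-to-fluid transmission reduces to known limits", {
  # L-mode at normal incidence: two-impedance form 2Zf/(ZL+Zf)
  sf <- solid_fluid_transmission(m$skull, m$water, "longitudinal", 0)
  ZL <- 1800 * 2900; Zf <- 1000 * 1486
  expect_equal(Re(sf$T), 2 * Zf / (ZL + Zf), tolerance = 1e-12)
  expect_equal(Im(sf$T), 0, tolerance = 1e-12)
  # pure shear cannot drive a normal-incidence longitudinal wave
  ss <- solid_fluid_transmission(m$skull, m$water, "shear", 0)
  expect_equal(Mod(ss$T), 0, tolerance = 1e-12)
  # beyond the solid->fluid critical angle for shear: total internal reflection
  crit_s <- asin(1444 / 1486)
  beyond <- solid_fluid_transmission(m$skull, m$water, "shear", crit_s + 0.01)
  expect_true(beyond$evanescent)
  expect_equal(Mod(beyond$T), 0)
  expect_error(solid_fluid_transmission(m$water, m$skull, "longitudinal", 0),
               "solid")
})

test_that("solid-to-fluid solver conserves energy flux at all angles", {
  # independent check of the boundary-condition solution: normal energy flux
  # of a potential-amplitude-A plane wave is prop. to rho * Re(k_z) * |A|^2
  w <- 2 * pi * 1e6
  kL <- w / 2900; kS <- w / 1444; kf <- w / 1486
  for (mode in c("longitudinal", "shear")) {
    th <- seq(0, 80, by = 2) * deg
    res <- solid_fluid_transmission(m$skull, m$water, mode, th)
    kx <- if (mode == "longitudinal") kL * sin(th) else kS * sin(th)
    az <- Re(sqrt(as.complex(kL^2 - kx^2)))
    bz <- Re(sqrt(as.complex(kS^2 - kx^2)))
    gz <- Re(sqrt(as.complex(kf^2 - kx^2)))
    Tf <- res$T * 1800 / 1000     # back to potential-ratio amplitude
    RL <- if (mode == "longitudinal") res$R_same else res$R_conv
    RS <- if (mode == "longitudinal") res$R_conv else res$R_same
    Ein <- 1800 * (if (mode == "longitudinal") az else bz)
    Eout <- 1800 * az * Mod(RL)^2 + 1800 * bz * Mod(RS)^2 +
      1000 * gz * Mod(Tf)^2
    ok <- Ein > 0 & !res$evanescent
    expect_equal(Eout[ok] / Ein[ok], rep(1, sum(ok)), tolerance = 1e-10)
  }
})

test_that("direction-vector reflection follows the mirror law", {
  n <- c(0, 0, 1)
  expect_equal(reflect_direction(-n, n), n)
  grazing <- c(1, 0, 0)
  expect_equal(reflect_direction(grazing, n), grazing)
  i45 <- c(sin(pi / 4), 0, -cos(pi / 4))
  r <- reflect_direction(i45, n)
  expect_equal(sqrt(sum(r^2)), 1)
  expect_equal(sum(r * n), -sum(i45 * n))
  expect_equal(r, c(sin(pi / 4), 0, cos(pi / 4)))
  expect_error(reflect_direction(n, n), "orientation|oppose")
})

test_that("direction-vector refraction agrees with Snell angles", {
  n <- c(0, 0, 1)
  expect_equal(refract_direction(c(0, 0, -1), n, 1.7), c(0, 0, -1))
  i <- c(sin(0.3), 0, -cos(0.3))
  expect_equal(refract_direction(i, n, 1), i)
  # tissue -> skull at 15 degrees bends to ~30 degrees from the normal
  t <- refract_direction(c(sin(15 * deg), 0, -cos(15 * deg)), n, 2900 / 1500)
  expect_equal(acos(sum(t * -n)), asin(2900 / 1500 * sin(15 * deg)),
               tolerance = 1e-10)
  # agreement with refraction_angles over a grid of incidence angles
  for (th in seq(0.01, asin(1500 / 2900) - 0.01, length.out = 25)) {
    i <- c(sin(th), 0, -cos(th))
    t <- refract_direction(i, n, 2900 / 1500)
    expect_equal(acos(sum(t * -n)),
                 refraction_angles(1500, 2900, 1444, th)$theta_L,
                 tolerance = 1e-10)
  }
  expect_error(refract_direction(c(sin(0.6), 0, -cos(0.6)), n, 2900 / 1500),
               class = "total_internal_reflection")
})

test_that("coefficients evaluated off the reference frequency use dispersive speeds", {
  at_ref <- intensity_coefficients(m$tissue, m$skull, 15 * deg)
  at_5m <- intensity_coefficients(m$tissue, m$skull, 15 * deg, freq = 5e6)
  expect_false(isTRUE(all.equal(at_ref$IL, at_5m$IL)))
  # still energy-closed
  expect_lte(at_5m$IL + at_5m$IS, 1)
})
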