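# Optical primitives: wavevector mapping, polarization transport, wave
# plates, galvo phase model and the closed-form design formulas.

test_that("pupil-to-wavevector mapping obeys the sine condition", {
  cfg <- defaultCfg()
  k0 <- 2 * pi * cfg@refractive_index / (cfg@wavelength * 1e-3)

  # on-axis beam is purely axial
  k <- pupilToWavevector(beam(c(0, 0)), cfg)
  expect_equal(k, c(0, 0, k0), tolerance = 1e-12)

  # normalization |k| = 2 pi n / lambda for arbitrary in-aperture beams
  set.seed(1)
  for (i in 1:20) {
    r <- runif(1, 0, apertureRadius(cfg))
    a <- runif(1, 0, 2 * pi)
    k <- pupilToWavevector(beam(r * c(cos(a), sin(a))), cfg)
    expect_equal(sqrt(sum(k^2)), k0, tolerance = 1e-12)
    expect_equal(atan2(k[2], k[1]), (a + pi) %% (2 * pi) - pi,
                 tolerance = 1e-9)
  }

  expect_error(pupilToWavevector(beam(c(1, 0) * 2 * apertureRadius(cfg)),
                                 cfg), "aperture")
})

test_that("two beams at +/- x0 give the closed-form fringe wavevector", {
  # derived cross-check at n = 1, where the fringe magnitude is
  # 2 * (2 pi / lambda) * x0 / f: synthesize the pattern and fit it
  cfg <- opticalConfig(refractive_index = 1, effective_NA = 0.9)
  x0 <- 60   # mm
  b1 <- beam(c(x0, 0)); b2 <- beam(c(-x0, 0))
  pre <- new("PatternPreset", name = "pair", beams = list(b1, b2),
             z_dependent = FALSE)
  expected_mag <- 2 * (2 * pi / (cfg@wavelength * 1e-3)) * x0 /
    cfg@focal_length_main                     # rad/um
  per <- 2 * pi / expected_mag
  fit <- fitSinusoid2d(intensity(synthesizeField(pre, cfg, nx = 96,
                                                 ny = 96,
                                                 pixel_size = per / 8)))
  expect_equal(2 * pi * sqrt(sum(fit@fringe_vector^2)), expected_mag,
               tolerance = 1e-6)
})

test_that("polarization transport preserves power and transversality", {
  cfg <- defaultCfg()
  set.seed(2)
  for (i in 1:20) {
    r <- runif(1, 0.1, apertureRadius(cfg))
    a <- runif(1, 0, 2 * pi)
    jn <- complex(real = rnorm(2), imaginary = rnorm(2))
    jn <- jn / sqrt(sum(Mod(jn)^2))
    k <- pupilToWavevector(beam(r * c(cos(a), sin(a)), jones = jn), cfg)
    e <- transportPolarization(jn, k)
    expect_equal(sum(Mod(e)^2), 1, tolerance = 1e-12)
    expect_lt(Mod(sum(e * k)) / sqrt(sum(k^2)), 1e-12)
  }
  # on-axis: transverse embedding
  expect_equal(transportPolarization(c(1, 0), c(0, 0, 1)),
               as.complex(c(1, 0, 0)))
  expect_error(transportPolarization(c(1, 0), c(0, 0, 0)), "degenerate")
})

test_that("s beams keep unit overlap while p beams lose cos(2 theta)", {
  cfg <- defaultCfg()
  r <- 0.9 * apertureRadius(cfg)
  theta <- asin(r / cfg@focal_length_main)
  kp <- pupilToWavevector(beam(c(r, 0)), cfg)
  km <- pupilToWavevector(beam(c(-r, 0)), cfg)
  # s-polarized (perpendicular to the x-z meridional plane): along y
  es1 <- transportPolarization(c(0, 1), kp)
  es2 <- transportPolarization(c(0, 1), km)
  expect_equal(Re(sum(es1 * Conj(es2))), 1, tolerance = 1e-12)
  # p-polarized: overlap magnitude cos(2 theta)
  ep1 <- transportPolarization(c(1, 0), kp)
  ep2 <- transportPolarization(c(1, 0), km)
  expect_equal(abs(Re(sum(ep1 * Conj(ep2)))), abs(cos(2 * theta)),
               tolerance = 1e-12)
})

test_that("s-polarized power fraction matches the fringe-plane geometry", {
  # horizontal beam, plane rotated 60 degrees: 75% s-polarized
  expect_equal(sFraction(c(1, 0), pi / 3), 0.75, tolerance = 1e-12)
  # plane horizontal: pure p; plane vertical: pure s
  expect_equal(sFraction(c(1, 0), 0), 0, tolerance = 1e-12)
  expect_equal(sFraction(c(1, 0), pi / 2), 1, tolerance = 1e-12)
  # complement property for linear polarizations
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0, pi); th <- runif(1, 0, pi)
    jn <- c(cos(a), sin(a))
    expect_equal(sFraction(jn, th) + sFraction(jn, th + pi / 2), 1,
                 tolerance = 1e-12)
  }
  expect_error(sFraction(c(0, 0), 0), "polarization")
})

test_that("a double-passed quarter-wave plate acts as a half-wave plate", {
  # horizontal in, fast axis 45 degrees -> vertical out
  out <- doublePassWaveplate(c(1, 0), wavePlate("quarter", pi / 4))
  expect_lt(Mod(out[1]), 1e-12)
  expect_equal(Mod(out[2]), 1, tolerance = 1e-12)
  # eigenaxis: polarization along the fast axis unchanged up to phase
  out2 <- doublePassWaveplate(c(1, 0), wavePlate("quarter", 0))
  expect_equal(Mod(out2), c(1, 0), tolerance = 1e-12)
  # fast axis 22.5 degrees: horizontal -> linear at 45 degrees
  # (Jones-matrix oracle computed inline)
  a <- pi / 8
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  oracle <- R %*% diag(c(1, -1)) %*% t(R) %*% c(1, 0)
  out3 <- doublePassWaveplate(c(1, 0), wavePlate("quarter", a))
  expect_equal(as.complex(out3), as.complex(oracle), tolerance = 1e-12)
  # power preserved for arbitrary states
  set.seed(4)
  jn <- complex(real = rnorm(2), imaginary = rnorm(2))
  jn <- jn / sqrt(sum(Mod(jn)^2))
  expect_equal(sum(Mod(doublePassWaveplate(jn, wavePlate("quarter",
                                                         1.1)))^2),
               1, tolerance = 1e-12)
})

test_that("galvo phase model is bilinear and matches a ray-trace oracle", {
  cfg <- defaultCfg()
  expect_equal(galvoPhase(0, 1.5, cfg), 0)
  expect_equal(galvoPhase(1e-4, 2, cfg), 2 * galvoPhase(1e-4, 1, cfg))
  expect_equal(galvoPhase(2e-4, 1, cfg), 2 * galvoPhase(1e-4, 1, cfg))

  # exact mirror-reflection ray trace: a mirror rotated by dtheta adds a
  # path 2 * x * sin(dtheta) (~2 x dtheta) to a ray hitting it at
  # lateral offset x; with the default double-pass gain 4 pi / lambda the
  # model must agree with the exact path phase at small angles
  lam_mm <- cfg@wavelength * 1e-6
  for (x in c(0.5, 1, 2)) for (dth in c(1e-5, 1e-4)) {
    path_exact <- 2 * x * sin(dth)                # mm
    phase_exact <- 2 * pi * path_exact / lam_mm
    expect_equal(galvoPhase(dth, x, cfg), phase_exact,
                 tolerance = 1e-8)
  }
})

test_that("required galvo stability reproduces the printed design bound", {
  # lambda/10 at 488 nm over 2 mm: about 24 urad
  s <- requiredGalvoStability(488, 1 / 10, 2)
  expect_equal(s * 1e6, 24.4, tolerance = 1e-3)
  expect_equal(round(s * 1e6), 24)
  expect_equal(requiredGalvoStability(488, 0, 2), 0)
  # direct arithmetic at another wavelength
  expect_equal(requiredGalvoStability(473, 1 / 10, 2), 2.365e-5,
               tolerance = 1e-3)
  # small-angle agreement to < 0.1%
  expect_equal(s, 48.8e-6 / 2, tolerance = 1e-3)
  expect_error(requiredGalvoStability(488, 0.1, -1), "separation")
})

test_that("Rayleigh focus diameter follows 0.61 lambda f / D", {
  expect_equal(rayleighFocusDiameter(473, 200, 0.1), 577.06,
               tolerance = 1e-4)
  expect_equal(rayleighFocusDiameter(500, 100, 10), 3.05,
               tolerance = 1e-6)
  expect_equal(rayleighFocusDiameter(473, 200, 0.05),
               2 * rayleighFocusDiameter(473, 200, 0.1))
  expect_error(rayleighFocusDiameter(-1, 1, 1))
})

test_that("DMD Nyquist bound reproduces the printed field coverage", {
  d <- dmdIlluminationBound(c(4096, 2176), 473, 1.5, 22, 60)
  expect_equal(d$area[1], 323, tolerance = 0.002)
  expect_equal(d$area[2], 172, tolerance = 0.003)
  expect_equal(d$fov_diameter, 22000 / 60, tolerance = 1e-9)
  expect_lt(d$coverage, 0.53)
  # doubling magnification halves the field diameter
  d2 <- dmdIlluminationBound(c(4096, 2176), 473, 1.5, 22, 120)
  expect_equal(d2$fov_diameter, d$fov_diameter / 2)
  # two pixels cover one fringe period
  d3 <- dmdIlluminationBound(c(2, 2), 473, 1.5, 22, 60)
  expect_equal(d3$area[1], 473e-3 / (2 * 1.5), tolerance = 1e-12)
})
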