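# Pattern synthesis: coherent superposition, intensity formation, fringe
# period and visibility, axial three-beam structure.

test_that("a single beam synthesizes a uniform intensity", {
  cfg <- defaultCfg()
  pre <- new("PatternPreset", name = "one",
             beams = list(beam(c(20, 0), jones = c(0, 1))),
             z_dependent = FALSE)
  ig <- intensity(synthesizeField(pre, cfg, nx = 32, ny = 32,
                                  pixel_size = 0.05))
  expect_lt(diff(range(ig@values)), 1e-12)
  expect_equal(mean(ig@values), 1, tolerance = 1e-12)
})

test_that("two equal s-polarized beams give the closed-form cosine", {
  cfg <- defaultCfg()
  pre <- twoBeamPreset(cfg, orientation = 0, radius_frac = 0.8)
  waves <- lapply(pre@beams, function(b) pupilToWavevector(b, cfg))
  dk <- waves[[1]] - waves[[2]]
  px <- 0.03
  f <- synthesizeField(pre, cfg, nx = 64, ny = 8, pixel_size = px)
  ig <- intensity(f)
  x <- (seq_len(64) - 1 - 32) * px
  oracle <- 2 * (1 + cos(dk[1] * x))
  expect_equal(as.numeric(ig@values[4, ]), oracle, tolerance = 1e-9)
})

test_that("the hexagonal preset is invariant under 120-degree rotation", {
  cfg <- defaultCfg()
  hx <- hexagonalPreset(cfg)
  set.seed(11)
  pts <- matrix(runif(30, -1.5, 1.5), ncol = 2)
  R <- matrix(c(cos(2 * pi / 3), sin(2 * pi / 3),
                -sin(2 * pi / 3), cos(2 * pi / 3)), 2, 2)
  iA <- intensityAtPoints(hx, cfg, pts)
  iB <- intensityAtPoints(hx, cfg, pts %*% t(R))
  expect_equal(iA, iB, tolerance = 1e-10)
  # equal-amplitude three-beam pattern peaks at the coherent phasor sum;
  # with parallel polarization at small tilt this approaches the scalar
  # 9 A^2
  hxp <- hexagonalPreset(cfg, radius_frac = 0.1,
                         polarization = "parallel")
  pols <- lapply(hxp@beams, function(b)
    transportPolarization(b@jones, pupilToWavevector(b, cfg)))
  phasor_sum <- sum(Mod(pols[[1]] + pols[[2]] + pols[[3]])^2)
  # all phases vanish at the origin: the constructive point
  i0 <- intensityAtPoints(hxp, cfg, rbind(c(0, 0)))
  expect_equal(i0, phasor_sum, tolerance = 1e-9)
  expect_equal(i0, 9, tolerance = 0.01)
  igp <- intensity(synthesizeField(hxp, cfg, nx = 128, ny = 128,
                                   pixel_size = 0.12))
  expect_lte(max(igp@values), i0 * (1 + 1e-9))
  expect_gte(max(igp@values), 0.97 * i0)
})

test_that("undersampled grids are rejected", {
  cfg <- defaultCfg()
  pre <- twoBeamPreset(cfg, radius_frac = 1)
  per <- fringePeriod(cfg@wavelength, cfg@effective_NA) / 1000
  expect_error(synthesizeField(pre, cfg, nx = 16, ny = 16,
                               pixel_size = per), "undersampled")
})

test_that("fringe period follows lambda over twice the NA", {
  expect_equal(fringePeriod(473, 1.5), 157.666, tolerance = 1e-5)
  expect_equal(fringePeriod(500, 0.25), 1000)
  expect_equal(fringePeriod(500, 0.5), fringePeriod(500, 0.25) / 2)
  expect_error(fringePeriod(500, 0), "NA_eff")
})

test_that("theoretical visibility matches its definition and limits", {
  expect_equal(theoreticalVisibility(c(1, 1), 1), 1)
  expect_equal(theoreticalVisibility(c(1, 0), 1), 0)
  expect_equal(theoreticalVisibility(c(1, 0.5), 1), 0.8)
  expect_equal(theoreticalVisibility(c(2, 1), 0), 0)
  expect_error(theoreticalVisibility(c(0, 0), 1), "zero")
  # cross-check against a synthesized pattern's max/min contrast
  cfg <- defaultCfg()
  pre <- twoBeamPreset(cfg, amplitudes = c(1, 0.5), radius_frac = 0.8)
  per <- 2 * pi / (2 * (2 * pi * 0.8 * cfg@effective_NA /
                          (cfg@wavelength * 1e-3)))
  ig <- intensity(synthesizeField(pre, cfg, nx = 64, ny = 8,
                                  pixel_size = per / 8))
  v_meas <- (max(ig@values) - min(ig@values)) /
    (max(ig@values) + min(ig@values))
  expect_equal(v_meas, 0.8, tolerance = 1e-9)
})

test_that("orthogonally polarized beams do not interfere", {
  cfg <- defaultCfg()
  pre <- twoBeamPreset(cfg, orientation = 0, radius_frac = 0.3)
  # rotate one beam's polarization orthogonal to the other
  pre@beams[[2]]@jones <- as.complex(c(cos(0), sin(0)))
  pre@beams[[1]]@jones <- as.complex(c(0, 1))
  ig <- intensity(synthesizeField(pre, cfg, nx = 64, ny = 8,
                                  pixel_size = 0.1))
  v <- (max(ig@values) - min(ig@values)) / (max(ig@values) +
                                              min(ig@values))
  # small residual from the p-components' axial fields at this tilt
  expect_lt(v, 0.05)
})

test_that("linear three-beam patterns are periodic in z", {
  cfg <- defaultCfg()
  pre <- linearThreeBeamPreset(cfg, radius_frac = 0.85)
  zp <- axialPeriod(pre, cfg)
  expect_true(is.finite(zp) && zp > 0)
  pts <- cbind(seq(-1, 1, length.out = 15), 0)
  i0 <- intensityAtPoints(pre, cfg, pts, z = 0.37)
  i1 <- intensityAtPoints(pre, cfg, pts, z = 0.37 + zp)
  expect_equal(i0, i1, tolerance = 1e-10)
  # zero center amplitude reduces to the z-invariant two-beam pattern
  pre2 <- linearThreeBeamPreset(cfg, center_amplitude = 0)
  expect_equal(axialPeriod(pre2, cfg), Inf)
  iA <- intensityAtPoints(pre2, cfg, pts, z = 0)
  iB <- intensityAtPoints(pre2, cfg, pts, z = 7.7)
  expect_equal(iA, iB, tolerance = 1e-10)
})

test_that("asymmetric side beams warn and produce beating contrast", {
  cfg <- defaultCfg()
  expect_warning(
    ig <- threeBeamAxialPattern(linearThreeBeamPreset(cfg,
                                                      asymmetry = 0.04),
                                cfg, nx = 384, nz = 6,
                                pixel_size = 0.03, z_pixel = 0.1),
    "beating|asymmetric")
  igs <- threeBeamAxialPattern(linearThreeBeamPreset(cfg), cfg, nx = 384,
                               nz = 6, pixel_size = 0.03, z_pixel = 0.1)
  # local fringe contrast across the field: range of per-window contrast
  rowContrasts <- function(v) {
    n <- length(v); w <- 48
    vapply(seq(1, n - w, by = w), function(i) {
      seg <- v[i:(i + w)]
      (max(seg) - min(seg)) / (max(seg) + min(seg))
    }, numeric(1))
  }
  ca <- rowContrasts(ig@values[3, ])
  cs <- rowContrasts(igs@values[3, ])
  # the asymmetric pattern's contrast varies across the field far more
  # than the symmetric one ("alternating bands of fringes and nodes")
  expect_gt(diff(range(ca)), 2 * diff(range(cs)))
})

test_that("galvo micro-rotation translates the pattern without changing it", {
  cfg <- defaultCfg()
  pre <- twoBeamPreset(cfg)
  d <- galvoStepForPhase(pre, cfg, pi / 2)
  f0 <- fitSinusoid2d(intensity(synthesizeField(pre, cfg, 96, 96, 0.04)))
  f1 <- fitSinusoid2d(intensity(synthesizeField(pre, cfg, 96, 96, 0.04,
                                                galvo_delta = d)))
  expect_equal(f0@visibility, f1@visibility, tolerance = 1e-9)
  expect_equal(f0@fringe_vector, f1@fringe_vector, tolerance = 1e-6)
  expect_equal(wrapToPi(f1@phase - f0@phase), pi / 2, tolerance = 1e-6)
})
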