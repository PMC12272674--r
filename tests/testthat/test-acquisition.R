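# Synthetic acquisition: phantoms, PSF, frame rendering, schedules.

test_that("bead phantoms are reproducible and respect separations", {
  p1 <- generateBeadPhantom(30, fov = 10, min_separation = 0.6, seed = 7)
  p2 <- generateBeadPhantom(30, fov = 10, min_separation = 0.6, seed = 7)
  expect_identical(p1@positions, p2@positions)
  expect_identical(p1@intensities, p2@intensities)
  d <- as.matrix(dist(p1@positions)); diag(d) <- Inf
  expect_gte(min(d), 0.6)
  # single bead is deterministic
  s1 <- generateBeadPhantom(1, fov = 5, seed = 3)
  expect_equal(nrow(s1@positions), 1)
  # infeasible packing errors out
  expect_error(generateBeadPhantom(500, fov = 2, min_separation = 0.5,
                                   seed = 1, max_tries = 200),
               "packing")
})

test_that("resolution pairs sit at the requested sub-diffraction spacing", {
  ph <- generateBeadPhantom(20, fov = 12, min_separation = 0.8, seed = 5,
                            n_pairs = 3, pair_separation_nm = 100,
                            pair_clearance = 1.5)
  n <- nrow(ph@positions)
  expect_equal(n, 26)
  for (k in 1:3) {
    a <- ph@positions[n - 2 * k + 1, ]
    b <- ph@positions[n - 2 * k + 2, ]
    expect_equal(sqrt(sum((a - b)^2)) * 1000, 100, tolerance = 1e-6)
    # clearance from all other beads
    ctr <- (a + b) / 2
    others <- ph@positions[seq_len(n - 6), , drop = FALSE]
    expect_gte(min(sqrt(rowSums(sweep(others, 2, ctr)^2))), 1.5)
  }
  # fixed pair axis
  ph2 <- generateBeadPhantom(5, fov = 8, seed = 2, n_pairs = 1,
                             pair_angle = 0)
  pp <- ph2@positions[(nrow(ph2@positions) - 1):nrow(ph2@positions), ]
  expect_equal(pp[1, 2], pp[2, 2], tolerance = 1e-12)
})

test_that("the detection PSF is normalized, symmetric and band-limited", {
  psf <- widefieldPsf(520, 1.333, 40)
  expect_equal(sum(psf), 1, tolerance = 1e-12)
  n <- nrow(psf)
  m <- matrix(psf, n, n)
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_equal(m, m[n:1, ], tolerance = 1e-12)
  # OTF is zero beyond 2 NA / lambda
  N <- 512
  otf <- Mod(stats::fft(galvoSIM:::padKernel(psf, N, N)))
  fr <- sqrt(outer(galvoSIM:::fftFreq(N)^2, galvoSIM:::fftFreq(N)^2,
                   "+")) / 0.04                       # cycles/um
  fc <- 2 * 1.333 / 0.52
  expect_lt(max(otf[fr > 1.05 * fc]), 1e-3)
  expect_gt(min(otf[fr < 0.5 * fc]), 0.05)
  # Airy core width ~0.51 lambda / NA on a fine grid
  psf_f <- widefieldPsf(520, 1.333, 4)
  v <- psf_f[(nrow(psf_f) + 1) / 2, ]
  fwhm <- sum(v > max(v) / 2) * 4
  expect_equal(fwhm, 0.51 * 520 / 1.333, tolerance = 0.05)
  expect_warning(widefieldPsf(520, 1.333, 200), "undersample")
})

test_that("rendered frames follow the image-formation contract", {
  cfg <- defaultCfg()
  camera <- cameraModel(roi = c(64, 64), offset = 100, read_noise = 1.6)
  psf <- detPsf()
  ph <- generateBeadPhantom(6, fov = 4, min_separation = 0.7, seed = 2)
  flat <- intensityGrid(matrix(1, 64, 64), 0.065)
  dark <- intensityGrid(matrix(0, 64, 64), 0.065)

  # zero illumination: offset plus read noise only
  img0 <- renderFrame(ph, dark, psf, camera, seed = 1)
  expect_equal(mean(img0), camera@offset, tolerance = 0.1)
  expect_equal(sd(img0), camera@read_noise / camera@gain, tolerance = 0.1)

  # noise off: deterministic, equals the blurred bead map
  imgA <- renderFrame(ph, flat, psf, camera, noise = FALSE)
  imgB <- renderFrame(ph, flat, psf, camera, noise = FALSE)
  expect_identical(imgA, imgB)
  expect_gt(max(imgA) - camera@offset, 100)

  # determinism under a fixed seed, difference under another
  n1 <- renderFrame(ph, flat, psf, camera, seed = 9)
  n2 <- renderFrame(ph, flat, psf, camera, seed = 9)
  n3 <- renderFrame(ph, flat, psf, camera, seed = 10)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("photon transfer: variance over mean tracks the camera gain", {
  cfg <- defaultCfg()
  for (g in c(1, 2)) {
    camera <- cameraModel(roi = c(64, 64), offset = 0, read_noise = 0,
                          gain = g)
    psf <- detPsf()
    # one large dim bead gives a near-uniform central region
    ph <- new("BeadPhantom", positions = matrix(0, 1, 2),
              intensities = 1, bead_diameter = 6000, fov = c(4.2, 4.2),
              seed = 1L)
    flat <- intensityGrid(matrix(1, 64, 64), 0.065)
    imgs <- lapply(1:6, function(s)
      renderFrame(ph, flat, psf, camera, exposure_scale = 2000,
                  seed = s)[27:38, 27:38])
    px <- do.call(cbind, lapply(imgs, as.numeric))
    vm <- mean(apply(px, 1, var) / rowMeans(px))
    expect_equal(vm, 1 / g, tolerance = 0.15)
  }
})

test_that("sinusoidal illumination modulates beads by V times the OTF ratio", {
  # noise-free render of an isolated bead under three phase-stepped
  # fringes: measured modulation equals V * OTF(k) / OTF(0) with the
  # OTF ratio computed numerically from the same PSF kernel (and the
  # bead's own spot transform)
  cfg <- defaultCfg()
  camera <- cameraModel(roi = c(96, 96), offset = 0)
  psf <- detPsf(1.42)
  ph <- new("BeadPhantom", positions = matrix(c(0.013, -0.007), 1, 2),
            intensities = 1, bead_diameter = 100, fov = c(6.2, 6.2),
            seed = 1L)
  pre <- twoBeamPreset(cfg, orientation = 0, radius_frac = 0.6,
                       amplitudes = c(1, 0.6))
  V <- theoreticalVisibility(c(1, 0.6), 1)
  k_um <- 2 * 0.6 * cfg@effective_NA / (cfg@wavelength * 1e-3)
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  tots <- vapply(phases, function(p) {
    d <- galvoStepForPhase(pre, cfg, p)
    ill <- illuminationOnCamera(pre, cfg, camera, galvo_delta = d)
    sum(renderFrame(ph, ill, psf, camera, noise = FALSE))
  }, numeric(1))
  # total flux modulation: offset a, modulation m from the 3-point DFT
  a <- mean(tots)
  m <- 2 * Mod(mean(tots * exp(-1i * phases))) / a
  # expected attenuation: bead spot transform at the fringe frequency
  sigma <- 0.025   # um (d/4)
  expect_equal(m, V * exp(-(2 * pi * k_um * sigma)^2 / 2),
               tolerance = 0.02)
})

test_that("schedule frame counts and rates match the acquisition design", {
  s <- simCycleSchedule()
  st <- scheduleStats(s)
  expect_equal(st$frames_per_cycle, 11)
  expect_equal(st$final_rate_fps, 89L)
  s2 <- simCycleSchedule(n_orientations = 1, n_phases = 1,
                         raw_frame_rate = 500)
  expect_equal(scheduleStats(s2)$final_rate, 500)
  # 15 single-frame positions at 3252 fps cycle at 216.8 fps
  s3 <- simCycleSchedule(n_orientations = 3, n_phases = 5,
                         raw_frame_rate = 3252, orientation_dwell = 1)
  expect_equal(nrow(s3@entries), 15)
  expect_equal(scheduleStats(s3)$final_rate, 3252 / 15, tolerance = 1e-9)
  # sweep: 15 positions, several frames each
  sw <- sweepSchedule(frames_per_position = 4)
  expect_equal(nrow(sw@entries), 15)
  expect_equal(scheduleStats(sw)$frames_per_cycle, 60)
})

test_that("running a schedule produces flagged transition frames", {
  cfg <- defaultCfg()
  camera <- smallCamera(48)
  psf <- detPsf()
  ph <- generateBeadPhantom(10, fov = 3, min_separation = 0.4, seed = 4)
  st <- runSchedule(ph, simPresets(cfg), simCycleSchedule(), cfg, camera,
                    psf, seed = 6, n_cycles = 2)
  meta <- frameMeta(st)
  expect_equal(dim(frames(st))[3], 22)
  # 11-frame cycles: transition frames at each orientation change, none
  # at the first frame of either cycle (direction alternation)
  expect_equal(sum(meta$transition[meta$cycle == 1]), 2)
  expect_false(meta$transition[1])
  expect_false(meta$transition[12])
  # single-entry schedule: no flags
  s1 <- simCycleSchedule(n_orientations = 1, n_phases = 1)
  st1 <- runSchedule(ph, simPresets(cfg)[1], s1, cfg, camera, psf,
                     seed = 6)
  expect_false(any(frameMeta(st1)$transition))
  # determinism
  stA <- runSchedule(ph, simPresets(cfg), simCycleSchedule(), cfg, camera,
                     psf, seed = 6)
  stB <- runSchedule(ph, simPresets(cfg), simCycleSchedule(), cfg, camera,
                     psf, seed = 6)
  expect_identical(frames(stA), frames(stB))
})
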