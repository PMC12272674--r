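# SIM reconstruction: band separation, parameter estimation, Wiener
# recombination, widefield deconvolution and FRC.

makeAnalyticFrames <- function(S, p, m, phases, px = 0.065,
                               psf = detPsf(1.42)) {
  ny <- nrow(S); nx <- ncol(S)
  x <- (0:(nx - 1)) * px; y <- (0:(ny - 1)) * px
  arg <- outer(2 * pi * p[2] * y, 2 * pi * p[1] * x, "+")
  lapply(phases, function(ph)
    galvoSIM:::fftConvolve(S * (1 + m * cos(arg + ph)), psf))
}

test_that("band separation inverts the forward mixing model exactly", {
  set.seed(7)
  ny <- nx <- 64; px <- 0.065
  S <- matrix(rnorm(ny * nx, 100, 10), ny, nx)
  p <- c(3.2, 1.1)
  m <- 0.8
  phases <- 0.3 + c(0, 2 * pi / 3, 4 * pi / 3)
  x <- (0:(nx - 1)) * px; y <- (0:(ny - 1)) * px
  arg <- outer(2 * pi * p[2] * y, 2 * pi * p[1] * x, "+")
  frames <- lapply(phases, function(ph) S * (1 + m * cos(arg + ph)))
  b <- separateBands(frames, phases)
  bp_true <- stats::fft(S * m * exp(1i * arg))
  relerr <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
  expect_lt(relerr(b$b0, stats::fft(S)), 1e-8)
  expect_lt(relerr(b$bp, bp_true), 1e-8)
  # conjugate mirror symmetry for real frames
  mirror <- function(M) {
    M2 <- Conj(M)[c(1, ny:2), ]
    M2[, c(1, nx:2)]
  }
  expect_lt(max(Mod(b$bm - mirror(b$bp))), 1e-6 * max(Mod(b$bp)))
  # zero modulation: order +/-1 bands vanish
  b0only <- separateBands(lapply(phases, function(ph) S), phases)
  expect_lt(max(Mod(b0only$bp)), 1e-8 * max(Mod(b0only$b0)))
  # degenerate phases are rejected
  expect_error(separateBands(frames, c(1, 1, 1)), "singular")
})

test_that("pattern parameters are recovered from simulated stacks", {
  cfg <- defaultCfg()
  st <- denseLayerStack(simCycleSchedule(), seed = 17, n = 128,
                        n_beads = 1200, exposure_scale = 3000)
  sp <- estimateSimParams(st)
  true_f <- 2 * 0.85 * cfg@effective_NA / (cfg@wavelength * 1e-3)
  true_ang <- c(0, 60, 120)
  for (o in 1:3) {
    f <- sp@orientations[[o]]$fringe_vector
    expect_equal(sqrt(sum(f^2)), true_f, tolerance = 0.005)
    expect_lt(axisAngleErr(atan2(f[2], f[1]) * 180 / pi, true_ang[o]),
              0.25)
    expect_length(sp@orientations[[o]]$phases, 3)
  }
  # two orientations 60 degrees apart are recovered as such
  a1 <- atan2(sp@orientations[[1]]$fringe_vector[2],
              sp@orientations[[1]]$fringe_vector[1]) * 180 / pi
  a2 <- atan2(sp@orientations[[2]]$fringe_vector[2],
              sp@orientations[[2]]$fringe_vector[1]) * 180 / pi
  expect_lt(abs(axisAngleErr(a1, a2) - 60), 0.3)
})

test_that("widefield-only stacks fail parameter estimation", {
  cfg <- defaultCfg()
  camera <- smallCamera(96)
  psf <- detPsf()
  ph <- generateBeadPhantom(300, fov = 6, min_separation = 0.15,
                            seed = 3)
  presets <- lapply(simPresets(cfg), function(p) {
    p@beams <- p@beams[1]   # single beam: uniform illumination, V = 0
    p
  })
  st <- runSchedule(ph, presets, simCycleSchedule(delta_per_phase = 0),
                    cfg, camera, psf, seed = 5)
  expect_error(estimateSimParams(st), "estimation failure")
})

test_that("Wiener recombination halves the effective PSF width", {
  cfg <- defaultCfg()
  px <- 0.065
  ny <- nx <- 128
  S <- matrix(0, ny, nx); S[64, 64] <- 1000
  k0 <- 2 * 0.85 * cfg@effective_NA / (cfg@wavelength * 1e-3)
  pv <- list(c(k0, 0), k0 * c(cos(pi / 3), sin(pi / 3)),
             k0 * c(cos(2 * pi / 3), sin(2 * pi / 3)))
  blist <- list(); orients <- list()
  for (o in 1:3) {
    phases <- c(0, 2 * pi / 3, 4 * pi / 3) + 0.2 * o
    frames <- makeAnalyticFrames(S, pv[[o]], 0.9, phases)
    blist[[o]] <- separateBands(frames, phases)
    orients[[o]] <- list(fringe_vector = pv[[o]], phases = phases,
                         modulation = 0.9)
  }
  params <- new("SimParams", orientations = orients)
  rec <- wienerReconstruct(blist, params, 520, 1.42, wiener_w = 0.02,
                           pixel_size = px)
  wf <- deconvolveWidefield(galvoSIM:::fftConvolve(S, detPsf(1.42)),
                            520, 1.42, 0.02, pixel_size = px)
  fwhmOf <- function(v, dx) sum(v - min(v) > (max(v) - min(v)) / 2) * dx
  fw_rec <- fwhmOf(rec@values[127, 107:147], px / 2 * 1000)
  fw_wf <- fwhmOf(wf@values[64, 54:74], px * 1000)
  expect_lt(fw_rec, 0.62 * fw_wf)
  # output is nonnegative on the 2x grid
  expect_true(all(rec@values >= 0))
  expect_equal(dim(rec@values), c(2 * ny, 2 * nx))
})

test_that("zero modulation reduces the pipeline to Wiener widefield", {
  set.seed(8)
  ny <- nx <- 64; px <- 0.065
  S <- matrix(0, ny, nx)
  S[cbind(sample(10:54, 12), sample(10:54, 12))] <- 500
  img <- galvoSIM:::fftConvolve(S, detPsf(1.42))
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  b <- separateBands(lapply(phases, function(p) img), phases)
  params <- new("SimParams", orientations = list(
    list(fringe_vector = c(3, 0), phases = phases, modulation = 0)))
  rec <- wienerReconstruct(list(b), params, 520, 1.42, wiener_w = 0.05,
                           apodize = FALSE, pixel_size = px)
  wf <- deconvolveWidefield(img, 520, 1.42, 0.05, pixel_size = px)
  # compare on the common (camera) grid: every other pixel of the 2x map
  rec_ds <- rec@values[seq(1, 2 * ny, 2), seq(1, 2 * nx, 2)]
  expect_gt(cor(as.numeric(rec_ds), as.numeric(wf@values)), 0.99)
})

test_that("widefield Wiener deconvolution behaves at its limits", {
  set.seed(9)
  # beads on a background keep the Wiener estimate positive, so the
  # limit properties are not confounded by negativity clamping
  S <- matrix(40, 64, 64)
  S[cbind(sample(10:54, 10), sample(10:54, 10))] <- 300
  img <- galvoSIM:::fftConvolve(S, detPsf(1.333))
  dec <- deconvolveWidefield(img, 520, 1.333, 0.02, pixel_size = 0.065)
  # energy approximately preserved (DC gain 1/(1+w))
  expect_equal(sum(dec@values), sum(img), tolerance = 0.05)
  # re-blurring the deconvolved image approximates the original
  reblur <- galvoSIM:::fftConvolve(dec@values, detPsf(1.333))
  expect_gt(cor(as.numeric(reblur), as.numeric(img)), 0.98)
  # huge regularization degenerates to a (scaled) OTF-filtered copy of
  # the input
  dec2 <- deconvolveWidefield(img, 520, 1.333, 1e6, pixel_size = 0.065)
  reblur2 <- galvoSIM:::fftConvolve(img, detPsf(1.333))
  expect_gt(cor(as.numeric(dec2@values), as.numeric(reblur2)), 0.9999)
  expect_gt(cor(as.numeric(dec2@values), as.numeric(img)), 0.9)
})

test_that("frequency-domain intermediates keep conjugate symmetry", {
  st <- denseLayerStack(simCycleSchedule(), seed = 19, n = 96,
                        n_beads = 600, exposure_scale = 3000)
  meta <- frameMeta(st)
  idx <- which(meta$orientation == 1 & !meta$transition)
  fr <- lapply(idx, function(i) st@frames[, , i])
  b <- separateBands(fr, (seq_along(idx) - 1) * 2 * pi / 3)
  ny <- 96; nx <- 96
  mirror <- function(M) {
    M2 <- Conj(M)[c(1, ny:2), ]
    M2[, c(1, nx:2)]
  }
  expect_lt(max(Mod(b$b0 - mirror(b$b0))), 1e-6 * max(Mod(b$b0)))
  expect_lt(max(Mod(b$bm - mirror(b$bp))), 1e-6 * max(Mod(b$bp)))
})

test_that("FRC is exact for identical and independent images", {
  set.seed(10)
  a <- matrix(rnorm(96^2), 96, 96)
  f_same <- frcCurve(a, a, pixel_size = 0.065)
  expect_true(all(abs(f_same@frc - 1) < 1e-9))
  expect_equal(frcResolution(f_same), 130)   # 2-pixel Nyquist floor
  b <- matrix(rnorm(96^2), 96, 96)
  f_ind <- frcCurve(a, b, pixel_size = 0.065)
  expect_lt(mean(abs(f_ind@frc[-(1:2)])), 0.15)
  expect_error(frcCurve(a, b[1:32, 1:32], pixel_size = 0.065), "shape")
})

test_that("SIM reconstructions beat deconvolved widefield in FRC", {
  # two consecutive noisy cycles reconstructed independently: the FRC
  # resolution of the SIM pair must improve on the widefield pair
  st <- denseLayerStack(simCycleSchedule(n_phases = 5,
                                         phase_step = 2 * pi / 5),
                        seed = 23, n = 128, n_beads = 700,
                        exposure_scale = 3000, n_cycles = 2,
                        radius_frac = 0.85)
  meta <- frameMeta(st)
  recOf <- function(cyc) {
    sub <- new("FrameStack",
               frames = st@frames[, , meta$cycle == cyc, drop = FALSE],
               meta = meta[meta$cycle == cyc, ],
               pixel_size = st@pixel_size, seed = st@seed)
    reconstructSim(sub, NA_det = 1.42, wiener_w = 0.02)
  }
  r1 <- recOf(1); r2 <- recOf(2)
  frc_sim <- frcCurve(r1$image, r2$image)
  wf1 <- deconvolveWidefield(r1$widefield, 520, 1.42, 0.02)
  wf2 <- deconvolveWidefield(r2$widefield, 520, 1.42, 0.02)
  frc_wf <- frcCurve(wf1, wf2)
  expect_lt(frcResolution(frc_sim), frcResolution(frc_wf))
})
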