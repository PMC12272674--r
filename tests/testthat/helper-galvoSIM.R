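# Shared fixtures and small utilities for the test suite. Everything is
# generated in code; no data files.

defaultCfg <- function() opticalConfig()

`%||%` <- function(a, b) if (is.null(a)) b else a

smallCamera <- function(n = 128) cameraModel(roi = c(n, n))

detPsf <- function(NA_det = 1.42, px = 65) widefieldPsf(520, NA_det, px)

# absolute angular difference between two axis angles (degrees, mod 180)
axisAngleErr <- function(a, b) {
  d <- (a - b) %% 180
  min(d, 180 - d)
}

# bilinear sample of an image at a continuous centered coordinate (um)
bilinAt <- function(im, px, pt) {
  noff <- floor(nrow(im) / 2) + 1
  fx <- pt[1] / px + noff
  fy <- pt[2] / px + noff
  x0 <- floor(fx); y0 <- floor(fy)
  tx <- fx - x0; ty <- fy - y0
  (1 - ty) * ((1 - tx) * im[y0, x0] + tx * im[y0, x0 + 1]) +
    ty * ((1 - tx) * im[y0 + 1, x0] + tx * im[y0 + 1, x0 + 1])
}

# profile through a bead pair and its saddle-to-peak ratio (< 1 means the
# two beads are resolved with a dip between them)
pairDipRatio <- function(im, px, p1, p2) {
  ctr <- (p1 + p2) / 2
  dr <- (p1 - p2) / sqrt(sum((p1 - p2)^2))
  sep <- sqrt(sum((p1 - p2)^2))
  ts <- seq(-1.2 * sep, 1.2 * sep, length.out = 97)
  pr <- vapply(ts, function(t) bilinAt(im, px, ctr + t * dr), numeric(1))
  pk1 <- max(pr[ts < -0.2 * sep & ts > -0.9 * sep])
  pk2 <- max(pr[ts > 0.2 * sep & ts < 0.9 * sep])
  sad <- min(pr[abs(ts) <= 0.3 * sep])
  sad / min(pk1, pk2)
}

# dense bead-layer stack under the default three orientations, as used by
# the characterization analyses (mirrors a uniformly bead-coated
# coverslip)
denseLayerStack <- function(schedule, seed = 1, n = 192, n_beads = 3000,
                            exposure_scale = 5000, radius_frac = 0.85,
                            NA_det = 1.42, noise = TRUE, n_cycles = 1,
                            noise_seed = seed + 1000) {
  cfg <- defaultCfg()
  camera <- smallCamera(n)
  psf <- detPsf(NA_det)
  phantom <- generateBeadPhantom(n_beads, fov = n * 0.065,
                                 min_separation = 0.08, seed = seed)
  runSchedule(phantom, simPresets(cfg, radius_frac = radius_frac),
              schedule, cfg, camera, psf,
              exposure_scale = exposure_scale, seed = noise_seed,
              n_cycles = n_cycles, noise = noise)
}

# per-orientation recovered consecutive phase steps from a trace
recoveredSteps <- function(trace, meta, orientation) {
  idx <- which(meta$orientation == orientation & !meta$transition)
  idx <- idx[!duplicated(meta$phase_index[idx])]
  diff(trace@phase[idx])
}

wrapToPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

wrap2Pi <- function(x) x %% (2 * pi)
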