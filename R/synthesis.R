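# Coherent field synthesis: vector superposition of the preset's transported
# plane waves on sample-plane grids, intensity formation, and the axial
# (x-z) pattern of linear three-beam presets.

# Per-beam precomputation: wavevector, transported polarization, total phase.
beamWaves <- function(preset, cfg, galvo_delta = 0) {
  lapply(preset@beams, function(b) {
    k <- pupilToWavevector(b, cfg)
    pol <- transportPolarization(b@jones, k)
    ph <- b@phase + galvoPhase(galvo_delta, b@lens_offset_x, cfg)
    list(k = k, pol = pol, amp = b@amplitude, phase = ph)
  })
}

# Smallest pairwise fringe period (um) of a wave set; Inf for single beams.
minFringePeriod <- function(waves) {
  n <- length(waves)
  if (n < 2) return(Inf)
  per <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dk <- waves[[i]]$k[1:2] - waves[[j]]$k[1:2]
    m <- sqrt(sum(dk^2))
    if (m > 1e-12) per <- min(per, 2 * pi / m)
  }
  per
}

#' Synthesize the interference field on a grid
#'
#' Coherent sum of the preset's transported plane waves,
#' \eqn{E(r) = \sum_j A_j \hat{p}_j \exp(i(k_j \cdot r + \phi_j))},
#' evaluated on a centered sample-plane grid at axial position \code{z}.
#' A galvo micro-rotation \code{galvo_delta} advances each beam's phase
#' through the galvo phase model, translating the pattern without changing
#' its structure.
#'
#' @param preset a \linkS4class{PatternPreset}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param nx,ny grid size in pixels.
#' @param pixel_size pixel pitch, um. Must be smaller than half the
#'   smallest fringe period (sampling condition).
#' @param z axial position, um.
#' @param galvo_delta galvo micro-rotation, rad.
#' @return An \linkS4class{InterferenceField}.
#' @examples
#' cfg <- opticalConfig()
#' f <- synthesizeField(twoBeamPreset(cfg), cfg, nx = 64, ny = 64,
#'                      pixel_size = 0.02)
#' intensity(f)
#' @export
synthesizeField <- function(preset, cfg, nx = 256, ny = 256,
                            pixel_size = 0.065, z = 0, galvo_delta = 0) {
  waves <- beamWaves(preset, cfg, galvo_delta)
  per <- minFringePeriod(waves)
  if (pixel_size >= per / 2)
    stop(sprintf(
      "undersampled grid: pixel %.1f nm >= half fringe period %.1f nm",
      1000 * pixel_size, 500 * per))
  x <- axisCoords(nx, pixel_size)
  y <- axisCoords(ny, pixel_size)
  vals <- array(0 + 0i, dim = c(ny, nx, 3))
  for (w in waves) {
    ey <- exp(1i * w$k[2] * y)
    ex <- exp(1i * (w$k[1] * x + w$k[3] * z + w$phase))
    ph <- outer(ey, ex)           # [ny, nx] phase factor
    for (cmp in 1:3)
      vals[, , cmp] <- vals[, , cmp] + w$amp * w$pol[cmp] * ph
  }
  new("InterferenceField", values = vals, pixel_size = pixel_size, z = z)
}

#' Evaluate field or intensity at arbitrary points
#'
#' Point-wise version of [synthesizeField()] for property checks (e.g.
#' rotational symmetry) that need off-grid sampling.
#'
#' @param preset a \linkS4class{PatternPreset}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param points n x 2 matrix of (x, y) sample positions, um.
#' @param z axial position, um.
#' @param galvo_delta galvo micro-rotation, rad.
#' @return Complex n x 3 matrix of field components.
#' @export
fieldAtPoints <- function(preset, cfg, points, z = 0, galvo_delta = 0) {
  points <- rbind(points)
  waves <- beamWaves(preset, cfg, galvo_delta)
  out <- matrix(0 + 0i, nrow(points), 3)
  for (w in waves) {
    ph <- exp(1i * (points[, 1] * w$k[1] + points[, 2] * w$k[2] +
                      z * w$k[3] + w$phase))
    out <- out + w$amp * outer(ph, w$pol)
  }
  out
}

#' @rdname fieldAtPoints
#' @export
intensityAtPoints <- function(preset, cfg, points, z = 0, galvo_delta = 0) {
  e <- fieldAtPoints(preset, cfg, points, z, galvo_delta)
  rowSums(Mod(e)^2)
}

#' @rdname intensity
#' @export
setMethod("intensity", "InterferenceField", function(x) {
  v <- x@values
  ig <- Mod(v[, , 1])^2 + Mod(v[, , 2])^2 + Mod(v[, , 3])^2
  intensityGrid(ig, x@pixel_size, z = x@z)
})

#' Axial (x-z) intensity pattern of a three-beam preset
#'
#' Evaluates the intensity on an x-z grid (y = 0). Linear three-beam
#' patterns are periodic along z with period
#' \eqn{2\pi/(k_{z,\mathrm{center}} - k_{z,\mathrm{side}})}; with zero
#' center amplitude the pattern is z-invariant. If the two side beams are
#' not symmetric about the axis, a warning is issued: asymmetric side beams
#' beat against each other and produce alternating bands of fringes and
#' nodes across the field.
#'
#' @param preset a \linkS4class{PatternPreset} (center + two side beams).
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param nx,nz grid size in pixels.
#' @param pixel_size lateral pixel pitch, um.
#' @param z_pixel axial pitch, um.
#' @return An \linkS4class{IntensityGrid} with values \code{[nz, nx]} and
#'   \code{z} coordinates set.
#' @export
threeBeamAxialPattern <- function(preset, cfg, nx = 256, nz = 128,
                                  pixel_size = 0.03, z_pixel = 0.05) {
  waves <- beamWaves(preset, cfg)
  kt <- t(vapply(waves, function(w) w$k[1:2], numeric(2)))
  side <- which(rowSums(kt^2) > 1e-12)
  if (length(side) >= 2) {
    mism <- sqrt(sum((kt[side[1], ] + kt[side[2], ])^2)) /
      sqrt(sum(kt[side[1], ]^2))
    if (mism > 1e-6)
      warning("asymmetric side beams: expect beating of fringe contrast ",
              "across the field")
  }
  x <- axisCoords(nx, pixel_size)
  zc <- axisCoords(nz, z_pixel)
  vals <- matrix(0, nz, nx)
  for (iz in seq_len(nz)) {
    pts <- cbind(x, 0)
    vals[iz, ] <- intensityAtPoints(preset, cfg, pts, z = zc[iz])
  }
  intensityGrid(vals, pixel_size, z = zc)
}

#' Axial period of a linear three-beam pattern
#'
#' \eqn{2\pi/(k_{z,\mathrm{center}} - k_{z,\mathrm{side}})} in um.
#'
#' @param preset a \linkS4class{PatternPreset} with an on-axis center beam.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @return Axial period in um (Inf for z-invariant presets).
#' @export
axialPeriod <- function(preset, cfg) {
  waves <- beamWaves(preset, cfg)
  waves <- waves[vapply(waves, function(w) w$amp > 0, logical(1))]
  kz <- vapply(waves, function(w) w$k[3], numeric(1))
  dkz <- max(kz) - min(kz)
  if (dkz < 1e-12) return(Inf)
  2 * pi / dkz
}
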