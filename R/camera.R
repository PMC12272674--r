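# Image formation and acquisition scheduling: rendering camera frames of a
# bead phantom under patterned illumination with Poisson + read noise, and
# running galvo schedules with settling-time (transition-frame) modelling.

#' Illumination pattern sampled on the camera grid
#'
#' Convenience wrapper around [synthesizeField()] that evaluates a preset's
#' intensity on the grid defined by a \linkS4class{CameraModel}.
#'
#' @param preset a \linkS4class{PatternPreset}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param camera a \linkS4class{CameraModel}.
#' @param galvo_delta galvo micro-rotation, rad.
#' @param z axial position, um.
#' @return An \linkS4class{IntensityGrid} matching the camera ROI.
#' @export
illuminationOnCamera <- function(preset, cfg, camera, galvo_delta = 0,
                                 z = 0) {
  px <- camera@pixel_size_sample / 1000
  f <- synthesizeField(preset, cfg, nx = camera@roi[2], ny = camera@roi[1],
                       pixel_size = px, z = z, galvo_delta = galvo_delta)
  intensity(f)
}

# Render the bead map (pre-PSF fluorophore distribution x illumination) on
# the camera grid. Beads are Gaussian spots whose width matches the
# projected profile of a solid sphere of the stated diameter
# (sigma = d/4), weighted by the illumination intensity at the bead
# center.
beadMap <- function(phantom, illum_values, px_um, ny, nx) {
  x <- axisCoords(nx, px_um)
  y <- axisCoords(ny, px_um)
  sigma <- max(phantom@bead_diameter / 1000 / 4, px_um / 4)
  half <- max(2L, ceiling(4 * sigma / px_um))
  out <- matrix(0, ny, nx)
  for (i in seq_len(nrow(phantom@positions))) {
    p <- phantom@positions[i, ]
    ix <- round((p[1] - x[1]) / px_um) + 1
    iy <- round((p[2] - y[1]) / px_um) + 1
    if (ix < 1 - half || ix > nx + half || iy < 1 - half || iy > ny + half)
      next
    xr <- max(1, ix - half):min(nx, ix + half)
    yr <- max(1, iy - half):min(ny, iy + half)
    if (!length(xr) || !length(yr)) next
    gx <- exp(-(x[xr] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(y[yr] - p[2])^2 / (2 * sigma^2))
    # illumination sampled at the true bead center (bilinear): rounding to
    # the pixel grid would shift the fringe-encoded bead position by up to
    # half a pixel
    fx <- (p[1] - x[1]) / px_um; fy <- (p[2] - y[1]) / px_um
    jx0 <- min(max(floor(fx) + 1, 1), nx - 1)
    jy0 <- min(max(floor(fy) + 1, 1), ny - 1)
    tx <- min(max(fx - (jx0 - 1), 0), 1)
    ty <- min(max(fy - (jy0 - 1), 0), 1)
    iv <- (1 - ty) * ((1 - tx) * illum_values[jy0, jx0] +
                        tx * illum_values[jy0, jx0 + 1]) +
      ty * ((1 - tx) * illum_values[jy0 + 1, jx0] +
              tx * illum_values[jy0 + 1, jx0 + 1])
    w <- phantom@intensities[i] * iv
    out[yr, xr] <- out[yr, xr] + w * outer(gy, gx)
  }
  out
}

# Bead (dye-density) mask on an os-times oversampled grid, matching the
# Fourier-upsampling sample positions x_i + (j-1)*px/os. No illumination
# weighting: the emission is formed as the pointwise product with the
# exactly upsampled illumination.
beadMapFine <- function(phantom, px_um, ny, nx, os) {
  pxf <- px_um / os
  nyf <- ny * os; nxf <- nx * os
  x <- axisCoords(nx, px_um); y <- axisCoords(ny, px_um)
  sub <- (seq_len(os) - 1) * pxf
  xf <- rep(x, each = os) + sub
  yf <- rep(y, each = os) + sub
  sigma <- max(phantom@bead_diameter / 1000 / 4, pxf / 4)
  half <- max(2L, ceiling(4 * sigma / pxf))
  out <- matrix(0, nyf, nxf)
  for (i in seq_len(nrow(phantom@positions))) {
    p <- phantom@positions[i, ]
    ix <- round((p[1] - xf[1]) / pxf) + 1
    iy <- round((p[2] - yf[1]) / pxf) + 1
    if (ix < 1 - half || ix > nxf + half || iy < 1 - half ||
        iy > nyf + half) next
    xr <- max(1, ix - half):min(nxf, ix + half)
    yr <- max(1, iy - half):min(nyf, iy + half)
    if (!length(xr) || !length(yr)) next
    gx <- exp(-(xf[xr] - p[1])^2 / (2 * sigma^2))
    gy <- exp(-(yf[yr] - p[2])^2 / (2 * sigma^2))
    out[yr, xr] <- out[yr, xr] +
      phantom@intensities[i] * outer(gy, gx) / os^2
  }
  out
}

# Block-mean binning of an (ny*os) x (nx*os) matrix down to ny x nx,
# times os^2 (i.e. block sums): integrates fine-grid flux per camera
# pixel.
binBlocks <- function(m, os) {
  a <- matrix(colSums(matrix(m, nrow = os)), nrow = nrow(m) / os)
  t(matrix(colSums(matrix(t(a), nrow = os)), nrow = ncol(a) / os))
}

#' Render one camera frame
#'
#' Image formation model: fluorescence emission proportional to the local
#' illumination intensity at each bead, blurred by the detection PSF,
#' scaled to expected photoelectrons, then Poisson shot noise plus Gaussian
#' read noise, conversion to counts, quantization and clipping to the
#' camera bit depth. With \code{noise = FALSE} the expected-count image is
#' returned deterministically (no quantization).
#'
#' @param phantom a \linkS4class{BeadPhantom}.
#' @param illumination an \linkS4class{IntensityGrid} on the camera grid
#'   (same ROI and pixel pitch).
#' @param psf detection PSF kernel from [widefieldPsf()] (same pixel pitch
#'   as the camera).
#' @param camera a \linkS4class{CameraModel}.
#' @param exposure_scale expected peak photoelectrons per unit
#'   bead-brightness-times-illumination (photon budget knob).
#' @param seed integer seed for the noise; required when \code{noise} is
#'   TRUE.
#' @param noise logical, apply shot/read noise and quantization.
#' @param oversample integer sub-pixel oversampling factor for the optical
#'   rendering. Sub-diffraction bead spots are narrower than a camera
#'   pixel, so they are rasterized and blurred on a finer grid and then
#'   integrated over each camera pixel; rendering at the camera pitch
#'   directly would alias the spot spectrum and shift apparent bead
#'   positions by tens of nanometres. Requires the PSF to carry the
#'   attributes set by [widefieldPsf()].
#' @return Numeric matrix of counts \code{[ny, nx]}; attribute
#'   \code{saturated} carries the saturated-pixel fraction and a
#'   \code{saturation} warning fires above 1 percent.
#' @export
renderFrame <- function(phantom, illumination, psf, camera,
                        exposure_scale = 2000, seed = NULL, noise = TRUE,
                        oversample = 2) {
  ny <- camera@roi[1]; nx <- camera@roi[2]
  iv <- illumination@values
  if (!all(dim(iv)[1:2] == c(ny, nx)))
    stop("illumination grid does not match the camera ROI")
  px_um <- camera@pixel_size_sample / 1000
  if (abs(illumination@pixel_size - px_um) > 1e-9)
    stop("illumination pixel size does not match the camera")
  os <- as.integer(oversample)
  if (os > 1 && !is.null(attr(psf, "wavelength"))) {
    psf_f <- widefieldPsf(attr(psf, "wavelength"), attr(psf, "NA"),
                          camera@pixel_size_sample / os)
    # emission = dye density x illumination, both on the fine grid; the
    # illumination (a finite sum of plane-wave fringes) is band-limited,
    # so its Fourier upsampling is exact
    ivf <- upsampleFourier(iv, os)
    ivf[ivf < 0] <- 0
    bm <- beadMapFine(phantom, px_um, ny, nx, os)
    fine <- fftConvolve(bm * ivf, psf_f)
    # integrate the fine grid over each camera pixel
    expected <- binBlocks(fine, os) * exposure_scale
  } else {
    bm <- beadMap(phantom, iv, px_um, ny, nx)
    expected <- fftConvolve(bm, psf) * exposure_scale
  }
  expected[expected < 0] <- 0
  toCounts <- function(e_electrons) {
    counts <- e_electrons / camera@gain + camera@offset
    cmax <- 2^camera@bit_depth - 1
    counts <- pmin(pmax(counts, 0), cmax)
    counts
  }
  if (!noise) {
    img <- toCounts(expected)
  } else {
    if (is.null(seed)) stop("seed required when noise = TRUE")
    img <- withSeed(seed, {
      e <- stats::rpois(length(expected), expected) +
        stats::rnorm(length(expected), 0, camera@read_noise)
      matrix(e, ny, nx)
    })
    img <- round(toCounts(img))
  }
  cmax <- 2^camera@bit_depth - 1
  sat <- mean(img >= cmax)
  if (sat > 0.01)
    warning(sprintf("saturation: %.1f%% of pixels at full scale", 100 * sat))
  attr(img, "saturated") <- sat
  img
}

# ---------------------------------------------------------------------------
# Schedules
# ---------------------------------------------------------------------------

#' SIM acquisition cycle schedule
#'
#' The fast 2D-SIM cycle: \code{n_phases} phase steps for each of
#' \code{n_orientations} orientations, visited as one galvo position per
#' frame, with the first phase of every orientation after the first held
#' for \code{orientation_dwell} frames to ride out the slower orientation
#' transition. The default (3 x 3 with 2-frame dwell at a 980 fps raw rate)
#' takes 11 raw frames per cycle, a 89 fps final rate.
#'
#' @param n_orientations number of pattern orientations.
#' @param n_phases phase steps per orientation.
#' @param phase_step fringe phase increment per step, rad.
#' @param raw_frame_rate raw camera frame rate, fps.
#' @param orientation_dwell frames spent at the first phase of orientations
#'   after an orientation change.
#' @param base_angles coarse galvo angle per orientation, rad.
#' @param delta_per_phase galvo micro-rotation per phase step, rad; when
#'   NULL it is derived at run time from the preset via
#'   [galvoStepForPhase()] and \code{phase_step} is stored as metadata.
#' @param alternate_direction alternate traversal direction between cycles.
#' @param orientation_settle orientation-change settling time, s.
#' @param phase_settle phase-step settling time, s.
#' @return A \linkS4class{GalvoSchedule}.
#' @examples
#' scheduleStats(simCycleSchedule())
#' @export
simCycleSchedule <- function(n_orientations = 3, n_phases = 3,
                             phase_step = 2 * pi / n_phases,
                             raw_frame_rate = 980, orientation_dwell = 2,
                             base_angles = NULL, delta_per_phase = NULL,
                             alternate_direction = TRUE,
                             orientation_settle = 0.9e-3,
                             phase_settle = 5e-5) {
  if (is.null(base_angles))
    base_angles <- (seq_len(n_orientations) - 1) * 17.5e-3
  rows <- do.call(rbind, lapply(seq_len(n_orientations), function(o) {
    data.frame(orientation = o, phase_index = seq_len(n_phases),
               n_frames = c(if (o > 1) orientation_dwell else 1,
                            rep(1, n_phases - 1)))
  }))
  rows$phase <- (rows$phase_index - 1) * phase_step
  rows$delta_angle <- if (is.null(delta_per_phase)) NA_real_ else
    (rows$phase_index - 1) * delta_per_phase
  attr(rows, "phase_step") <- phase_step
  new("GalvoSchedule", entries = rows, base_angles = base_angles,
      raw_frame_rate = raw_frame_rate,
      alternate_direction = alternate_direction,
      orientation_settle = orientation_settle, phase_settle = phase_settle)
}

#' Characterization sweep schedule
#'
#' The pattern-stability sweep: \code{n_orientations} orientations times
#' \code{n_phases} galvo positions each (15 by default), each held for a
#' fixed number of frames, traversed back and forth. Defaults match a
#' 3252 fps camera with a 1/300 s dwell per position.
#'
#' @param n_orientations number of orientations.
#' @param n_phases positions per orientation.
#' @param phase_step fringe phase increment per position, rad (the default
#'   is slightly larger than an even 2pi/n_phases step).
#' @param frames_per_position frames recorded at each position.
#' @param raw_frame_rate raw camera frame rate, fps.
#' @param base_angles coarse galvo angle per orientation, rad.
#' @param orientation_settle,phase_settle settling times, s.
#' @return A \linkS4class{GalvoSchedule}.
#' @export
sweepSchedule <- function(n_orientations = 3, n_phases = 5,
                          phase_step = 1.1 * 2 * pi / n_phases,
                          frames_per_position = 10, raw_frame_rate = 3252,
                          base_angles = NULL,
                          orientation_settle = 0.9e-3,
                          phase_settle = 5e-5) {
  sched <- simCycleSchedule(
    n_orientations = n_orientations, n_phases = n_phases,
    phase_step = phase_step, raw_frame_rate = raw_frame_rate,
    orientation_dwell = frames_per_position, base_angles = base_angles,
    alternate_direction = TRUE, orientation_settle = orientation_settle,
    phase_settle = phase_settle)
  sched@entries$n_frames <- frames_per_position
  sched
}

#' Frame count and final rate of a schedule
#'
#' @param schedule a \linkS4class{GalvoSchedule}.
#' @return List with \code{frames_per_cycle}, \code{final_rate} (exact,
#'   fps) and \code{final_rate_fps} (floored to whole fps, the
#'   conventionally reported figure).
#' @examples
#' scheduleStats(simCycleSchedule())   # 11 frames, 89 fps
#' @export
scheduleStats <- function(schedule) {
  fpc <- sum(schedule@entries$n_frames)
  rate <- schedule@raw_frame_rate / fpc
  list(frames_per_cycle = fpc, final_rate = rate,
       final_rate_fps = as.integer(floor(rate)))
}

# ---------------------------------------------------------------------------
# Schedule execution
# ---------------------------------------------------------------------------

# Phase-washed (fringe-free) mean level of an illumination pattern.
flatIllum <- function(illum) {
  matrix(mean(illum@values), nrow(illum@values), ncol(illum@values))
}

#' Run a galvo schedule against a phantom
#'
#' Renders the full frame sequence of \code{n_cycles} schedule cycles.
#' Each entry's illumination is the preset for its orientation, phase
#' stepped through the galvo phase model (entry \code{delta_angle}, derived
#' from the stored phase via [galvoStepForPhase()] when absent). Frames
#' exposed while the galvo is still settling are rendered as exposure-time
#' mixtures of the moving and settled pattern: a phase micro-step
#' contributes the sweep average over the traversed phases, an orientation
#' change contributes the fringe-free washed-out level, for the fraction
#' \code{f_move} of the exposure the move occupies. Orientation-change
#' settling may span several frames (e.g. ~3 frames at 3252 fps for a
#' 0.9 ms settle); those frames are flagged \code{transition}. With
#' \code{alternate_direction} the traversal reverses on every other cycle,
#' so the galvo holds its position across the cycle boundary and the first
#' frame of each cycle is clean.
#'
#' @param phantom a \linkS4class{BeadPhantom}.
#' @param presets list of \linkS4class{PatternPreset}, one per orientation.
#' @param schedule a \linkS4class{GalvoSchedule}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param camera a \linkS4class{CameraModel}.
#' @param psf detection PSF from [widefieldPsf()].
#' @param exposure_scale photon budget, see [renderFrame()].
#' @param seed integer seed; each frame derives its own noise stream.
#' @param n_cycles number of cycles to run.
#' @param noise logical, apply camera noise.
#' @return A \linkS4class{FrameStack}.
#' @export
runSchedule <- function(phantom, presets, schedule, cfg, camera, psf,
                        exposure_scale = 2000, seed = 1, n_cycles = 1,
                        noise = TRUE) {
  ent <- schedule@entries
  if (max(ent$orientation) > length(presets))
    stop("schedule references orientation ", max(ent$orientation),
         " but only ", length(presets), " preset(s) supplied")
  exposure <- 1 / schedule@raw_frame_rate

  # resolve galvo deltas: derive from stored phases when not explicit
  if (all(is.na(ent$delta_angle))) {
    ent$delta_angle <- vapply(seq_len(nrow(ent)), function(i) {
      galvoStepForPhase(presets[[ent$orientation[i]]], cfg, ent$phase[i])
    }, numeric(1))
  }

  # cache stationary illuminations per entry and flat levels per orientation
  illums <- lapply(seq_len(nrow(ent)), function(i)
    illuminationOnCamera(presets[[ent$orientation[i]]], cfg, camera,
                         galvo_delta = ent$delta_angle[i]))
  flats <- lapply(seq_along(presets), function(o) {
    i <- which(ent$orientation == o)[1]
    flatIllum(illums[[i]])
  })
  sweepAvg <- function(o, d0, d1, n = 9) {
    ds <- seq(d0, d1, length.out = n)
    acc <- 0
    for (d in ds)
      acc <- acc + illuminationOnCamera(presets[[o]], cfg, camera,
                                        galvo_delta = d)@values
    acc / n
  }

  order_fwd <- seq_len(nrow(ent))
  frames_list <- list()
  meta <- list()
  prev <- NULL    # list(orientation, delta)
  fidx <- 0
  for (cy in seq_len(n_cycles)) {
    ord <- if (schedule@alternate_direction && cy %% 2 == 0)
      rev(order_fwd) else order_fwd
    for (ei in ord) {
      o <- ent$orientation[ei]
      d <- ent$delta_angle[ei]
      moved <- !is.null(prev) &&
        (prev$orientation != o || abs(prev$delta - d) > 1e-15)
      orient_change <- !is.null(prev) && prev$orientation != o
      settle <- if (!moved) 0 else if (orient_change)
        schedule@orientation_settle else schedule@phase_settle
      moving_illum <- if (!moved) NULL else if (orient_change)
        0.5 * (flats[[prev$orientation]] + flats[[o]])
      else sweepAvg(o, prev$delta, d)
      remaining <- settle
      for (fr in seq_len(ent$n_frames[ei])) {
        fidx <- fidx + 1
        f_move <- min(1, remaining / exposure)
        remaining <- max(0, remaining - exposure)
        iv <- illums[[ei]]@values
        if (f_move > 0)
          iv <- (1 - f_move) * iv + f_move * moving_illum
        ig <- intensityGrid(iv, illums[[ei]]@pixel_size)
        frames_list[[fidx]] <- renderFrame(
          phantom, ig, psf, camera, exposure_scale,
          seed = seed + 7919 * fidx, noise = noise)
        meta[[fidx]] <- data.frame(
          galvo_angle = schedule@base_angles[o] + d,
          orientation = o, phase_index = ent$phase_index[ei],
          transition = orient_change && f_move > 0.05,
          f_move = f_move, cycle = cy)
      }
      prev <- list(orientation = o, delta = d)
    }
  }
  ny <- camera@roi[1]; nx <- camera@roi[2]
  arr <- array(unlist(frames_list), dim = c(ny, nx, fidx))
  new("FrameStack", frames = arr, meta = do.call(rbind, meta),
      pixel_size = camera@pixel_size_sample / 1000, seed = as.integer(seed))
}
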