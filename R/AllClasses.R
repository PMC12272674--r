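#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# OpticalConfig
# ---------------------------------------------------------------------------

#' Optical configuration of the single-galvo interferometer
#'
#' Holds the handful of physical constants the rest of the package needs:
#' excitation wavelength, refractive index of the medium in which the
#' pattern forms, focal length of the main (pattern-forming) lens, effective
#' numerical aperture, the galvo-to-phase gain, and the beam separation on
#' the galvo mirror.
#'
#' The galvo phase gain relates a galvo micro-rotation \eqn{\delta\theta}
#' (rad) and a beam's horizontal offset \eqn{x} (mm, measured in the galvo
#' plane) to the optical phase picked up by that beam:
#' \eqn{\phi = g \, x \, \delta\theta}. Its default is the double-pass
#' reflection value \eqn{g = 4\pi/\lambda} (with \eqn{\lambda} in mm), under
#' which a full \eqn{2\pi} fringe step for beams spanning 2 mm requires a
#' galvo step of roughly one percent of a typical column-to-column
#' reorientation step.
#'
#' @slot wavelength excitation wavelength, nm.
#' @slot refractive_index refractive index of the pattern-forming medium.
#' @slot focal_length_main focal length of the main lens, mm.
#' @slot effective_NA effective numerical aperture (\eqn{\le} refractive
#'   index).
#' @slot galvo_phase_gain phase gain, rad per (rad \eqn{\times} mm).
#' @slot beam_separation_on_galvo separation of the outermost beams on the
#'   galvo mirror, mm.
#' @seealso [opticalConfig()], [galvoPhase()], [pupilToWavevector()]
#' @export
setClass("OpticalConfig",
  representation(
    wavelength = "numeric",
    refractive_index = "numeric",
    focal_length_main = "numeric",
    effective_NA = "numeric",
    galvo_phase_gain = "numeric",
    beam_separation_on_galvo = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number (nm)")
  if (object@refractive_index < 1)
    msg <- c(msg, "refractive_index must be >= 1")
  if (object@focal_length_main <= 0)
    msg <- c(msg, "focal_length_main must be > 0 (mm)")
  if (object@effective_NA <= 0 ||
      object@effective_NA > object@refractive_index)
    msg <- c(msg, "effective_NA must satisfy 0 < NA <= refractive_index")
  if (object@galvo_phase_gain <= 0 || !is.finite(object@galvo_phase_gain))
    msg <- c(msg, "galvo_phase_gain must be a positive finite number")
  if (object@beam_separation_on_galvo <= 0)
    msg <- c(msg, "beam_separation_on_galvo must be > 0 (mm)")
  if (length(msg)) msg else TRUE
})

#' Create an optical configuration
#'
#' @param wavelength excitation wavelength in nm.
#' @param refractive_index refractive index of the pattern-forming medium.
#' @param focal_length_main main-lens focal length in mm.
#' @param effective_NA effective numerical aperture.
#' @param galvo_phase_gain galvo-to-phase gain in rad/(rad mm); default is
#'   the double-pass value \eqn{4\pi/\lambda}.
#' @param beam_separation_on_galvo beam separation on the galvo in mm.
#' @return An \linkS4class{OpticalConfig}.
#' @examples
#' cfg <- opticalConfig()
#' cfg
#' @export
opticalConfig <- function(wavelength = 473,
                          refractive_index = 1.518,
                          focal_length_main = 200,
                          effective_NA = 1.5,
                          galvo_phase_gain = NULL,
                          beam_separation_on_galvo = 2) {
  if (is.null(galvo_phase_gain))
    galvo_phase_gain <- 4 * pi / (wavelength * 1e-6)  # wavelength nm -> mm
  new("OpticalConfig",
      wavelength = wavelength,
      refractive_index = refractive_index,
      focal_length_main = focal_length_main,
      effective_NA = effective_NA,
      galvo_phase_gain = galvo_phase_gain,
      beam_separation_on_galvo = beam_separation_on_galvo)
}

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n",
      sprintf("  wavelength: %.1f nm, n = %.3f, NA = %.3f\n",
              object@wavelength, object@refractive_index,
              object@effective_NA),
      sprintf("  main lens f = %.1f mm, aperture radius = %.2f mm\n",
              object@focal_length_main, apertureRadius(object)),
      sprintf("  galvo gain = %.3g rad/(rad mm), beam separation = %.1f mm\n",
              object@galvo_phase_gain, object@beam_separation_on_galvo),
      sep = "")
})

#' Aperture radius of the main lens back focal plane
#'
#' Maximum pupil radius a beam may occupy, \eqn{\mathrm{NA} \cdot f / n} in mm.
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @return Radius in mm.
#' @export
apertureRadius <- function(cfg) {
  cfg@effective_NA * cfg@focal_length_main / cfg@refractive_index
}

# ---------------------------------------------------------------------------
# Beam / WavePlate
# ---------------------------------------------------------------------------

#' A single coherent plane-wave source
#'
#' One focus at the back focal plane of the main lens, i.e. one angled plane
#' wave after the lens. The Jones vector is the pupil-plane transverse
#' polarization (complex, normalized); \code{lens_offset_x} is the beam's
#' horizontal offset in the galvo plane (mm), which sets how much phase the
#' beam picks up per galvo micro-rotation.
#'
#' @slot pupil_position numeric(2), position in the back focal plane, mm.
#' @slot amplitude square root of beam power (arbitrary units), >= 0.
#' @slot jones complex(2), pupil-plane Jones vector, unit norm.
#' @slot phase static phase offset, rad.
#' @slot lens_offset_x horizontal beam offset in the galvo plane, mm.
#' @seealso [beam()], [pupilToWavevector()], [galvoPhase()]
#' @export
setClass("Beam",
  representation(
    pupil_position = "numeric",
    amplitude = "numeric",
    jones = "complex",
    phase = "numeric",
    lens_offset_x = "numeric"
  )
)

setValidity("Beam", function(object) {
  msg <- character()
  if (length(object@pupil_position) != 2 ||
      any(!is.finite(object@pupil_position)))
    msg <- c(msg, "pupil_position must be a finite 2-vector (mm)")
  if (length(object@amplitude) != 1 || object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single number >= 0")
  if (length(object@jones) != 2)
    msg <- c(msg, "jones must be a complex 2-vector")
  if (object@amplitude > 0) {
    nrm <- sqrt(sum(Mod(object@jones)^2))
    if (!is.finite(nrm) || abs(nrm - 1) > 1e-8)
      msg <- c(msg, "jones must have unit norm when amplitude > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Create a beam
#'
#' @param pupil_position numeric(2), focus position in the back focal plane
#'   (mm). Checked against the aperture when \code{cfg} is supplied.
#' @param amplitude square root of power, >= 0.
#' @param jones complex or numeric 2-vector; normalized internally.
#' @param phase static phase, rad.
#' @param lens_offset_x horizontal galvo-plane offset, mm.
#' @param cfg optional \linkS4class{OpticalConfig} for the aperture check.
#' @return A \linkS4class{Beam}.
#' @examples
#' beam(c(1, 0), jones = c(0, 1))
#' @export
beam <- function(pupil_position, amplitude = 1, jones = c(1, 0), phase = 0,
                 lens_offset_x = 0, cfg = NULL) {
  jones <- as.complex(jones)
  nrm <- sqrt(sum(Mod(jones)^2))
  if (amplitude > 0) {
    if (nrm == 0) stop("jones vector must be nonzero when amplitude > 0")
    jones <- jones / nrm
  }
  if (!is.null(cfg)) {
    r <- sqrt(sum(pupil_position^2))
    if (r > apertureRadius(cfg) * (1 + 1e-9))
      stop("beam outside aperture: |pupil_position| = ", signif(r, 4),
           " mm exceeds NA*f/n = ", signif(apertureRadius(cfg), 4), " mm")
  }
  new("Beam", pupil_position = as.numeric(pupil_position),
      amplitude = amplitude, jones = jones, phase = phase,
      lens_offset_x = lens_offset_x)
}

#' A wave plate
#'
#' @slot kind "quarter" or "half".
#' @slot fast_axis_angle fast-axis angle from horizontal, rad.
#' @seealso [wavePlate()], [doublePassWaveplate()]
#' @export
setClass("WavePlate",
  representation(kind = "character", fast_axis_angle = "numeric"))

setValidity("WavePlate", function(object) {
  if (!object@kind %in% c("quarter", "half"))
    return("kind must be 'quarter' or 'half'")
  TRUE
})

#' Create a wave plate
#'
#' @param kind "quarter" or "half".
#' @param fast_axis_angle fast-axis angle from horizontal, rad.
#' @return A \linkS4class{WavePlate}.
#' @export
wavePlate <- function(kind = c("quarter", "half"), fast_axis_angle = 0) {
  kind <- match.arg(kind)
  new("WavePlate", kind = kind, fast_axis_angle = fast_axis_angle)
}

# ---------------------------------------------------------------------------
# Lens array / pattern presets
# ---------------------------------------------------------------------------

#' Miniature lens array layout
#'
#' Positions of the mini-lens centers in the back-aperture plane. The
#' default is a hexagonally close-packed arrangement of seven lenses
#' (one central, six on a ring).
#'
#' @slot slots n x 2 matrix of lens-center positions, mm.
#' @slot layout_rotation rotation of the whole layout, rad.
#' @seealso [hexLensLayout()]
#' @export
setClass("LensArrayLayout",
  representation(slots = "matrix", layout_rotation = "numeric"))

setValidity("LensArrayLayout", function(object) {
  s <- object@slots
  if (ncol(s) != 2) return("slots must be an n x 2 matrix (mm)")
  d <- as.matrix(stats::dist(s))
  diag(d) <- Inf
  if (any(d < 1e-9)) return("lens slot positions must be distinct")
  TRUE
})

#' Hexagonally close-packed seven-lens layout
#'
#' @param spacing center-to-center lens spacing, mm.
#' @param rotation layout rotation, rad.
#' @return A \linkS4class{LensArrayLayout} with 7 slots (slot 1 central).
#' @examples
#' hexLensLayout()@slots
#' @export
hexLensLayout <- function(spacing = 4, rotation = 0) {
  ang <- rotation + seq(0, by = pi / 3, length.out = 6)
  slots <- rbind(c(0, 0), cbind(spacing * cos(ang), spacing * sin(ang)))
  new("LensArrayLayout", slots = slots, layout_rotation = rotation)
}

#' A named interference-pattern preset
#'
#' A set of beams defining one fringe pattern (orientation). Two-beam
#' presets give a laterally sinusoidal, axially invariant pattern;
#' hexagonal presets three-fold symmetric lateral structure; linear
#' three-beam presets are periodic in z as well.
#'
#' @slot name preset name.
#' @slot beams list of \linkS4class{Beam}.
#' @slot z_dependent logical, whether the intensity varies along z.
#' @seealso [twoBeamPreset()], [hexagonalPreset()], [linearThreeBeamPreset()]
#' @export
setClass("PatternPreset",
  representation(name = "character", beams = "list",
                 z_dependent = "logical"))

setValidity("PatternPreset", function(object) {
  if (length(object@beams) < 1)
    return("preset needs at least one beam")
  if (!all(vapply(object@beams, is, logical(1), class2 = "Beam")))
    return("beams must all be Beam objects")
  pos <- t(vapply(object@beams, function(b) b@pupil_position, numeric(2)))
  if (nrow(pos) > 1) {
    d <- as.matrix(stats::dist(pos)); diag(d) <- Inf
    if (any(d < 1e-9)) return("beams must occupy distinct pupil positions")
  }
  TRUE
})

setMethod("show", "PatternPreset", function(object) {
  cat(sprintf("PatternPreset '%s': %d beam(s), %s\n", object@name,
              length(object@beams),
              if (object@z_dependent) "z-dependent" else "z-invariant"))
  for (b in object@beams)
    cat(sprintf("  pupil (%+.3f, %+.3f) mm  A = %.3f  galvo x = %+.3f mm\n",
                b@pupil_position[1], b@pupil_position[2], b@amplitude,
                b@lens_offset_x))
})

# ---------------------------------------------------------------------------
# Field / intensity grids
# ---------------------------------------------------------------------------

#' Complex vectorial field on a grid
#'
#' @slot values complex array \code{[ny, nx, 3]}, field components (x, y, z).
#' @slot pixel_size pixel pitch, um.
#' @slot z axial position of the grid, um.
#' @export
setClass("InterferenceField",
  representation(values = "array", pixel_size = "numeric", z = "numeric"))

#' Nonnegative intensity on a grid
#'
#' 2D (y, x) or 3D (z or axial dimension as third index) nonnegative
#' intensity array with pixel metadata. The grid origin is the center of
#' the grid; x runs along columns (rightwards), y along rows (upwards).
#'
#' @slot values nonnegative numeric array.
#' @slot pixel_size lateral pixel pitch, um.
#' @slot z axial coordinates (um) when the array is an x-z or x-y-z slice,
#'   else numeric(0).
#' @export
setClass("IntensityGrid",
  representation(values = "array", pixel_size = "numeric", z = "numeric"))

setValidity("IntensityGrid", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("intensity values must be finite")
  if (any(v < -1e-12 * max(abs(v), 1))) return("intensity values must be >= 0")
  if (object@pixel_size <= 0) return("pixel_size must be > 0 (um)")
  TRUE
})

#' Create an intensity grid
#'
#' @param values numeric matrix or array of nonnegative intensities.
#' @param pixel_size pixel pitch, um.
#' @param z optional axial coordinates, um.
#' @return An \linkS4class{IntensityGrid}.
#' @export
intensityGrid <- function(values, pixel_size, z = numeric(0)) {
  values[values < 0] <- 0  # clip numerical negatives
  if (is.matrix(values)) values <- array(values, dim = dim(values))
  new("IntensityGrid", values = values, pixel_size = pixel_size, z = z)
}

#' @rdname accessors
#' @export
setMethod("pixelSize", "IntensityGrid", function(x) x@pixel_size)

#' @rdname accessors
#' @export
setMethod("pixelSize", "InterferenceField", function(x) x@pixel_size)

setMethod("show", "IntensityGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("IntensityGrid %s, pixel %.1f nm, range [%.3g, %.3g]\n",
              paste(d, collapse = " x "), 1000 * object@pixel_size,
              min(object@values), max(object@values)))
})

# ---------------------------------------------------------------------------
# Acquisition containers
# ---------------------------------------------------------------------------

#' Sparse fluorescent bead phantom
#'
#' @slot positions n x 2 matrix of bead centers, um, origin at field center.
#' @slot intensities positive per-bead brightness factors.
#' @slot bead_diameter physical bead diameter, nm.
#' @slot fov numeric(2) field extent (x, y), um.
#' @slot seed integer seed used to generate the phantom.
#' @seealso [generateBeadPhantom()]
#' @export
setClass("BeadPhantom",
  representation(positions = "matrix", intensities = "numeric",
                 bead_diameter = "numeric", fov = "numeric",
                 seed = "integer"))

setValidity("BeadPhantom", function(object) {
  msg <- character()
  if (ncol(object@positions) != 2)
    msg <- c(msg, "positions must be n x 2 (um)")
  if (length(object@intensities) != nrow(object@positions))
    msg <- c(msg, "one intensity per bead required")
  if (any(object@intensities <= 0))
    msg <- c(msg, "intensities must be > 0")
  hw <- object@fov / 2
  if (any(abs(object@positions[, 1]) > hw[1] + 1e-9) ||
      any(abs(object@positions[, 2]) > hw[2] + 1e-9))
    msg <- c(msg, "bead positions must lie within the field")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BeadPhantom", function(object) {
  cat(sprintf(
    "BeadPhantom: %d beads, diameter %.0f nm, field %.1f x %.1f um, seed %d\n",
    nrow(object@positions), object@bead_diameter, object@fov[1],
    object@fov[2], object@seed))
})

#' Camera model
#'
#' @slot pixel_size_sample pixel pitch referred to the sample plane, nm.
#' @slot read_noise read noise, electrons RMS.
#' @slot gain electrons per output count.
#' @slot offset dark offset, counts.
#' @slot bit_depth 8 or 16.
#' @slot roi numeric(2) region of interest, pixels (rows, cols).
#' @seealso [cameraModel()], [renderFrame()]
#' @export
setClass("CameraModel",
  representation(pixel_size_sample = "numeric", read_noise = "numeric",
                 gain = "numeric", offset = "numeric", bit_depth = "numeric",
                 roi = "numeric"))

setValidity("CameraModel", function(object) {
  msg <- character()
  if (object@pixel_size_sample <= 0)
    msg <- c(msg, "pixel_size_sample must be > 0 (nm)")
  if (!object@bit_depth %in% c(8, 16))
    msg <- c(msg, "bit_depth must be 8 or 16")
  if (length(object@roi) != 2 || any(object@roi < 8))
    msg <- c(msg, "roi must be two pixel counts >= 8")
  if (object@gain <= 0) msg <- c(msg, "gain must be > 0 (e-/count)")
  if (object@read_noise < 0) msg <- c(msg, "read_noise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a camera model
#'
#' Defaults emulate a fast sCMOS at 100x magnification: 65 nm sample-plane
#' pixels, ~1.6 e- read noise, 16-bit.
#'
#' @param pixel_size_sample sample-plane pixel pitch, nm.
#' @param read_noise read noise, electrons RMS.
#' @param gain electrons per count.
#' @param offset dark offset, counts.
#' @param bit_depth 8 or 16.
#' @param roi c(rows, cols) in pixels.
#' @return A \linkS4class{CameraModel}.
#' @export
cameraModel <- function(pixel_size_sample = 65, read_noise = 1.6, gain = 1,
                        offset = 100, bit_depth = 16, roi = c(256, 256)) {
  new("CameraModel", pixel_size_sample = pixel_size_sample,
      read_noise = read_noise, gain = gain, offset = offset,
      bit_depth = bit_depth, roi = roi)
}

#' Galvo acquisition schedule
#'
#' Ordered galvo set points with per-position dwell (in frames). Each entry
#' names the pattern orientation it addresses, the micro-rotation
#' \code{delta_angle} (rad) applied on top of that orientation's base
#' angle, and the number of frames recorded there.
#'
#' @slot entries data.frame with columns \code{orientation} (integer),
#'   \code{phase_index} (integer), \code{delta_angle} (rad),
#'   \code{n_frames} (integer >= 1).
#' @slot base_angles coarse galvo angle per orientation, rad.
#' @slot raw_frame_rate raw camera frame rate, frames/s.
#' @slot alternate_direction logical; if TRUE consecutive cycles traverse
#'   the entries in alternating order, so the galvo does not move at cycle
#'   boundaries.
#' @slot orientation_settle galvo settling time for an orientation change, s.
#' @slot phase_settle galvo settling time for a phase micro-step, s.
#' @seealso [simCycleSchedule()], [sweepSchedule()], [runSchedule()],
#'   [scheduleStats()]
#' @export
setClass("GalvoSchedule",
  representation(entries = "data.frame", base_angles = "numeric",
                 raw_frame_rate = "numeric",
                 alternate_direction = "logical",
                 orientation_settle = "numeric", phase_settle = "numeric"))

setValidity("GalvoSchedule", function(object) {
  e <- object@entries
  need <- c("orientation", "phase_index", "delta_angle", "n_frames")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) < 1) return("schedule must have at least one entry")
  if (any(e$n_frames < 1)) return("n_frames must be >= 1")
  if (object@raw_frame_rate <= 0) return("raw_frame_rate must be > 0")
  if (max(e$orientation) > length(object@base_angles))
    return("base_angles must cover every orientation index used")
  TRUE
})

setMethod("show", "GalvoSchedule", function(object) {
  st <- scheduleStats(object)
  cat(sprintf(
    "GalvoSchedule: %d positions, %d frames/cycle, %.0f fps raw -> %d fps\n",
    nrow(object@entries), st$frames_per_cycle, object@raw_frame_rate,
    st$final_rate_fps))
})

#' Stack of camera frames with per-frame metadata
#'
#' @slot frames numeric array \code{[ny, nx, n_frames]} of counts.
#' @slot meta data.frame, one row per frame: \code{galvo_angle} (rad),
#'   \code{orientation}, \code{phase_index}, \code{transition} (logical),
#'   \code{f_move} (fraction of the exposure spent moving), \code{cycle}.
#' @slot pixel_size lateral pixel pitch, um.
#' @slot seed integer seed used for the acquisition noise.
#' @export
setClass("FrameStack",
  representation(frames = "array", meta = "data.frame",
                 pixel_size = "numeric", seed = "integer"))

setValidity("FrameStack", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3) return("frames must be a 3D array [ny, nx, frame]")
  if (nrow(object@meta) != d[3])
    return("meta must have one row per frame")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("frameMeta", "FrameStack", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixel_size)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "FrameStack: %d frames of %d x %d px (%.0f nm px), %d transition frame(s)\n",
    d[3], d[1], d[2], 1000 * object@pixel_size,
    sum(object@meta$transition)))
})

# ---------------------------------------------------------------------------
# Estimation results
# ---------------------------------------------------------------------------

#' 2D sinusoid fit of a fringe image
#'
#' Model: \eqn{I(r) = \mathrm{offset}\,(1 + V \cos(2\pi f \cdot r + \phi))},
#' coordinates centered on the grid.
#'
#' @slot visibility fringe visibility V in [0, 1].
#' @slot fringe_vector numeric(2), fringe frequency, cycles/um.
#' @slot phase phase at the grid center, rad in [0, 2pi).
#' @slot offset mean intensity level.
#' @slot residual_rms RMS of fit residuals.
#' @seealso [fitSinusoid2d()], [theoreticalVisibility()]
#' @export
setClass("SinusoidFit",
  representation(visibility = "numeric", fringe_vector = "numeric",
                 phase = "numeric", offset = "numeric",
                 residual_rms = "numeric"))

setValidity("SinusoidFit", function(object) {
  if (object@visibility < -1e-9 || object@visibility > 1 + 1e-9)
    return("visibility must be in [0, 1]")
  if (object@phase < 0 || object@phase >= 2 * pi + 1e-9)
    return("phase must be wrapped to [0, 2pi)")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("visibility", "SinusoidFit", function(x) x@visibility)

setMethod("show", "SinusoidFit", function(object) {
  f <- object@fringe_vector
  cat(sprintf(
    "SinusoidFit: V = %.4f, period = %.1f nm, angle = %.2f deg, phase = %.3f rad\n",
    object@visibility, 1000 / sqrt(sum(f^2)),
    atan2(f[2], f[1]) * 180 / pi, object@phase))
})

#' Per-frame Fourier-correlation trace
#'
#' For each frame: the amplitude, phase and frequency-space position of the
#' off-DC peak of the correlation between the frame's Fourier transform and
#' the reference's Fourier transform. Amplitude is normalized by the
#' zero-shift (DC) correlation so plateaus are comparable across
#' orientations.
#'
#' @slot amplitude per-frame normalized correlation amplitude, >= 0.
#' @slot phase per-frame correlation phase, rad.
#' @slot peak n x 2 matrix, peak position, cycles/um.
#' @slot peak_px n x 2 matrix, peak position in (fractional) frequency
#'   pixels.
#' @slot meta per-frame metadata carried over from the stack (may have 0
#'   rows).
#' @seealso [fourierCorrelationTrace()], [detectTransitions()]
#' @export
setClass("PatternEstimate",
  representation(amplitude = "numeric", phase = "numeric", peak = "matrix",
                 peak_px = "matrix", meta = "data.frame"))

setValidity("PatternEstimate", function(object) {
  n <- length(object@amplitude)
  if (length(object@phase) != n || nrow(object@peak) != n)
    return("amplitude, phase and peak must share the frame count")
  if (any(object@amplitude < 0)) return("amplitudes must be >= 0")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("amplitudeTrace", "PatternEstimate", function(x) x@amplitude)

#' @rdname accessors
#' @export
setMethod("phaseTrace", "PatternEstimate", function(x) x@phase)

setMethod("show", "PatternEstimate", function(object) {
  cat(sprintf(
    "PatternEstimate: %d frames, amplitude range [%.3g, %.3g]\n",
    length(object@amplitude), min(object@amplitude), max(object@amplitude)))
})

#' Galvo voltage-to-phase calibration
#'
#' @slot slope pattern phase per volt, rad/V.
#' @slot intercept phase at zero volts, rad.
#' @slot voltages_for_steps voltages realizing even phase steps, V.
#' @slot residual RMS residual of the linear fit, rad.
#' @slot target_step requested phase step, rad.
#' @seealso [calibrateGalvo()]
#' @export
setClass("GalvoCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 voltages_for_steps = "numeric", residual = "numeric",
                 target_step = "numeric"))

setMethod("show", "GalvoCalibration", function(object) {
  cat(sprintf(
    "GalvoCalibration: slope %.4g rad/V, residual %.3g rad, %d step voltages\n",
    object@slope, object@residual, length(object@voltages_for_steps)))
})

# ---------------------------------------------------------------------------
# Reconstruction containers
# ---------------------------------------------------------------------------

#' Estimated SIM pattern parameters
#'
#' One element per orientation, each a list with \code{fringe_vector}
#' (cycles/um, 2-vector), \code{phases} (rad, one per phase step) and
#' \code{modulation} (estimated modulation depth in [0, 1]).
#'
#' @slot orientations list of per-orientation parameter lists.
#' @seealso [estimateSimParams()], [wienerReconstruct()]
#' @export
setClass("SimParams", representation(orientations = "list"))

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: %d orientation(s)\n", length(object@orientations)))
  for (i in seq_along(object@orientations)) {
    o <- object@orientations[[i]]
    f <- o$fringe_vector
    cat(sprintf(
      "  [%d] |f| = %.4f cyc/um, angle = %.2f deg, m = %.3f, %d phases\n",
      i, sqrt(sum(f^2)), atan2(f[2], f[1]) * 180 / pi, o$modulation,
      length(o$phases)))
  }
})

#' Separated frequency bands for SIM
#'
#' Per orientation, the complex frequency-domain components of orders 0 and
#' +/-1 obtained from phase-stepped frames (standard FFT index layout,
#' DC at [1, 1]).
#'
#' @slot bands list (one per orientation) of lists with elements \code{b0},
#'   \code{bp}, \code{bm} (complex matrices).
#' @slot pixel_size real-space pixel pitch of the source frames, um.
#' @seealso [separateBands()]
#' @export
setClass("BandSet",
  representation(bands = "list", pixel_size = "numeric"))

#' Fourier ring correlation curve
#'
#' @slot freq ring center frequencies, cycles/um.
#' @slot frc correlation per ring, in [-1, 1] up to noise.
#' @slot resolution estimated resolution, nm.
#' @slot threshold threshold rule value used (e.g. 1/7).
#' @seealso [frcCurve()]
#' @export
setClass("FrcCurve",
  representation(freq = "numeric", frc = "numeric", resolution = "numeric",
                 threshold = "numeric"))

#' @rdname accessors
#' @export
setMethod("frcResolution", "FrcCurve", function(x) x@resolution)

setMethod("show", "FrcCurve", function(object) {
  cat(sprintf(
    "FrcCurve: %d rings, threshold %.3f, resolution %.1f nm\n",
    length(object@freq), object@threshold, object@resolution))
})
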