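# Pattern presets: beam sets realizing the two-beam, hexagonal three-beam
# and linear three-beam interference configurations, plus the mapping from
# pupil position to galvo-plane beam offset that drives phase stepping.

# Galvo-plane horizontal offset for a pupil position: the outermost
# aperture diameter maps to beam_separation_on_galvo.
galvoOffsetX <- function(pupil_x, cfg) {
  pupil_x * cfg@beam_separation_on_galvo / (2 * apertureRadius(cfg))
}

# Unit Jones vector linear at angle a from horizontal.
linearJones <- function(a) c(cos(a), sin(a))

#' Two-beam interference preset
#'
#' Two beams at mirror-image pupil positions along direction
#' \code{orientation}, producing a laterally sinusoidal, axially invariant
#' fringe pattern with wavevector along \code{orientation}. By default both
#' beams are s-polarized with respect to the fringe plane (polarization
#' perpendicular to it), the configuration that preserves full contrast at
#' high NA.
#'
#' The fringe period is \eqn{\lambda / (2\,\mathrm{NA}\cdot
#' \mathrm{radius\_frac})}: beams at the aperture edge give the finest
#' fringe \eqn{\lambda/2\mathrm{NA}}.
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param orientation fringe direction from horizontal, rad.
#' @param radius_frac pupil radius as a fraction of the aperture radius.
#' @param amplitudes numeric(2) beam amplitudes.
#' @param spol if TRUE both beams are polarized perpendicular to the fringe
#'   plane; if FALSE both keep horizontal polarization.
#' @param phases numeric(2) static phases, rad.
#' @param name preset name.
#' @return A \linkS4class{PatternPreset}.
#' @examples
#' cfg <- opticalConfig()
#' twoBeamPreset(cfg, orientation = 0)
#' @export
twoBeamPreset <- function(cfg, orientation = 0, radius_frac = 0.85,
                          amplitudes = c(1, 1), spol = TRUE,
                          phases = c(0, 0), name = "two-beam") {
  r <- radius_frac * apertureRadius(cfg)
  u <- c(cos(orientation), sin(orientation))
  jn <- if (spol) linearJones(orientation + pi / 2) else c(1, 0)
  b <- list(
    beam(r * u, amplitudes[1], jn, phases[1],
         lens_offset_x = galvoOffsetX(r * u[1], cfg), cfg = cfg),
    beam(-r * u, amplitudes[2], jn, phases[2],
         lens_offset_x = galvoOffsetX(-r * u[1], cfg), cfg = cfg))
  new("PatternPreset", name = name, beams = b, z_dependent = FALSE)
}

#' Hexagonal three-beam preset
#'
#' Three equal-radius beams 120 degrees apart on the pupil ring, giving a
#' hexagonal (three-fold symmetric) lateral pattern that is invariant along
#' z (all beams share the same axial wavevector). The layout is rotated 90
#' degrees relative to the two-beam configuration so each beam keeps a
#' distinct horizontal offset for phase stepping.
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param rotation rotation of the beam triplet, rad; the default places the
#'   beams at 90, 210 and 330 degrees.
#' @param radius_frac pupil radius fraction.
#' @param amplitudes numeric(3) beam amplitudes.
#' @param phases numeric(3) static phases, rad.
#' @param polarization "azimuthal" (each beam s-polarized with respect to
#'   its own meridional plane, the high-contrast choice) or "parallel"
#'   (all beams share one linear pupil polarization, approaching the
#'   scalar superposition at small radius).
#' @param name preset name.
#' @return A \linkS4class{PatternPreset}.
#' @export
hexagonalPreset <- function(cfg, rotation = pi / 2, radius_frac = 0.85,
                            amplitudes = c(1, 1, 1), phases = c(0, 0, 0),
                            polarization = c("azimuthal", "parallel"),
                            name = "hexagonal") {
  polarization <- match.arg(polarization)
  r <- radius_frac * apertureRadius(cfg)
  ang <- rotation + c(0, 2, 4) * pi / 3
  b <- lapply(1:3, function(i) {
    p <- r * c(cos(ang[i]), sin(ang[i]))
    jn <- if (polarization == "azimuthal")
      linearJones(ang[i] + pi / 2) else c(1, 0)
    beam(p, amplitudes[i], jn, phases[i],
         lens_offset_x = galvoOffsetX(p[1], cfg), cfg = cfg)
  })
  new("PatternPreset", name = name, beams = b, z_dependent = FALSE)
}

#' Linear three-beam preset
#'
#' A central on-axis beam plus two symmetric side beams along
#' \code{orientation}. The pattern is periodic both laterally and along z
#' (period set by the axial wavevector mismatch between center and side
#' beams); with zero center amplitude it reduces to the z-invariant
#' two-beam pattern. All three beams are polarized perpendicular to the
#' fringe plane (the center beam's polarization is rotated to match the
#' side beams, as a double-passed quarter-wave plate does in hardware).
#'
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param orientation fringe direction from horizontal, rad.
#' @param radius_frac side-beam pupil radius fraction.
#' @param center_amplitude amplitude of the on-axis beam.
#' @param side_amplitudes numeric(2) side-beam amplitudes.
#' @param asymmetry fractional angular asymmetry applied to the second side
#'   beam's radius (0 = symmetric); a nonzero value models a misaligned
#'   beam and produces the beating of fringe contrast across the field.
#' @param phases numeric(3) static phases (side+, center, side-).
#' @param name preset name.
#' @return A \linkS4class{PatternPreset}.
#' @export
linearThreeBeamPreset <- function(cfg, orientation = 0, radius_frac = 0.85,
                                  center_amplitude = 1,
                                  side_amplitudes = c(1, 1),
                                  asymmetry = 0,
                                  phases = c(0, 0, 0),
                                  name = "linear-3") {
  r <- radius_frac * apertureRadius(cfg)
  u <- c(cos(orientation), sin(orientation))
  jn <- linearJones(orientation + pi / 2)
  b <- list(
    beam(r * u, side_amplitudes[1], jn, phases[1],
         lens_offset_x = galvoOffsetX(r * u[1], cfg), cfg = cfg),
    beam(c(0, 0), center_amplitude, jn, phases[2],
         lens_offset_x = 0, cfg = cfg),
    beam(-r * (1 + asymmetry) * u, side_amplitudes[2], jn, phases[3],
         lens_offset_x = galvoOffsetX(-r * (1 + asymmetry) * u[1], cfg),
         cfg = cfg))
  new("PatternPreset", name = name, beams = b, z_dependent = TRUE)
}

#' Galvo micro-rotation realizing a fringe phase step
#'
#' Inverts the galvo phase model for a preset: returns the micro-rotation
#' \eqn{\delta\theta} for which the differential phase across the preset's
#' beam span (largest minus smallest galvo-plane offset) equals
#' \code{phase}. For a two-beam preset this shifts the fringe by exactly
#' \code{phase}.
#'
#' @param preset a \linkS4class{PatternPreset}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @param phase desired differential phase, rad.
#' @return Galvo micro-rotation in rad.
#' @export
galvoStepForPhase <- function(preset, cfg, phase) {
  xs <- vapply(preset@beams, function(b) b@lens_offset_x, numeric(1))
  span <- max(xs) - min(xs)
  if (span <= 0) stop("preset has no galvo-plane beam span; cannot phase-step")
  phase / (cfg@galvo_phase_gain * span)
}

#' Fringe period of a two-beam SIM pattern
#'
#' \eqn{\lambda / (2\,\mathrm{NA}_{\mathrm{eff}})}.
#'
#' @param wavelength wavelength, nm.
#' @param NA_eff effective numerical aperture of the interfering beams.
#' @return Period in nm.
#' @examples
#' fringePeriod(473, 1.5)   # 157.7 nm
#' @export
fringePeriod <- function(wavelength, NA_eff) {
  if (NA_eff <= 0) stop("NA_eff must be > 0")
  wavelength / (2 * NA_eff)
}

#' Theoretical two-beam fringe visibility
#'
#' \eqn{V = 2 A_1 A_2 |o| / (A_1^2 + A_2^2)} for beam amplitudes
#' \eqn{A_1, A_2} and field polarization overlap \eqn{o}. Equal-amplitude
#' beams with unit overlap give V = 1; orthogonal polarizations give V = 0
#' for any amplitudes.
#'
#' @param amplitudes numeric(2), beam amplitudes >= 0, not both zero.
#' @param polarization_overlap real in [-1, 1], the (real part of the)
#'   complex overlap of the two transported field polarizations.
#' @return Visibility in [0, 1].
#' @examples
#' theoreticalVisibility(c(1, 0.5), 1)   # 0.8
#' @export
theoreticalVisibility <- function(amplitudes, polarization_overlap = 1) {
  a <- amplitudes
  if (any(a < 0)) stop("amplitudes must be >= 0")
  if (sum(a^2) == 0) stop("undefined: both amplitudes are zero")
  2 * a[1] * a[2] * abs(polarization_overlap) / sum(a^2)
}
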