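# Physical primitives: pupil-to-wavevector mapping, polarization transport,
# Jones-calculus wave plates, the galvo micro-rotation phase model, and
# closed-form design formulas (galvo stability, Rayleigh focus size, DMD
# field-coverage bound).

#' Convert a pupil focus position to a plane-wave wavevector
#'
#' Each focus in the back focal plane of the main lens becomes an angled
#' plane wave after the lens. The mapping uses the sine condition
#' \eqn{\sin\theta = |p|/f}: the transverse wavevector is
#' \eqn{k_t = (2\pi n/\lambda)\, p/f} and the axial component completes
#' \eqn{|k| = 2\pi n/\lambda}.
#'
#' @param beam a \linkS4class{Beam}.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @return Numeric 3-vector wavevector in rad/um (x, y, z components).
#' @examples
#' cfg <- opticalConfig()
#' pupilToWavevector(beam(c(0, 0)), cfg)   # on-axis: purely axial
#' @export
pupilToWavevector <- function(beam, cfg) {
  p <- beam@pupil_position
  f <- cfg@focal_length_main
  r <- sqrt(sum(p^2))
  if (r > apertureRadius(cfg) * (1 + 1e-9))
    stop("beam outside aperture: |pupil_position| = ", signif(r, 4),
         " mm exceeds NA*f/n = ", signif(apertureRadius(cfg), 4), " mm")
  k0 <- 2 * pi * cfg@refractive_index / (cfg@wavelength * 1e-3)  # rad/um
  s <- p / f                      # sin(theta) components
  sz <- sqrt(max(0, 1 - sum(s^2)))
  k0 * c(s[1], s[2], sz)
}

#' Transport a pupil-plane Jones vector onto a tilted plane wave
#'
#' Standard aplanatic (meridional-rotation) model: the field component
#' perpendicular to the meridional plane (s) is preserved, while the
#' in-plane (p) component is rotated about the s axis so the field stays
#' orthogonal to the propagation direction. Power is preserved. This is the
#' mechanism by which p-polarized beam pairs lose interference contrast at
#' high tilt (their field overlap falls as \eqn{\cos 2\theta}) while
#' s-polarized pairs do not.
#'
#' @param jones complex 2-vector, pupil-plane polarization (x, y).
#' @param wavevector numeric 3-vector from [pupilToWavevector()].
#' @return Complex 3-vector field polarization, \eqn{|out| = |jones|},
#'   orthogonal to the wavevector.
#' @examples
#' cfg <- opticalConfig()
#' k <- pupilToWavevector(beam(c(20, 0)), cfg)
#' transportPolarization(c(0, 1), k)   # s-polarized: unchanged direction
#' @export
transportPolarization <- function(jones, wavevector) {
  jones <- as.complex(jones)
  kn <- sqrt(sum(wavevector^2))
  if (kn <= 0) stop("degenerate direction: wavevector magnitude must be > 0")
  u <- wavevector / kn
  st <- sqrt(u[1]^2 + u[2]^2)
  if (st < 1e-12) {
    # on-axis: embed the transverse Jones vector directly
    return(c(jones, 0 + 0i))
  }
  phi <- atan2(u[2], u[1])
  ct <- u[3]                       # cos(theta)
  s_hat <- c(-sin(phi), cos(phi), 0)
  p_out <- c(ct * cos(phi), ct * sin(phi), -st)
  s_amp <- -sin(phi) * jones[1] + cos(phi) * jones[2]
  p_amp <- cos(phi) * jones[1] + sin(phi) * jones[2]
  s_amp * as.complex(s_hat) + p_amp * as.complex(p_out)
}

#' Fraction of power in the s-polarized component
#'
#' For a beam interfering in a (meridional) plane at angle
#' \code{fringe_plane_angle} from the horizontal pupil axis, the s
#' direction is perpendicular to that plane. Returns the fraction of the
#' beam power carried by the s component; s and p fractions sum to one.
#'
#' @param jones complex or numeric 2-vector, nonzero.
#' @param fringe_plane_angle angle of the interference plane from
#'   horizontal, rad (counterclockwise).
#' @return Fraction in [0, 1].
#' @examples
#' sFraction(c(1, 0), pi / 3)   # horizontal beam, plane at 60 deg: 0.75
#' @export
sFraction <- function(jones, fringe_plane_angle) {
  jones <- as.complex(jones)
  pw <- sum(Mod(jones)^2)
  if (pw <= 0) stop("undefined polarization: jones vector must be nonzero")
  s_hat <- c(-sin(fringe_plane_angle), cos(fringe_plane_angle))
  Mod(sum(Conj(as.complex(s_hat)) * jones))^2 / pw
}

#' Jones matrix of a wave plate
#'
#' @param plate a \linkS4class{WavePlate}.
#' @return Complex 2 x 2 Jones matrix (fast axis retardance convention:
#'   quarter plate = diag(1, i) in its own frame).
#' @export
jonesMatrix <- function(plate) {
  a <- plate@fast_axis_angle
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ret <- if (plate@kind == "quarter") 1i else -1 + 0i   # exp(i*pi/2), exp(i*pi)
  R %*% diag(c(1 + 0i, ret)) %*% t(R)
}

#' Double pass through a wave plate
#'
#' A beam reflected off a mirror behind a quarter-wave plate traverses it
#' twice, so the plate acts as a half-wave plate at the same fast axis:
#' linear polarization is mirrored about the fast axis (horizontal in, fast
#' axis at 45 degrees, gives vertical out). Power is preserved.
#'
#' @param jones complex or numeric 2-vector.
#' @param plate a \linkS4class{WavePlate}; \code{kind = "quarter"} is the
#'   double-pass contract (a half plate double-passed is a full wave plate,
#'   i.e. identity up to phase).
#' @return Complex 2-vector.
#' @examples
#' doublePassWaveplate(c(1, 0), wavePlate("quarter", pi / 4))  # -> vertical
#' @export
doublePassWaveplate <- function(jones, plate) {
  M <- jonesMatrix(plate)
  as.complex(M %*% M %*% as.complex(jones))
}

#' Phase shift from a galvo micro-rotation
#'
#' The galvo is conjugate to the lens array, so a micro-rotation
#' \code{delta_angle} advances the phase of each beam in proportion to the
#' beam's horizontal offset: \eqn{\phi = g\, x\, \delta\theta} with
#' \eqn{g} the configured gain. Exactly bilinear in its two arguments.
#'
#' @param delta_angle galvo micro-rotation, rad.
#' @param lens_offset_x horizontal beam offset in the galvo plane, mm.
#' @param cfg an \linkS4class{OpticalConfig}.
#' @return Phase in rad.
#' @export
galvoPhase <- function(delta_angle, lens_offset_x, cfg) {
  cfg@galvo_phase_gain * lens_offset_x * delta_angle
}

#' Required galvo angular stability
#'
#' To hold the relative phase of the outermost beams to a fraction of a
#' wavelength, the galvo must be stable to
#' \eqn{\arctan(\lambda \cdot \mathrm{fraction} / \mathrm{separation})}.
#'
#' @param wavelength wavelength, nm.
#' @param phase_fraction fraction of a wavelength to hold (e.g. 1/10).
#' @param separation beam separation on the galvo, mm.
#' @return Required stability in rad.
#' @examples
#' requiredGalvoStability(488, 1/10, 2) * 1e6   # ~24 urad
#' @export
requiredGalvoStability <- function(wavelength, phase_fraction, separation) {
  if (separation <= 0) stop("separation must be > 0 (mm)")
  if (phase_fraction < 0) stop("phase_fraction must be >= 0")
  atan(wavelength * 1e-6 * phase_fraction / separation)
}

#' Rayleigh-criterion focus diameter
#'
#' Diameter of the focus formed when a beam of diameter \code{beam_diameter}
#' is focused by a lens of focal length \code{focal_length}:
#' \eqn{d \approx 0.61 \lambda f / D}.
#'
#' @param wavelength wavelength, nm.
#' @param focal_length lens focal length, mm.
#' @param beam_diameter beam diameter at the lens, mm.
#' @return Focus diameter in um.
#' @examples
#' rayleighFocusDiameter(473, 200, 0.1)   # ~577 um
#' @export
rayleighFocusDiameter <- function(wavelength, focal_length, beam_diameter) {
  if (wavelength <= 0 || focal_length <= 0 || beam_diameter <= 0)
    stop("all arguments must be > 0")
  0.61 * (wavelength * 1e-3) * focal_length / beam_diameter  # um
}

#' Maximum illuminated area of a DMD-projected SIM pattern
#'
#' A digital micromirror device must Nyquist-sample the SIM fringe (period
#' \eqn{\lambda/2\mathrm{NA}}) with two mirror pixels per period, capping
#' the sample-referred pixel pitch at \eqn{\lambda/4\mathrm{NA}} and hence
#' the illuminated rectangle at \code{pixels} times that pitch. Compared
#' against the objective field of view (field number / magnification).
#'
#' @param pixels integer 2-vector, DMD resolution (long, short side).
#' @param wavelength wavelength, nm.
#' @param NA_obj numerical aperture at the objective.
#' @param field_number objective field number, mm.
#' @param magnification objective magnification.
#' @return List with \code{area} (2-vector, um), \code{fov_diameter} (um)
#'   and \code{coverage} (illuminated rectangle area over field circle
#'   area).
#' @examples
#' dmdIlluminationBound(c(4096, 2176), 473, 1.5, 22, 60)
#' @export
dmdIlluminationBound <- function(pixels, wavelength, NA_obj, field_number,
                                 magnification) {
  if (any(pixels <= 0) || wavelength <= 0 || NA_obj <= 0 ||
      field_number <= 0 || magnification <= 0)
    stop("all arguments must be > 0")
  pitch <- wavelength * 1e-3 / (4 * NA_obj)       # um on the sample
  area <- pixels * pitch
  fov <- field_number * 1e3 / magnification       # um
  coverage <- prod(area) / (pi * (fov / 2)^2)
  list(area = area, fov_diameter = fov, coverage = coverage)
}
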