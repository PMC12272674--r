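# Synthetic sample generation: seeded sparse bead phantoms (optionally with
# sub-diffraction "resolution pairs") and the scalar Airy detection PSF/OTF.

#' Generate a sparse fluorescent bead phantom
#'
#' Beads are placed uniformly at random inside the field with a minimum
#' pairwise separation (rejection sampling with bounded retries).
#' Optionally, a number of "resolution pairs" is added: pairs of beads at a
#' stated sub-diffraction spacing (default 100 nm) used as two-point
#' resolution targets. Reproducible for a fixed seed; the caller's RNG
#' state is untouched.
#'
#' @param n_beads number of single beads (>= 1 total placements including
#'   pairs).
#' @param fov field extent, um; scalar or c(x, y).
#' @param min_separation minimum center-to-center separation between
#'   placements, um.
#' @param seed integer seed.
#' @param n_pairs number of resolution pairs to add.
#' @param pair_separation_nm spacing of each resolution pair, nm.
#' @param pair_angle axis of the pairs, rad from horizontal; NULL draws a
#'   random axis per pair.
#' @param pair_clearance minimum distance between a pair's center and any
#'   other placement, um; defaults to \code{min_separation}. A larger
#'   clearance keeps the two-point resolution targets free of
#'   neighbouring beads, as one would pick an isolated pair to measure.
#' @param bead_diameter physical bead diameter, nm.
#' @param intensity mean bead brightness (expected peak photons scale).
#' @param intensity_cv coefficient of variation of per-bead brightness.
#' @param max_tries placement retries before giving up.
#' @return A \linkS4class{BeadPhantom}.
#' @examples
#' generateBeadPhantom(20, fov = 10, seed = 1)
#' @export
generateBeadPhantom <- function(n_beads, fov = 16, min_separation = 0.8,
                                seed = 1, n_pairs = 0,
                                pair_separation_nm = 100,
                                pair_angle = NULL, pair_clearance = NULL,
                                bead_diameter = 100, intensity = 1,
                                intensity_cv = 0, max_tries = 5000) {
  if (n_beads < 1 && n_pairs < 1) stop("need at least one bead")
  fov <- rep(fov, length.out = 2)
  withSeed(seed, {
    margin <- min(fov) * 0.03 + pair_separation_nm * 5e-4
    lo <- -fov / 2 + margin
    hi <- fov / 2 - margin
    if (is.null(pair_clearance)) pair_clearance <- min_separation
    anchors <- matrix(numeric(0), 0, 2)
    n_anchor <- n_beads + n_pairs
    tries <- 0
    # pair anchors are placed first so their (possibly larger) clearance
    # is honoured by every later placement
    while (nrow(anchors) < n_anchor) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      cand_is_pair <- nrow(anchors) < n_pairs
      ok <- nrow(anchors) == 0 || {
        d <- sqrt(rowSums(sweep(anchors, 2, cand)^2))
        req <- rep(min_separation, nrow(anchors))
        if (n_pairs > 0)
          req[seq_len(min(n_pairs, nrow(anchors)))] <- pair_clearance
        if (cand_is_pair) req[] <- pair_clearance
        all(d >= req)
      }
      if (ok) anchors <- rbind(anchors, cand)
      tries <- tries + 1
      if (tries > max_tries)
        stop("infeasible packing: could not place ", n_anchor,
             " beads at min separation ", min_separation, " um")
    }
    # pair anchors first in the list; reorder so singles come first
    if (n_pairs > 0)
      anchors <- rbind(anchors[-seq_len(n_pairs), , drop = FALSE],
                       anchors[seq_len(n_pairs), , drop = FALSE])
    pos <- anchors[seq_len(n_beads), , drop = FALSE]
    if (n_pairs > 0) {
      sep_um <- pair_separation_nm / 1000
      for (i in seq_len(n_pairs)) {
        ctr <- anchors[n_beads + i, ]
        ang <- if (is.null(pair_angle)) stats::runif(1, 0, pi) else pair_angle
        d <- sep_um / 2 * c(cos(ang), sin(ang))
        pos <- rbind(pos, ctr + d, ctr - d)
      }
    }
    n <- nrow(pos)
    ints <- rep(intensity, n)
    if (intensity_cv > 0)
      ints <- ints * pmax(0.05, stats::rnorm(n, 1, intensity_cv))
    dimnames(pos) <- NULL
    new("BeadPhantom", positions = pos, intensities = ints,
        bead_diameter = bead_diameter, fov = fov, seed = as.integer(seed))
  })
}

#' Widefield detection point spread function
#'
#' Scalar paraxial Airy pattern
#' \eqn{\mathrm{PSF}(r) \propto (2 J_1(v)/v)^2},
#' \eqn{v = 2\pi\,\mathrm{NA}\, r/\lambda}, sampled on the camera grid and
#' normalized to unit sum. Its OTF is band-limited at
#' \eqn{2\mathrm{NA}/\lambda}. A warning is issued when the pixel pitch
#' undersamples that cutoff (pitch above \eqn{\lambda/4\mathrm{NA}}).
#'
#' @param emission_wavelength emission wavelength, nm.
#' @param NA_det detection numerical aperture.
#' @param pixel_size pixel pitch, nm.
#' @param radius_px kernel half-width in pixels; default covers ~10 Airy
#'   radii.
#' @return Square numeric matrix of odd size, unit sum, with attributes
#'   \code{pixel_size} (nm), \code{wavelength} and \code{NA}.
#' @examples
#' psf <- widefieldPsf(520, 1.333, 65)
#' sum(psf)
#' @export
widefieldPsf <- function(emission_wavelength, NA_det, pixel_size,
                         radius_px = NULL) {
  if (NA_det <= 0) stop("NA_det must be > 0")
  nyq <- emission_wavelength / (4 * NA_det)
  if (pixel_size > nyq)
    warning(sprintf(
      "pixel size %.0f nm undersamples the OTF cutoff (Nyquist %.0f nm)",
      pixel_size, nyq))
  airy_r <- 0.61 * emission_wavelength / NA_det    # nm
  if (is.null(radius_px)) radius_px <- ceiling(10 * airy_r / pixel_size)
  ax <- (-radius_px):radius_px * pixel_size
  r <- sqrt(outer(ax^2, ax^2, "+"))
  v <- 2 * pi * NA_det * r / emission_wavelength
  psf <- matrix(1, nrow(r), ncol(r))
  nz <- v > 1e-12
  psf[nz] <- (2 * besselJ(v[nz], 1) / v[nz])^2
  psf <- psf / sum(psf)
  attr(psf, "pixel_size") <- pixel_size
  attr(psf, "wavelength") <- emission_wavelength
  attr(psf, "NA") <- NA_det
  psf
}

#' Analytic incoherent (Airy) OTF
#'
#' The classic autocorrelation-of-pupil OTF of an aberration-free circular
#' aperture: \eqn{(2/\pi)(\arccos\rho - \rho\sqrt{1-\rho^2})} for
#' normalized frequency \eqn{\rho = f / (2\mathrm{NA}/\lambda) \le 1},
#' zero beyond.
#'
#' @param freq spatial frequency magnitude(s), cycles/um.
#' @param emission_wavelength emission wavelength, nm.
#' @param NA_det detection numerical aperture.
#' @return OTF values in [0, 1].
#' @export
airyOtf <- function(freq, emission_wavelength, NA_det) {
  fc <- 2 * NA_det / (emission_wavelength * 1e-3)   # cycles/um
  rho <- pmin(abs(freq) / fc, 1)
  (2 / pi) * (acos(rho) - rho * sqrt(1 - rho^2))
}

# 2D OTF matrix on an FFT-layout grid of size ny x nx with real-space pixel
# pitch px_um, optionally shifted by `shift` (cycles/um).
otfGrid <- function(ny, nx, px_um, emission_wavelength, NA_det,
                    shift = c(0, 0)) {
  fy <- fftFreq(ny) / px_um
  fx <- fftFreq(nx) / px_um
  fr <- sqrt(outer((fy - shift[1])^2, (fx - shift[2])^2, "+"))
  airyOtf(fr, emission_wavelength, NA_det)
}
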