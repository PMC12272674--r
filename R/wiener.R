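# Wiener SIM recombination and widefield Wiener deconvolution.
#
# Bands are upsampled onto a 2x Fourier canvas, the order +/-1 bands are
# shifted to their true frequencies by real-space carrier multiplication,
# re-phased and de-modulated against the order-0 band over the OTF overlap
# region, and combined with generalized Wiener weights plus a triangle
# apodization to the extended support.

# Zero-pad an FFT-layout spectrum onto a 2x canvas (Fourier upsampling).
pad2Spectrum <- function(B) {
  padSpectrumTo(B, 2 * nrow(B), 2 * ncol(B))
}

# Shift a band to its true frequencies: spectrum(k) <- spectrum(k + p).
# p in cycles/um, grid pitch px_um (of the 2x canvas).
shiftBand <- function(B2, p, px_um) {
  NY <- nrow(B2); NX <- ncol(B2)
  b <- stats::fft(B2, inverse = TRUE) / (NY * NX)
  xs <- (seq_len(NX) - 1) * px_um
  ys <- (seq_len(NY) - 1) * px_um
  carrier <- outer(exp(-2i * pi * p[2] * ys), exp(-2i * pi * p[1] * xs))
  stats::fft(b * carrier)
}

#' Reconstruct a super-resolved SIM image
#'
#' Generalized Wiener recombination of separated bands over all
#' orientations on a 2x upsampled grid: each order +/-1 band is shifted to
#' its true frequency position, its residual global phase and modulation
#' depth are estimated against the order-0 band over the OTF overlap
#' region, and all bands are combined as
#' \eqn{\hat{S} = A \sum_b \mathrm{OTF}_b^{*} B_b / (\sum_b
#' |\mathrm{OTF}_b|^2 + w)}
#' with a triangle apodization \eqn{A} falling to zero at the extended
#' cutoff. The output is clamped to nonnegative values.
#'
#' @param bands a \linkS4class{BandSet}, or a list of per-orientation band
#'   lists as returned by [separateBands()] (then supply
#'   \code{pixel_size}).
#' @param params a \linkS4class{SimParams} with one entry per orientation.
#' @param emission_wavelength emission wavelength, nm.
#' @param NA_det detection NA used for the OTF model.
#' @param wiener_w Wiener regularization parameter.
#' @param apodize logical, apply the triangle apodization.
#' @param pixel_size camera pixel pitch, um (for bare band lists).
#' @return An \linkS4class{IntensityGrid} on the 2x grid (half the pixel
#'   pitch of the input frames).
#' @seealso [separateBands()], [estimateSimParams()],
#'   [deconvolveWidefield()]
#' @export
wienerReconstruct <- function(bands, params, emission_wavelength = 520,
                              NA_det = 1.333, wiener_w = 0.05,
                              apodize = TRUE, pixel_size = NULL) {
  if (is(bands, "BandSet")) {
    blist <- bands@bands
    if (is.null(pixel_size)) pixel_size <- bands@pixel_size
  } else blist <- bands
  if (is.null(pixel_size)) stop("pixel_size required")
  stopifnot(length(blist) == length(params@orientations))
  ny <- nrow(blist[[1]]$b0); nx <- ncol(blist[[1]]$b0)
  NY <- 2 * ny; NX <- 2 * nx
  px2 <- pixel_size / 2
  fc <- 2 * NA_det / (emission_wavelength * 1e-3)

  num <- matrix(0 + 0i, NY, NX)
  den <- matrix(0, NY, NX)
  pmax_mag <- 0
  otf0 <- otfGrid(NY, NX, px2, emission_wavelength, NA_det)
  for (i in seq_along(blist)) {
    b <- blist[[i]]
    p <- params@orientations[[i]]$fringe_vector   # (fx, fy) cycles/um
    pmax_mag <- max(pmax_mag, sqrt(sum(p^2)))
    B0 <- pad2Spectrum(b$b0)
    # shifted band bp(k + p) = OTF(k + p) S(k): its effective OTF is the
    # detection OTF displaced by -p (support extended on that side)
    Bp <- shiftBand(pad2Spectrum(b$bp), p, px2)
    Bm <- shiftBand(pad2Spectrum(b$bm), -p, px2)
    otf_p <- otfGrid(NY, NX, px2, emission_wavelength, NA_det,
                     shift = c(-p[2], -p[1]))
    otf_m <- otfGrid(NY, NX, px2, emission_wavelength, NA_det,
                     shift = c(p[2], p[1]))
    # residual modulation/global-phase factor from the overlap with order
    # 0; weighting by the OTF product keeps every overlap pixel in play at
    # its natural SNR (a hard support threshold leaves too few pixels when
    # the fringe frequency approaches the detection cutoff)
    wt <- otf0 * otf_p
    use_orders <- FALSE
    if (sum(wt) > 0) {
      cnum <- sum(wt * Conj(B0) * Bp)
      cden <- sum(wt * Mod(B0)^2 * (otf_p / pmax(otf0, 1e-6)))
      cfac <- cnum / cden
      if (is.finite(Mod(cfac)) && Mod(cfac) > 0.02) {
        # demodulate; below 2% modulation the shifted bands carry no
        # usable signal and are dropped (the zero-modulation limit then
        # reduces exactly to widefield Wiener deconvolution)
        Bp <- Bp / cfac
        Bm <- Bm / Conj(cfac)
        params@orientations[[i]]$modulation <- min(1, Mod(cfac))
        use_orders <- TRUE
      }
    }
    num <- num + otf0 * B0
    den <- den + otf0^2
    if (use_orders) {
      num <- num + otf_p * Bp + otf_m * Bm
      den <- den + otf_p^2 + otf_m^2
    }
  }
  S <- num / (den + wiener_w)
  if (apodize) {
    fy <- fftFreq(NY) / px2
    fx <- fftFreq(NX) / px2
    frq <- sqrt(outer(fy^2, fx^2, "+"))
    k_apo <- fc + pmax_mag
    S <- S * pmax(0, 1 - frq / k_apo)
  }
  img <- Re(stats::fft(S, inverse = TRUE)) / (NY * NX)
  img[img < 0] <- 0
  intensityGrid(img, px2)
}

#' Wiener deconvolution of a widefield image
#'
#' \eqn{\hat{S} = F\,\mathrm{OTF} / (\mathrm{OTF}^2 + w)} with the
#' analytic Airy OTF. Energy (the DC term) is preserved to within
#' \eqn{w/(1+w)}.
#'
#' @param image numeric matrix or \linkS4class{IntensityGrid}.
#' @param emission_wavelength emission wavelength, nm.
#' @param NA_det detection NA.
#' @param wiener_w regularization parameter.
#' @param pixel_size pixel pitch, um (taken from the grid when omitted).
#' @return An \linkS4class{IntensityGrid}.
#' @export
deconvolveWidefield <- function(image, emission_wavelength = 520,
                                NA_det = 1.333, wiener_w = 0.02,
                                pixel_size = NULL) {
  if (is(image, "IntensityGrid")) {
    m <- image@values
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (is.null(pixel_size)) pixel_size <- image@pixel_size
  } else m <- image
  if (is.null(pixel_size)) stop("pixel_size required")
  ny <- nrow(m); nx <- ncol(m)
  otf <- otfGrid(ny, nx, pixel_size, emission_wavelength, NA_det)
  S <- stats::fft(m) * otf / (otf^2 + wiener_w)
  out <- Re(stats::fft(S, inverse = TRUE)) / (ny * nx)
  # clamp ringing negatives but keep the total flux of the raw estimate
  raw_sum <- sum(out)
  out[out < 0] <- 0
  if (sum(out) > 0 && raw_sum > 0) out <- out * raw_sum / sum(out)
  intensityGrid(out, pixel_size)
}

#' End-to-end SIM reconstruction from a frame stack
#'
#' Convenience pipeline: drops transition frames, estimates pattern
#' parameters per orientation ([estimateSimParams()]), separates bands
#' ([separateBands()]) and recombines them ([wienerReconstruct()]).
#'
#' @param stack a \linkS4class{FrameStack} with orientation/phase metadata.
#' @param params optional precomputed \linkS4class{SimParams}; estimated
#'   from the stack when NULL.
#' @param emission_wavelength emission wavelength, nm.
#' @param NA_det detection NA for the reconstruction OTF.
#' @param wiener_w Wiener parameter.
#' @param apodize logical.
#' @return List with \code{image} (\linkS4class{IntensityGrid}, 2x grid),
#'   \code{params} (\linkS4class{SimParams}) and \code{widefield}
#'   (\linkS4class{IntensityGrid}, camera grid, mean of the frames used).
#' @export
reconstructSim <- function(stack, params = NULL, emission_wavelength = 520,
                           NA_det = 1.333, wiener_w = 0.05,
                           apodize = TRUE) {
  meta <- stack@meta
  keep <- !meta$transition
  # drop duplicate dwell frames: keep the last frame of each
  # (cycle, orientation, phase) group so every phase appears once per cycle
  key <- paste(meta$cycle, meta$orientation, meta$phase_index)
  last <- !duplicated(key, fromLast = TRUE)
  use <- keep & last
  orients <- sort(unique(meta$orientation[use]))
  if (is.null(params)) {
    groups <- lapply(orients, function(o)
      stack@frames[, , use & meta$orientation == o, drop = FALSE])
    params <- estimateSimParams(groups, pixel_size = stack@pixel_size)
  }
  blist <- lapply(seq_along(orients), function(i) {
    o <- orients[i]
    idx <- which(use & meta$orientation == o)
    fr <- lapply(idx, function(j) stack@frames[, , j])
    separateBands(fr, params@orientations[[i]]$phases)
  })
  wf_idx <- which(use)
  wf <- apply(stack@frames[, , wf_idx, drop = FALSE], c(1, 2), mean)
  img <- wienerReconstruct(blist, params, emission_wavelength, NA_det,
                           wiener_w, apodize, pixel_size = stack@pixel_size)
  list(image = img, params = params,
       widefield = intensityGrid(wf, stack@pixel_size))
}
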