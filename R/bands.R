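# SIM band separation and pattern-parameter estimation.
#
# Forward model per orientation: with illumination
# 1 + m*cos(2*pi*p.x + phi_j), the Fourier transform of phase-stepped
# frame j is D_j(k) = b0(k) + (m/2) e^{i phi_j} bp(k) + (m/2) e^{-i phi_j}
# bm(k), where b0 = OTF*S, bp(k) = OTF(k)*S(k - p), bm(k) = OTF(k)*S(k + p).
# separateBands solves this 3x3 (or overdetermined) system per frequency
# pixel; the modulation depth m is folded into the recovered bp/bm.

#' Separate the frequency bands of one SIM orientation
#'
#' Solves the per-pixel linear mixing model relating >= 3 phase-stepped
#' images to the order 0 and +/-1 object bands. Phases must be distinct
#' and non-degenerate (the mixing matrix must be well conditioned); the
#' modulation depth is absorbed into the order +/-1 bands.
#'
#' @param frames list of >= 3 numeric matrices (one per phase step), or a
#'   3D array \code{[ny, nx, phase]}.
#' @param phases illumination phases, rad, one per frame.
#' @return List with complex matrices \code{b0}, \code{bp}, \code{bm}
#'   (standard FFT layout). For real input frames \code{bm(k)} is the
#'   conjugate mirror of \code{bp(-k)}.
#' @examples
#' ny <- 32; nx <- 32
#' x <- outer(rep(1, ny), 0:(nx - 1))
#' phases <- c(0, 2 * pi / 3, 4 * pi / 3)
#' frames <- lapply(phases, function(p) 1 + 0.8 * cos(2 * pi * 5 * x / nx + p))
#' b <- separateBands(frames, phases)
#' @export
separateBands <- function(frames, phases) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  nph <- length(frames)
  if (nph < 3) stop("need >= 3 phase-stepped frames")
  if (length(phases) != nph) stop("one phase per frame required")
  M <- cbind(1, 0.5 * exp(1i * phases), 0.5 * exp(-1i * phases))
  sv <- svd(M)$d
  if (sv[length(sv)] <= sv[1] * 1e-8)
    stop("singular mixing: phases are degenerate (equal or evenly ",
         "conflicting); provide distinct, well-spread phases")
  Minv <- if (nph == 3) solve(M) else
    solve(Conj(t(M)) %*% M) %*% Conj(t(M))   # least squares for > 3 phases
  Fs <- lapply(frames, stats::fft)
  comb <- function(row) {
    acc <- 0
    for (j in seq_len(nph)) acc <- acc + Minv[row, j] * Fs[[j]]
    acc
  }
  list(b0 = comb(1), bp = comb(2), bm = comb(3))
}

# Refine a fringe frequency by maximizing the product-spectrum magnitude
# |DFT[frame * reference](s)| summed over frames, over continuous s
# (cycles/pixel).
refineFringeFreq <- function(prods, s0) {
  obj <- function(s) -sum(vapply(prods, function(p) Mod(dftAt(p, s)),
                                 numeric(1)))
  opt <- stats::optim(s0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  opt$par
}

#' Estimate SIM pattern parameters from phase-stepped frames
#'
#' Per orientation: forms the widefield reference (mean of the frames),
#' locates the fringe wavevector as the off-DC peak of the Fourier
#' correlation between each frame and the reference (see
#' [fourierCorrelationTrace()]), refines it to sub-pixel precision by
#' maximizing the correlation magnitude over continuous frequency, and
#' reads each frame's illumination phase off the correlation argument at
#' the refined peak. The modulation depth is estimated from the ratio of
#' the correlation peak to the reference's windowed power (a lower bound:
#' it carries the OTF attenuation at the fringe frequency).
#'
#' The recovered phases share an arbitrary object-dependent global offset
#' per orientation; [wienerReconstruct()] resolves it against the order-0
#' band in the overlap region.
#'
#' @param stack a \linkS4class{FrameStack} (frames grouped by the
#'   \code{orientation} metadata column; transition frames are dropped), or
#'   a list of 3D arrays, one per orientation.
#' @param pixel_size pixel pitch, um (taken from the stack when omitted).
#' @param window_alpha Tukey taper fraction.
#' @param min_snr required peak-to-median-floor ratio; below it the
#'   orientation fails with an estimation error.
#' @return A \linkS4class{SimParams}.
#' @export
estimateSimParams <- function(stack, pixel_size = NULL, window_alpha = 0.25,
                              min_snr = 5) {
  if (is(stack, "FrameStack")) {
    if (is.null(pixel_size)) pixel_size <- stack@pixel_size
    meta <- stack@meta
    keep <- !meta$transition
    orients <- sort(unique(meta$orientation[keep]))
    groups <- lapply(orients, function(o) {
      stack@frames[, , keep & meta$orientation == o, drop = FALSE]
    })
  } else {
    if (is.null(pixel_size)) stop("pixel_size required for bare arrays")
    groups <- stack
  }
  res <- lapply(groups, function(arr) {
    ny <- dim(arr)[1]; nx <- dim(arr)[2]; nf <- dim(arr)[3]
    if (nf < 3) stop("need >= 3 phase frames per orientation")
    w <- tukeyWindow(ny, nx, window_alpha)
    ref <- apply(arr, c(1, 2), mean)
    ref_w <- w * ref
    denom <- sum(ref_w^2)
    # widefield component removed per frame: the product spectrum then
    # peaks at the fringe wavevector rather than at the object's own
    # DC-centered power
    prods <- lapply(seq_len(nf),
                    function(i) (w * (arr[, , i] - ref)) * ref_w)
    fy <- fftFreq(ny); fx <- fftFreq(nx)
    rr <- sqrt(outer(fy^2, fx^2, "+"))
    dc_mask <- rr <= 3 / max(ny, nx)
    Gsum <- 0
    for (p in prods) Gsum <- Gsum + Mod(stats::fft(p))^2
    A <- sqrt(Gsum)
    W <- A / ringEnvelope(A)      # whitened magnitude for peak finding
    W[dc_mask] <- 0
    med <- stats::median(W[W > 0])
    j <- which.max(W)
    iy <- (j - 1) %% ny + 1; ix <- (j - 1) %/% ny + 1
    if (!is.finite(med) || med <= 0 || W[iy, ix] < min_snr * med)
      stop("estimation failure: no detectable fringe peak above the noise ",
           "floor (widefield-only or zero-modulation input?)")
    fr <- subpixelPeak(W, iy, ix)
    s0 <- canonicalFreq(c(fy[iy] + fr[1] / ny, fx[ix] + fr[2] / nx))
    s <- refineFringeFreq(prods, s0)
    s <- canonicalFreq(s)
    vals <- vapply(prods, function(p) dftAt(p, s), complex(1))
    # de-bias the common offset left by residual fringe in the reference
    vals <- debiasPhasors(vals, rep(TRUE, length(vals)))
    phases <- Arg(vals)
    phases <- refineClusterPhases(lapply(prods, stats::fft), s, phases,
                                  anchor = which.max(Mod(vals)), ny, nx)
    modulation <- min(1, mean(2 * Mod(vals) / denom))
    list(fringe_vector = c(s[2], s[1]) / pixel_size,  # (fx, fy) cycles/um
         phases = phases, modulation = modulation)
  })
  new("SimParams", orientations = res)
}
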