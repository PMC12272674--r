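# Pattern characterization: 2D sinusoid (visibility) fitting,
# Fourier-correlation amplitude/phase/orientation traces, transition-frame
# detection, galvo voltage-to-phase calibration, and plateau phase
# repeatability.

# Refine the phases of one fringe cluster by alternating self-calibration.
#
# Model per frame at every frequency bin s near the fringe peak:
# G_j(s) = X(s) e^{i phi_j} + Y(s) e^{-i phi_j} + Z(s), with X the fringe
# hump, Y conjugate-hump (speckle) leakage and Z a frame-independent
# residue. With >= 4 frames at distinct phases the per-bin fields and the
# phases are jointly identifiable: alternate between solving the linear
# least-squares for (X, Y, Z) given the phases and re-optimizing each
# frame's phase given the fields. With only 3 distinct phases the system
# has zero degrees of freedom and the initial phases are returned
# unchanged.
refineClusterPhases <- function(Gm, s, phi0, anchor, ny, nx,
                                use = seq_along(Gm), n_iter = 6) {
  distinct <- length(unique(round(phi0[use], 1)))
  if (distinct < 4) return(phi0)
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  d2 <- outer((fy - s[1])^2, (fx - s[2])^2, "+")
  r <- 4 / min(ny, nx)
  Msel <- which(d2 <= r^2)
  if (length(Msel) < 8) return(phi0)
  V <- vapply(Gm, function(G) G[Msel], complex(length(Msel)))  # [s, frame]
  Vu <- V[, use, drop = FALSE]
  phi <- phi0
  for (it in seq_len(n_iter)) {
    pu <- phi[use]
    D <- cbind(exp(1i * pu), exp(-1i * pu), 1)
    XYZ <- tryCatch(t(qr.solve(D, t(Vu))), error = function(e) NULL)
    if (is.null(XYZ)) return(phi)
    X <- XYZ[, 1]; Y <- XYZ[, 2]; Z <- XYZ[, 3]
    r2 <- sum(Conj(X) * Y)
    newphi <- vapply(seq_along(phi), function(j) {
      vz <- V[, j] - Z
      p <- sum(Conj(X) * vz)
      q <- sum(Conj(Y) * vz)
      f <- function(a) {
        u <- exp(1i * a)
        -2 * Re(Conj(p) * u) - 2 * Re(Conj(q) * Conj(u)) +
          2 * Re(Conj(r2) * u^2)
      }
      o <- stats::optimize(f, c(-pi, pi))
      # optimize() can miss a minimum at the interval edge; fall back to
      # the leading-order estimate when it does
      if (f(Arg(p)) < o$objective) Arg(p) else o$minimum
    }, numeric(1))
    phi <- wrapPi(newphi - newphi[anchor] + phi0[anchor])
  }
  phi
}

# Off-DC Fourier peak of a real matrix: returns NULL when no peak stands
# above the noise floor, else list(iy, ix, frac = c(dy, dx), mag).
offDcPeak <- function(m, dc_radius = 2, min_snr = 8) {
  F <- stats::fft(m)
  A <- Mod(F)
  ny <- nrow(A); nx <- ncol(A)
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  rr <- sqrt(outer(fy^2, fx^2, "+"))
  A[rr <= dc_radius / max(ny, nx)] <- 0
  med <- stats::median(A[A > 0])
  i <- which.max(A)
  iy <- (i - 1) %% ny + 1
  ix <- (i - 1) %/% ny + 1
  if (!is.finite(med) || med <= 0 || A[iy, ix] < min_snr * med) return(NULL)
  list(iy = iy, ix = ix, frac = subpixelPeak(A, iy, ix), mag = A[iy, ix],
       F = F)
}

# Canonical half-plane for a fringe frequency (resolves the +/-k ambiguity):
# keep fx > 0, or fx == 0 and fy > 0.
canonicalFreq <- function(s) {
  if (s[2] < 0 || (abs(s[2]) < 1e-12 && s[1] < 0)) -s else s
}

#' Fit a 2D sinusoid with offset to a fringe image
#'
#' Fits \eqn{I(r) = a\,(1 + V\cos(2\pi f \cdot r + \phi))} by least
#' squares: the fringe frequency is seeded from the off-DC Fourier peak and
#' refined by numerical optimization, with the amplitude coefficients
#' solved linearly at each trial frequency. The visibility follows the
#' \eqn{(I_{max}-I_{min})/(I_{max}+I_{min})} convention, which for this
#' model equals \eqn{V}.
#'
#' @param image an \linkS4class{IntensityGrid} or numeric matrix.
#' @param pixel_size pixel pitch in um (taken from the grid when omitted).
#' @param initial_guess optional numeric(2) fringe frequency (cycles/um) to
#'   seed the fit instead of the Fourier peak.
#' @return A \linkS4class{SinusoidFit}. Errors with "no fringe" when the
#'   image has no off-DC Fourier peak above the noise floor.
#' @examples
#' cfg <- opticalConfig()
#' ig <- intensity(synthesizeField(twoBeamPreset(cfg), cfg, nx = 128,
#'                                 ny = 128, pixel_size = 0.04))
#' fitSinusoid2d(ig)
#' @export
fitSinusoid2d <- function(image, pixel_size = NULL, initial_guess = NULL) {
  if (is(image, "IntensityGrid")) {
    m <- image@values
    if (length(dim(m)) == 3) m <- m[, , 1]
    if (is.null(pixel_size)) pixel_size <- image@pixel_size
  } else {
    m <- image
    if (is.null(pixel_size)) stop("pixel_size required for a bare matrix")
  }
  m <- matrix(as.numeric(m), nrow(m), ncol(m))
  ny <- nrow(m); nx <- ncol(m)
  x <- axisCoords(nx, pixel_size)
  y <- axisCoords(ny, pixel_size)
  X <- matrix(rep(x, each = ny), ny, nx)
  Y <- matrix(rep(y, times = nx), ny, nx)

  if (is.null(initial_guess)) {
    pk <- offDcPeak(m)
    if (is.null(pk))
      stop("no fringe: no off-DC Fourier peak above the noise floor")
    fy <- (fftFreq(ny)[pk$iy] + pk$frac[1] / ny) / pixel_size
    fx <- (fftFreq(nx)[pk$ix] + pk$frac[2] / nx) / pixel_size
    f0 <- canonicalFreq(c(fy, fx))
  } else {
    f0 <- canonicalFreq(c(initial_guess[2], initial_guess[1]))
  }

  rssFor <- function(f) {
    arg <- 2 * pi * (f[2] * X + f[1] * Y)
    D <- cbind(1, as.vector(cos(arg)), as.vector(sin(arg)))
    cf <- stats::.lm.fit(D, as.vector(m))$coefficients
    res <- as.vector(m) - D %*% cf
    list(rss = sum(res^2), coef = cf)
  }
  opt <- stats::optim(f0, function(f) rssFor(f)$rss, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 500))
  f <- canonicalFreq(opt$par)
  fin <- rssFor(f)
  a <- fin$coef[1]; b <- fin$coef[2]; cc <- fin$coef[3]
  V <- sqrt(b^2 + cc^2) / a
  phase <- wrap2Pi(atan2(-cc, b))
  new("SinusoidFit", visibility = min(max(V, 0), 1),
      fringe_vector = c(f[2], f[1]), phase = phase, offset = a,
      residual_rms = sqrt(fin$rss / length(m)))
}

#' Fourier-correlation trace of a frame stack
#'
#' For each frame, correlates the frame's Fourier transform against the
#' reference's Fourier transform over frequency shifts; by Parseval this
#' correlation is the Fourier transform of the pixelwise product of the two
#' (windowed) spatial images. Because image formation is linear in the
#' illumination, the reference (widefield) component is subtracted from
#' each frame first, so the product spectrum is free of the object's own
#' DC-centered power and its off-DC maximum sits at the fringe wavevector:
#' the peak amplitude tracks the fringe visibility, its argument the
#' fringe phase, and its position the pattern orientation. Amplitudes are
#' normalized by the reference's windowed power so plateaus are comparable
#' across frames and orientations; a frame with no fringe content (e.g. a
#' transition frame) yields a small amplitude. Peak positions are refined
#' to sub-pixel precision by local quadratic interpolation.
#'
#' Frames are clustered by the location of their correlation peak (one
#' cluster per fringe orientation); a single sub-pixel frequency is refined
#' per cluster from the pooled spectra and every member frame's amplitude
#' and phase are evaluated at that common frequency. Reading all phases of
#' an orientation at one frequency is what makes frame-to-frame phase
#' differences exact; a per-frame frequency would leak its jitter into the
#' phases through the coordinate origin.
#'
#' @param stack a \linkS4class{FrameStack}, or a 3D array \code{[ny, nx,
#'   frame]} (then supply \code{pixel_size}).
#' @param reference optional reference image; defaults to the average of
#'   all frames.
#' @param pixel_size pixel pitch, um (for bare arrays).
#' @param window_alpha Tukey taper fraction applied before the transforms
#'   to suppress ROI-edge leakage.
#' @param dc_radius radius (in frequency pixels) excluded around DC.
#' @param lock_freqs optional matrix of known fringe frequencies (rows of
#'   (fx, fy) in cycles/um): peaks snap to the nearest row and no
#'   refinement is performed, making phases comparable across traces.
#' @return A \linkS4class{PatternEstimate}. The phase origin depends on the
#'   reference and the object, so phase differences between frames are the
#'   meaningful quantity.
#' @export
fourierCorrelationTrace <- function(stack, reference = NULL,
                                    pixel_size = NULL, window_alpha = 0.25,
                                    dc_radius = 2, lock_freqs = NULL) {
  if (is(stack, "FrameStack")) {
    arr <- stack@frames
    if (is.null(pixel_size)) pixel_size <- stack@pixel_size
    meta <- stack@meta
  } else {
    arr <- stack
    if (is.null(pixel_size)) stop("pixel_size required for a bare array")
    meta <- data.frame()
  }
  if (length(dim(arr)) != 3 || dim(arr)[3] < 1)
    stop("input error: need a stack with at least one frame")
  ny <- dim(arr)[1]; nx <- dim(arr)[2]; nf <- dim(arr)[3]
  if (is.null(reference)) {
    if (nf < 2) stop("input error: need >= 2 frames to form an average reference")
    reference <- apply(arr, c(1, 2), mean)
  }
  w <- tukeyWindow(ny, nx, window_alpha)
  ref_w <- w * reference
  denom <- sum(ref_w^2)
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  rr <- sqrt(outer(fy^2, fx^2, "+"))
  dc_mask <- rr <= dc_radius / max(ny, nx)

  amplitude <- numeric(nf); phase <- numeric(nf)
  peak <- matrix(0, nf, 2); peak_px <- matrix(0, nf, 2)

  # pass 1: product images and whitened integer-bin peaks
  prods <- vector("list", nf)
  Gs <- vector("list", nf)
  s_coarse <- matrix(NA_real_, nf, 2)   # (sy, sx) cycles/px
  for (i in seq_len(nf)) {
    P <- (w * (arr[, , i] - reference)) * ref_w
    prods[[i]] <- P
    Gs[[i]] <- stats::fft(P)
    A <- Mod(Gs[[i]])
    W <- A / ringEnvelope(A)      # whitened magnitude for peak finding
    W[dc_mask] <- 0
    j <- which.max(W)
    iy <- (j - 1) %% ny + 1
    ix <- (j - 1) %/% ny + 1
    if (A[iy, ix] > 1e-12 * denom)
      s_coarse[i, ] <- canonicalFreq(c(fy[iy], fx[ix]))
  }

  # pass 2: one common frequency per peak cluster (= fringe orientation)
  tol <- 3 / min(ny, nx)
  cluster <- rep(NA_integer_, nf)
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nf)) {
    if (any(is.na(s_coarse[i, ]))) next
    if (nrow(centers)) {
      d <- sqrt(rowSums(sweep(centers, 2, s_coarse[i, ])^2))
      k <- which.min(d)
    }
    if (nrow(centers) && d[k] < tol) cluster[i] <- k
    else {
      centers <- rbind(centers, s_coarse[i, ])
      cluster[i] <- nrow(centers)
    }
  }
  for (k in seq_len(max(c(cluster, 0), na.rm = TRUE))) {
    mem <- which(cluster == k)
    if (!length(mem)) next
    if (!is.null(lock_freqs)) {
      lf <- rbind(lock_freqs)
      slock <- cbind(lf[, 2], lf[, 1]) * pixel_size   # -> (sy, sx) cyc/px
      d <- sqrt(rowSums(sweep(slock, 2, colMeans(rbind(s_coarse[mem, ])))^2))
      s <- canonicalFreq(slock[which.min(d), ])
    } else {
      Gsum <- 0
      for (i in mem) Gsum <- Gsum + Mod(stats::fft(prods[[i]]))^2
      A <- sqrt(Gsum)
      W <- A / ringEnvelope(A)
      W[dc_mask] <- 0
      j <- which.max(W)
      iy <- (j - 1) %% ny + 1
      ix <- (j - 1) %/% ny + 1
      fr <- subpixelPeak(W, iy, ix)
      s0 <- canonicalFreq(c(fy[iy] + fr[1] / ny, fx[ix] + fr[2] / nx))
      obj <- function(s) -sum(vapply(mem, function(i)
        Mod(dftAt(prods[[i]], s)), numeric(1)))
      s <- canonicalFreq(stats::optim(s0, obj, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 300))$par)
    }
    vals <- vapply(mem, function(i) dftAt(prods[[i]], s), complex(1))
    # remove the common offset induced by residual fringe content in the
    # reference: plateau phasors are K*exp(i*phi_j) plus a shared offset
    ph <- Arg(vals)
    if (max(Mod(vals)) > 0) {
      plateau <- Mod(vals) >= 0.5 * max(Mod(vals))
      dup <- duplicated(round(Arg(vals / vals[which(plateau)[1]]), 1))
      vals <- debiasPhasors(vals, plateau & !dup)
      ph <- Arg(vals)
      if (sum(plateau & !dup) >= 3)
        ph <- refineClusterPhases(Gs[mem], s, ph,
                                  anchor = which.max(Mod(vals)), ny, nx,
                                  use = which(plateau & !dup))
    }
    for (j in seq_along(mem)) {
      i <- mem[j]
      amplitude[i] <- Mod(vals[j]) / denom
      phase[i] <- ph[j]
      peak_px[i, ] <- c(s[2] * nx, s[1] * ny)
      peak[i, ] <- c(s[2], s[1]) / pixel_size
    }
  }
  new("PatternEstimate", amplitude = amplitude, phase = phase, peak = peak,
      peak_px = peak_px, meta = meta)
}

#' Detect transition frames in a correlation trace
#'
#' Flags frames whose correlation amplitude drops below
#' \code{drop_fraction} times the plateau (median) amplitude, and groups
#' them into contiguous runs. Frames exposed while the galvo moves show
#' exactly this amplitude drop.
#'
#' @param estimate a \linkS4class{PatternEstimate}.
#' @param drop_fraction threshold as a fraction of the median amplitude.
#' @return List with \code{indices} (integer frame indices) and
#'   \code{runs} (data.frame with \code{start} and \code{length}).
#' @export
detectTransitions <- function(estimate, drop_fraction = 0.5) {
  a <- estimate@amplitude
  if (!length(a)) stop("empty estimate")
  med <- stats::median(a)
  if (med <= 0)
    stop("degenerate trace: no plateau amplitude to compare against")
  idx <- which(a < drop_fraction * med)
  if (length(idx) == length(a))
    stop("degenerate trace: every frame is below the transition threshold")
  runs <- if (!length(idx)) data.frame(start = integer(0),
                                       length = integer(0))
  else {
    brk <- c(0, which(diff(idx) > 1), length(idx))
    data.frame(
      start = idx[brk[-length(brk)] + 1],
      length = diff(brk))
  }
  list(indices = idx, runs = runs)
}

#' Calibrate galvo voltage against fringe phase
#'
#' Sequentially unwraps the measured phases over the fine voltage scan,
#' fits a least-squares line (phase vs voltage), and solves it for the
#' voltages that realize even phase steps of \code{target_step} (e.g.
#' \eqn{2\pi/3} for three-phase 2D SIM, \eqn{2\pi/5} for five-phase 3D
#' SIM).
#'
#' @param voltages galvo drive voltages, V (>= 3 values).
#' @param phases measured fringe phases, rad (wrapped).
#' @param target_step requested phase step, rad.
#' @return A \linkS4class{GalvoCalibration} whose
#'   \code{voltages_for_steps} realize phases \eqn{0, s, 2s, \ldots} up to
#'   \eqn{2\pi}. Errors when the scan is too coarse to unwrap
#'   unambiguously.
#' @examples
#' v <- seq(0, 1, length.out = 12)
#' cal <- calibrateGalvo(v, (1.5 + 7 * v) %% (2 * pi), 2 * pi / 3)
#' cal@voltages_for_steps
#' @export
calibrateGalvo <- function(voltages, phases, target_step = 2 * pi / 3) {
  if (length(voltages) < 3 || length(voltages) != length(phases))
    stop("need >= 3 (voltage, phase) pairs")
  if (target_step <= 0 || target_step > 2 * pi)
    stop("target_step must be in (0, 2*pi]")
  o <- order(voltages)
  v <- voltages[o]; ph <- phases[o]
  d <- wrapPi(diff(ph))
  if (any(abs(d) > 0.9 * pi))
    stop("calibration ambiguity: phase steps between scan points approach ",
         "pi; use a finer voltage scan")
  un <- cumsum(c(ph[1], d))
  fit <- stats::lm(un ~ v)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < 1e-12) stop("degenerate calibration: zero slope")
  n_steps <- max(2L, as.integer(round(2 * pi / target_step)))
  targets <- (seq_len(n_steps) - 1) * target_step
  vsteps <- (targets - intercept) / slope
  new("GalvoCalibration", slope = slope, intercept = intercept,
      voltages_for_steps = vsteps,
      residual = sqrt(mean(stats::residuals(fit)^2)),
      target_step = target_step)
}

#' Plateau phase repeatability between two traces
#'
#' Compares two correlation traces of the same schedule: per plateau
#' (grouped by schedule metadata when present, else by runs of
#' above-threshold amplitude), the circular mean of the frame-wise phase
#' differences, plus the overall RMS in fractions of \eqn{2\pi}. Transition
#' frames are excluded.
#'
#' @param traceA,traceB \linkS4class{PatternEstimate}s of equal length.
#' @param drop_fraction amplitude threshold used to exclude low-amplitude
#'   frames when metadata is absent.
#' @return List with \code{plateau_diff} (rad, circular mean per plateau)
#'   and \code{rms_fraction} (overall RMS difference as a fraction of
#'   \eqn{2\pi}).
#' @export
phaseRepeatability <- function(traceA, traceB, drop_fraction = 0.5) {
  if (length(traceA@amplitude) != length(traceB@amplitude))
    stop("input error: traces have different lengths")
  n <- length(traceA@amplitude)
  if (nrow(traceA@meta) == n && all(c("orientation", "phase_index") %in%
                                    names(traceA@meta))) {
    keep <- !traceA@meta$transition & !traceB@meta$transition
    grp <- interaction(traceA@meta$orientation, traceA@meta$phase_index,
                       traceA@meta$cycle, drop = TRUE)
  } else {
    medA <- stats::median(traceA@amplitude)
    keep <- traceA@amplitude >= drop_fraction * medA &
      traceB@amplitude >= drop_fraction * stats::median(traceB@amplitude)
    grp <- factor(cumsum(c(TRUE, diff(keep) != 0)))
  }
  d <- wrapPi(traceA@phase - traceB@phase)
  circMean <- function(x) Arg(mean(exp(1i * x)))
  plateau <- tapply(d[keep], droplevels(grp[keep]), circMean)
  rms <- sqrt(mean(wrapPi(d[keep])^2)) / (2 * pi)
  list(plateau_diff = as.numeric(plateau), rms_fraction = rms)
}
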