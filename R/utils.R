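# Internal helpers: seeded RNG scoping, grid coordinates, windows, FFT
# utilities and sub-pixel peak refinement.

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Centered grid axis: n pixels of pitch px, origin at pixel floor(n/2) + 1.
axisCoords <- function(n, px) {
  (seq_len(n) - 1 - floor(n / 2)) * px
}

# FFT bin frequencies in cycles per pixel (standard wrap-around layout).
fftFreq <- function(n) {
  i <- seq_len(n) - 1
  i[i > n / 2] <- i[i > n / 2] - n
  i / n
}

# 2D Tukey (tapered cosine) window, outer product of 1D windows.
tukeyWindow <- function(ny, nx, alpha = 0.25) {
  tk1 <- function(n) {
    if (alpha <= 0) return(rep(1, n))
    x <- (seq_len(n) - 1) / (n - 1)
    w <- rep(1, n)
    lo <- x < alpha / 2
    hi <- x > 1 - alpha / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * x[hi] / alpha - 2 / alpha + 1)))
    w
  }
  outer(tk1(ny), tk1(nx))
}

# Quadratic (3-point parabola, per axis) sub-pixel refinement of a peak in
# magnitude image `m` at integer indices (iy, ix); wraps around edges.
# Returns fractional index offsets c(dy, dx) each in (-0.5, 0.5).
subpixelPeak <- function(m, iy, ix) {
  ny <- nrow(m); nx <- ncol(m)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  refine1 <- function(ym, y0, yp) {
    den <- ym - 2 * y0 + yp
    if (abs(den) < .Machine$double.eps) return(0)
    d <- 0.5 * (ym - yp) / den
    max(-0.5, min(0.5, d))
  }
  dy <- refine1(m[wrap(iy - 1, ny), ix], m[iy, ix], m[wrap(iy + 1, ny), ix])
  dx <- refine1(m[iy, wrap(ix - 1, nx)], m[iy, ix], m[iy, wrap(ix + 1, nx)])
  c(dy, dx)
}

# Direct DFT of a real/complex matrix at one continuous frequency
# s = c(sy, sx) in cycles/pixel (corner origin, matching fft()).
dftAt <- function(p, s) {
  ny <- nrow(p); nx <- ncol(p)
  ey <- exp(-2i * pi * s[1] * (seq_len(ny) - 1))
  ex <- exp(-2i * pi * s[2] * (seq_len(nx) - 1))
  as.complex(crossprod(ey, p %*% ex))[1]
}

# Wrap angles to (-pi, pi].
wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# Wrap angles to [0, 2*pi).
wrap2Pi <- function(x) x %% (2 * pi)

# Rolling polynomial hash of a serialized R object, as 8 hex digits; used
# to stamp configs into sidecar files without external digest
# dependencies. (Double-precision arithmetic keeps every intermediate
# exact below 2^53.)
configHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 257 + b + 1) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

# Vectorized order-sensitive checksum of a file's bytes (for fixture
# manifests).
fileHash <- function(path) {
  b <- as.integer(readBin(path, "raw", file.size(path)))
  p <- 2147483647
  s1 <- sum(b) %% p
  s2 <- sum(b * ((seq_along(b) %% 9973) + 1)) %% p
  sprintf("%08x%08x", as.integer(s1), as.integer(s2))
}

# Centered -> corner-origin index shift of a centered kernel onto an
# ny x nx canvas (for FFT convolution with DC-centered kernels).
padKernel <- function(kern, ny, nx) {
  ky <- nrow(kern); kx <- ncol(kern)
  if (ky > ny || kx > nx) {
    # crop the (centered) kernel to the target grid
    cy <- floor(ky / 2) + 1; cx <- floor(kx / 2) + 1
    hy <- floor((min(ny, ky) - 1) / 2); hx <- floor((min(nx, kx) - 1) / 2)
    kern <- kern[(cy - hy):(cy + hy), (cx - hx):(cx + hx), drop = FALSE]
    kern <- kern / sum(kern)
    ky <- nrow(kern); kx <- ncol(kern)
  }
  out <- matrix(0, ny, nx)
  cy <- floor(ky / 2); cx <- floor(kx / 2)
  ys <- ((seq_len(ky) - 1 - cy) %% ny) + 1
  xs <- ((seq_len(kx) - 1 - cx) %% nx) + 1
  out[ys, xs] <- kern
  out
}

# Least-squares (Kasa) circle center of complex phasor points. When a
# fringe reference retains residual fringe content, per-frame correlation
# phasors K*exp(i*phi_j) are all offset by the same complex constant; the
# circle center recovers that offset. Returns 0+0i when underdetermined
# (fewer than 3 well-spread points).
phasorCircleCenter <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) < 3) return(0 + 0i)
  x <- Re(z); y <- Im(z)
  if (stats::sd(x) + stats::sd(y) < 1e-9 * max(Mod(z), 1)) return(0 + 0i)
  A <- cbind(2 * x, 2 * y, 1)
  ft <- tryCatch(stats::.lm.fit(A, x^2 + y^2), error = function(e) NULL)
  if (is.null(ft)) return(0 + 0i)
  cf <- ft$coefficients
  if (any(!is.finite(cf))) return(0 + 0i)
  ctr <- complex(real = cf[1], imaginary = cf[2])
  # reject wild extrapolations (nearly collinear points)
  if (Mod(ctr) > 2 * max(Mod(z))) return(0 + 0i)
  ctr
}

# Remove the common complex offset of a set of fringe phasors
# K*exp(i*phi_j) + Z. For a balanced (evenly stepped, full circle) phase
# set the plateau mean equals Z exactly, so 3-point plateaus use the mean;
# larger plateaus (possibly unevenly stepped) use the least-squares circle
# center.
debiasPhasors <- function(vals, plateau) {
  if (sum(plateau) < 3) return(vals)
  z0 <- if (sum(plateau) == 3) mean(vals[plateau])
  else phasorCircleCenter(vals[plateau])
  vals - z0
}

# Radial (ring-median) envelope of a magnitude spectrum in FFT layout;
# used to whiten product spectra before peak finding so a coherent fringe
# peak is not outcompeted by the low-frequency speckle envelope.
ringEnvelope <- function(A) {
  ny <- nrow(A); nx <- ncol(A)
  fr <- sqrt(outer(fftFreq(ny)^2, fftFreq(nx)^2, "+"))
  nb <- max(8L, floor(min(ny, nx) / 2))
  bin <- pmin(nb, 1 + floor(fr / 0.7072 * nb))
  med <- tapply(A, bin, stats::median)
  env <- med[as.character(bin)]
  env <- matrix(as.numeric(env), ny, nx)
  env[env <= 0] <- max(A) * 1e-12 + .Machine$double.xmin
  env
}

# Zero-pad an FFT-layout spectrum onto a larger canvas (Fourier
# upsampling); quadrants preserved.
padSpectrumTo <- function(B, NY, NX) {
  ny <- nrow(B); nx <- ncol(B)
  out <- matrix(0 + 0i, NY, NX)
  hy <- ny %/% 2; hx <- nx %/% 2
  ylo <- seq_len(hy); yhi <- (ny - hy + 1):ny
  xlo <- seq_len(hx); xhi <- (nx - hx + 1):nx
  out[ylo, xlo] <- B[ylo, xlo]
  out[ylo, NX - nx + xhi] <- B[ylo, xhi]
  out[NY - ny + yhi, xlo] <- B[yhi, xlo]
  out[NY - ny + yhi, NX - nx + xhi] <- B[yhi, xhi]
  out
}

# Exact (sinc) upsampling of a band-limited real image by an integer
# factor. Fine sample j of camera pixel i lies at x_i + (j-1)*px/os.
upsampleFourier <- function(m, os) {
  ny <- nrow(m); nx <- ncol(m)
  F2 <- padSpectrumTo(stats::fft(m), ny * os, nx * os)
  Re(stats::fft(F2, inverse = TRUE)) / (ny * nx)
}

# FFT-based circular convolution of image with a centered kernel.
fftConvolve <- function(img, kern) {
  ny <- nrow(img); nx <- ncol(img)
  K <- stats::fft(padKernel(kern, ny, nx))
  Re(stats::fft(stats::fft(img) * K, inverse = TRUE)) / (ny * nx)
}
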