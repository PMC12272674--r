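# Fourier ring correlation resolution estimation.

#' Fourier ring correlation between two images
#'
#' Radially binned normalized cross-correlation of the Fourier transforms
#' of two independent images of the same scene:
#' \eqn{\mathrm{FRC}(r) = \mathrm{Re}\sum_r F_1 F_2^{*} /
#' \sqrt{\sum_r |F_1|^2 \sum_r |F_2|^2}}.
#' The resolution is the inverse of the frequency at which the curve first
#' drops below the threshold (fixed 1/7 by default), linearly interpolated
#' between rings; identical images never cross and report the Nyquist
#' floor of two pixels.
#'
#' @param imageA,imageB numeric matrices (or
#'   \linkS4class{IntensityGrid}s) of equal shape.
#' @param pixel_size pixel pitch, um (taken from a grid when omitted).
#' @param threshold crossing threshold; default the fixed-1/7 criterion.
#' @param window_alpha Tukey taper fraction applied before the transforms.
#' @return An \linkS4class{FrcCurve} (resolution in nm).
#' @examples
#' a <- matrix(rnorm(64^2), 64, 64)
#' frcCurve(a, a, pixel_size = 0.065)   # identical: resolution = 2 px
#' @export
frcCurve <- function(imageA, imageB, pixel_size = NULL, threshold = 1 / 7,
                     window_alpha = 0.25) {
  getm <- function(x) {
    if (is(x, "IntensityGrid")) {
      if (is.null(pixel_size)) pixel_size <<- x@pixel_size
      m <- x@values
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    } else x
  }
  a <- getm(imageA); b <- getm(imageB)
  if (is.null(pixel_size)) stop("pixel_size required")
  if (!all(dim(a) == dim(b))) stop("input error: images differ in shape")
  ny <- nrow(a); nx <- ncol(a)
  w <- tukeyWindow(ny, nx, window_alpha)
  Fa <- stats::fft(w * (a - mean(a)))
  Fb <- stats::fft(w * (b - mean(b)))
  fy <- fftFreq(ny); fx <- fftFreq(nx)
  fr <- sqrt(outer(fy^2, fx^2, "+"))          # cycles/px
  nbin <- floor(min(ny, nx) / 2)
  if (nbin < 3) stop("input error: fewer than 3 radial bins")
  bin <- pmin(nbin, 1 + floor(fr * min(ny, nx)))
  cross <- tapply(Re(Fa * Conj(Fb)), bin, sum)
  pa <- tapply(Mod(Fa)^2, bin, sum)
  pb <- tapply(Mod(Fb)^2, bin, sum)
  frc <- as.numeric(cross / sqrt(pa * pb))
  freq_px <- (as.numeric(names(cross)) - 0.5) / min(ny, nx)
  freq <- freq_px / pixel_size                 # cycles/um
  keep <- seq_len(nbin)
  frc <- frc[keep]; freq <- freq[keep]

  below <- which(frc < threshold)
  below <- below[below > 1]
  if (!length(below)) {
    resolution <- 2 * pixel_size * 1000        # Nyquist floor, nm
  } else {
    i <- below[1]
    f0 <- freq[i - 1]; f1 <- freq[i]
    y0 <- frc[i - 1]; y1 <- frc[i]
    fc <- if (y0 == y1) f1 else f0 + (y0 - threshold) * (f1 - f0) / (y0 - y1)
    resolution <- 1000 / fc
  }
  new("FrcCurve", freq = freq, frc = frc, resolution = resolution,
      threshold = threshold)
}
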