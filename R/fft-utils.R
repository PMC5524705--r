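# Fourier helpers: orthonormal 2-D transforms, sub-pixel shifts, and
# upsampled cross-correlation registration.

# DFT frequency index in cycles/sample
fftFreq <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= (n - 1) %/% 2, k, k - n) / n
}

fft2 <- function(x) stats::fft(x) / sqrt(length(x))
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# Fourier shift of a matrix by (dr, dc) pixels (periodic boundaries).
# Real input returns real output.
fourierShift <- function(x, dr, dc) {
  wasReal <- is.numeric(x)
  xc <- matrix(as.complex(x), nrow(x), ncol(x))
  out <- cpp_fourier_shift(xc, dr, dc)
  if (wasReal) Re(out) else out
}

# Shift with 10% edge-replication padding to suppress periodic wrap-around.
#' Shift an image by a (possibly sub-pixel) displacement
#'
#' Applies a translation by Fourier-domain phase ramps. The image is
#' edge-padded by 10% per side before the periodic shift and cropped back,
#' suppressing wrap-around of content across the borders.
#'
#' @param img numeric or complex matrix.
#' @param dy,dx displacement in pixels along rows / columns (content moves
#'   down / right for positive values).
#' @return matrix of the same dimensions and mode as `img`.
#' @export
applyImageShift <- function(img, dy, dx) {
  if (dy == 0 && dx == 0) return(img)
  pr <- max(2L, ceiling(nrow(img) * 0.1))
  pc <- max(2L, ceiling(ncol(img) * 0.1))
  big <- img[c(rep(1L, pr), seq_len(nrow(img)), rep(nrow(img), pr)),
             c(rep(1L, pc), seq_len(ncol(img)), rep(ncol(img), pc))]
  out <- fourierShift(big, dy, dx)
  out[pr + seq_len(nrow(img)), pc + seq_len(ncol(img))]
}

# 1-D counterpart for profiles
applyProfileShift <- function(p, d) {
  n <- length(p)
  pad <- max(2L, ceiling(n * 0.1))
  big <- c(rep(p[1], pad), p, rep(p[n], pad))
  f <- stats::fft(big)
  ramp <- exp(-2i * pi * fftFreq(length(big)) * d)
  out <- Re(stats::fft(f * ramp, inverse = TRUE)) / length(big)
  out[pad + seq_len(n)]
}

# Local DFT on an upsampled frequency-space patch (matrix-multiply DFT),
# the workhorse of sub-pixel registration.
upsampledXcorr <- function(X, up, nor, noc, roff, coff) {
  nr <- nrow(X); nc <- ncol(X)
  kr <- ifftshiftIdx(nr)  # frequencies in FFT order
  kc <- ifftshiftIdx(nc)
  Wr <- exp(2i * pi / (nr * up) * outer((0:(nor - 1)) - roff, kr))
  Wc <- exp(2i * pi / (nc * up) * outer(kc, (0:(noc - 1)) - coff))
  Wr %*% X %*% Wc
}

ifftshiftIdx <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= (n - 1) %/% 2, k, k - n)
}

#' Register a translation between two images to sub-pixel precision
#'
#' Estimates the displacement of `img` relative to `ref` (such that `img`
#' is approximately `ref` shifted by the returned amount) by
#' cross-correlation: a coarse integer-pixel peak search followed by a
#' refined peak search on a locally upsampled Fourier-domain
#' cross-correlation (matrix-multiply discrete Fourier transform).
#'
#' @param ref,img numeric or complex matrices of identical dimensions.
#' @param upsample upsampling factor; the shift is quantized to
#'   1/`upsample` pixels (default 100, i.e. 0.01 px).
#' @return numeric length-2 vector c(dy, dx) in pixels.
#' @export
registerTranslation <- function(ref, img, upsample = 100) {
  stopifnot(identical(dim(ref), dim(img)))
  Fr <- stats::fft(as.matrix(ref))
  Fi <- stats::fft(as.matrix(img))
  X <- Fi * Conj(Fr)
  cc <- stats::fft(X, inverse = TRUE)
  peak <- which.max(Mod(cc))
  pr <- (peak - 1) %% nrow(cc)
  pc <- (peak - 1) %/% nrow(cc)
  if (pr > nrow(cc) / 2) pr <- pr - nrow(cc)
  if (pc > ncol(cc) / 2) pc <- pc - ncol(cc)
  if (upsample <= 1) return(c(dy = pr, dx = pc))
  # refine on a 1.5-px neighbourhood at 1/upsample resolution
  nloc <- ceiling(1.5 * upsample)
  roff <- nloc / 2 - pr * upsample
  coff <- nloc / 2 - pc * upsample
  ccu <- upsampledXcorr(X, upsample, nloc, nloc, roff, coff)
  pk <- which.max(Mod(ccu))
  ur <- (pk - 1) %% nrow(ccu)
  uc <- (pk - 1) %/% nrow(ccu)
  c(dy = (ur - nloc / 2) / upsample + pr, dx = (uc - nloc / 2) / upsample + pc)
}

# 1-D registration of profiles with parabolic sub-pixel refinement
registerProfile <- function(ref, p) {
  n <- length(ref)
  X <- stats::fft(p) * Conj(stats::fft(ref))
  cc <- Re(stats::fft(X, inverse = TRUE)) / n
  pk <- which.max(cc)
  # parabolic interpolation around the peak (periodic neighbours)
  ym <- cc[(pk - 2) %% n + 1]; y0 <- cc[pk]; yp <- cc[pk %% n + 1]
  denom <- ym - 2 * y0 + yp
  frac <- if (abs(denom) > 1e-12 * max(abs(cc))) 0.5 * (ym - yp) / denom else 0
  frac <- max(-0.5, min(0.5, frac))
  d <- (pk - 1) + frac
  if (d > n / 2) d <- d - n
  d
}
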