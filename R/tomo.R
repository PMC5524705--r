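# Tomographic reconstruction from phase-derivative sinograms: filtered
# back-projection with the derivative-domain filter -(i/2pi) sign(w), and
# calibration of the volume to electron density.

# Core FBP on a derivative sinogram stack [H, W, nAngles].
# Returns a (H, W, W) volume of line-integral density per voxel (the same
# units as the integrated projections, i.e. phase per voxel when the input
# is d(phi)/dx in rad/pixel).
fbpDerivativeCore <- function(derivStack, angles, weights = NULL) {
  d <- dim(derivStack)
  H <- d[1]; W <- d[2]; nA <- d[3]
  stopifnot(length(angles) == nA)
  if (is.null(weights)) weights <- angularWeights(angles)
  if (any(!is.finite(derivStack))) stop("non-finite values in the sinogram")

  # Derivative-domain reconstruction filter on projections zero-padded to
  # 2x width: the ramp |w| divided by the transfer function of the forward
  # difference, H(w) = |w| / (e^{i 2 pi w} - 1) -> -(i/2pi) sign(w) for
  # small w. The ramp is realized from the band-limited spatial kernel
  # (1/4 at 0, -1/(pi^2 n^2) for odd lags), whose small positive DC term
  # removes the cupping bias of a naively sampled |w|.
  Wp <- 4L * W
  m <- ifftshiftIdx(Wp)
  h <- ifelse(m == 0, 0.25, ifelse(m %% 2 != 0, -1 / (pi^2 * m^2), 0))
  ramp <- Re(stats::fft(h))
  f <- fftFreq(Wp)
  dtf <- exp(2i * pi * f) - 1
  filt <- ifelse(abs(dtf) > 1e-12, ramp / dtf, 0)

  # The filtered projections are kept on the full padded grid: the ramp
  # filter's slowly decaying tails beyond the measured width are needed by
  # voxels near the grid boundary for exact cancellation outside the sample.
  filtered <- array(0, c(H, Wp, nA))
  zeroPad <- matrix(0, Wp - W, H)
  for (a in seq_len(nA)) {
    Dp <- rbind(t(derivStack[, , a]), zeroPad)       # W-dim along rows
    Fq <- stats::mvfft(Dp) * filt
    q <- Re(stats::mvfft(Fq, inverse = TRUE)) / Wp
    # DC bin of the ramp-filtered projection, lost in the derivative data:
    # ramp(0) times the total integrated phase of each row
    dc <- ramp[1] * rowSums(integrateDerivative(derivStack[, , a])) / Wp
    filtered[, , a] <- t(q) + dc
  }

  # back-project: out(y, x, z) = (pi/nA) sum_a w_a q_a(y, x cos + z sin),
  # sampling the padded filtered projection periodically
  ctr <- (W + 1) / 2
  xc <- seq_len(W) - ctr
  out <- matrix(0, H, W * W)
  for (a in seq_len(nA)) {
    th <- angles[a] * pi / 180
    tg <- ctr + outer(xc * cos(th), xc * sin(th), "+")   # (x, z) sample positions
    i0 <- floor(tg)
    fr <- tg - i0
    c0 <- ((i0 - 1L) %% Wp) + 1L
    c1 <- (i0 %% Wp) + 1L
    Q <- filtered[, , a]
    out <- out + weights[a] *
      (Q[, c0, drop = FALSE] * rep(1 - fr, each = H) +
       Q[, c1, drop = FALSE] * rep(fr, each = H))
  }
  array(out * pi / nA, c(H, W, W))
}

#' Filtered back-projection of a phase-derivative sinogram
#'
#' Reconstructs the 3-D refractive-index decrement from aligned horizontal
#' phase derivatives. Each projection row is filtered in the Fourier
#' domain with H(w) = -(i/2pi) sign(w) -- the ramp filter |w| divided by
#' the transfer function i 2 pi w of the derivative -- on a grid
#' zero-padded to twice the width, then back-projected with per-angle
#' weights and pi/nAngles scaling, slice by slice along the rotation axis
#' (exact under the parallel-beam assumption). The phase-per-voxel volume
#' v is converted to the decrement via delta = -v * lambda / (2 pi *
#' voxelSize): reconstructed phase is negative in matter under the
#' package's sign convention, so delta is positive.
#'
#' @param sinogram an [AlignedSinogram-class], or an H-by-W-by-nAngles
#'   array of d(phi)/dx in rad/pixel.
#' @param angles angles in degrees (taken from the sinogram if omitted).
#' @param weights per-angle weights (defaults to [angularWeights()]).
#' @param pixelSizeNm pixel size in nanometres (taken from the sinogram if
#'   omitted).
#' @param wavelengthM X-ray wavelength in metres.
#' @return a [Tomogram-class] with a (H, W, W) delta volume.
#' @seealso [electronDensity()], [splitHalfTomograms()]
#' @export
derivativeFBP <- function(sinogram, angles = NULL, weights = NULL,
                          pixelSizeNm = NULL, wavelengthM) {
  if (is(sinogram, "AlignedSinogram")) {
    if (is.null(angles)) angles <- sinogram@angles
    if (is.null(weights)) weights <- sinogram@weights
    if (is.null(pixelSizeNm)) pixelSizeNm <- sinogram@pixelSizeNm
    stack <- sinogram@derivative
  } else stack <- sinogram
  stopifnot(!is.null(angles), !is.null(pixelSizeNm), wavelengthM > 0)
  gaps <- diff(c(angles, angles[1] + 180))
  if (max(gaps) > 10)
    warning("angular gap exceeds 10 degrees; expect limited-angle artifacts")
  vol <- fbpDerivativeCore(stack, angles, weights)
  if (any(!is.finite(vol))) stop("non-finite filter output")
  delta <- -vol * wavelengthM / (2 * pi * pixelSizeNm * 1e-9)
  new("Tomogram", delta = delta, voxelSizeNm = pixelSizeNm,
      wavelengthM = wavelengthM,
      provenance = list(angles = angles, weights = weights))
}

#' Electron density from the refractive-index decrement
#'
#' n_e = 2 pi delta / (r_e lambda^2), the exact inverse of
#' [deltaBetaFromElectronDensity()]; returned in electrons/Angstrom^3.
#'
#' @param delta numeric array of the refractive index decrement.
#' @param wavelengthM X-ray wavelength in metres.
#' @return numeric array, electrons/Angstrom^3.
#' @export
electronDensityFromDelta <- function(delta, wavelengthM) {
  stopifnot(wavelengthM > 0)
  delta * 2 * pi / (.const$electronRadiusM * wavelengthM^2) / 1e30
}

#' Independent half-tomograms for resolution estimation
#'
#' Partitions the retained angles into even- and odd-indexed subsets,
#' recomputes angular weights for each, and reconstructs two tomograms on
#' the same grid and calibration. Fourier shell correlation of the two
#' halves measures the reproducible resolution.
#'
#' @param sinogram an [AlignedSinogram-class] or derivative array.
#' @inheritParams derivativeFBP
#' @return list with elements `even` and `odd`, both [Tomogram-class].
#' @export
splitHalfTomograms <- function(sinogram, angles = NULL, pixelSizeNm = NULL,
                               wavelengthM) {
  if (is(sinogram, "AlignedSinogram")) {
    if (is.null(angles)) angles <- sinogram@angles
    if (is.null(pixelSizeNm)) pixelSizeNm <- sinogram@pixelSizeNm
    stack <- sinogram@derivative
  } else stack <- sinogram
  nA <- dim(stack)[3]
  if (nA < 8) stop("need at least 8 angles to split")
  iEven <- seq(1, nA, by = 2)
  iOdd <- seq(2, nA, by = 2)
  if (length(iEven) < 4 || length(iOdd) < 4)
    stop("fewer than 4 angles per half")
  mk <- function(idx) derivativeFBP(stack[, , idx, drop = FALSE],
                                    angles = angles[idx],
                                    weights = angularWeights(angles[idx]),
                                    pixelSizeNm = pixelSizeNm,
                                    wavelengthM = wavelengthM)
  list(even = mk(iEven), odd = mk(iOdd))
}
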