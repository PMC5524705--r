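# Forward measurement model: scan trajectory, illumination, far-field
# diffraction with optional Poisson counting noise.

#' Fermat-spiral scan trajectory
#'
#' Point k (k = 0, 1, 2, ...) lies at radius c*sqrt(k) and azimuth
#' k * 137.508 degrees (the golden angle), with c = step/sqrt(pi) so that
#' the mean area per point equals step^2. Points are generated over the
#' circle circumscribing the field of view and clipped to it. The spiral
#' gives near-uniform point density without the periodic artifacts of
#' raster scanning.
#'
#' @param fieldOfViewM length-2 numeric (width, height) of the scanned
#'   field, metres.
#' @param stepM nominal step size, metres; must not exceed the smaller
#'   field-of-view side.
#' @return a [ScanPattern-class]; positions are ordered by generation index
#'   and the first point is the origin.
#' @examples
#' fermatSpiral(c(20e-6, 20e-6), 2.2e-6)  # ~82 positions
#' @export
fermatSpiral <- function(fieldOfViewM, stepM) {
  stopifnot(length(fieldOfViewM) == 2, all(fieldOfViewM > 0), stepM > 0)
  if (stepM > min(fieldOfViewM))
    stop("step exceeds the field of view; no overlap is possible")
  cc <- stepM / sqrt(pi)
  golden <- 137.508 * pi / 180
  rmax <- sqrt(sum((fieldOfViewM / 2)^2))
  kmax <- ceiling((rmax / cc)^2)
  k <- 0:kmax
  r <- cc * sqrt(k)
  a <- k * golden
  x <- r * cos(a); y <- r * sin(a)
  keep <- abs(x) <= fieldOfViewM[1] / 2 & abs(y) <= fieldOfViewM[2] / 2
  new("ScanPattern", positions = cbind(x = x[keep], y = y[keep]),
      nominalStepM = stepM, fieldOfViewM = as.numeric(fieldOfViewM))
}

#' Model illumination: tapered disc with defocus phase
#'
#' A circular top-hat of the configured probe diameter with a raised-cosine
#' edge taper (taper width 10% of the diameter) and a quadratic defocus
#' phase, normalized so that sum(|field|^2) equals the photon budget per
#' exposure. Only the probe extent and overlap matter for pipeline
#' verification; reconstruction retrieves the actual probe jointly with the
#' object.
#'
#' @param optics an [OpticsConfig-class]; the grid is
#'   detectorRegionPx^2 at the reconstruction pixel size.
#' @param totalPhotons photons per exposure (default 1).
#' @param defocusRad quadratic phase in radians at the nominal probe edge;
#'   0 gives a purely real, nonnegative field.
#' @return a [Probe-class].
#' @export
makeProbe <- function(optics, totalPhotons = 1, defocusRad = 2) {
  stopifnot(is(optics, "OpticsConfig"), totalPhotons > 0)
  N <- optics@detectorRegionPx
  p <- pixelSizeM(optics)
  dia <- optics@probeDiameterM
  if (dia < 4 * p) stop("probe diameter must span at least 4 pixels")
  if (dia > N * p) stop("probe diameter exceeds the reconstruction grid")
  ctr <- N / 2 + 1
  r <- sqrt(outer((seq_len(N) - ctr)^2, (seq_len(N) - ctr)^2, "+")) * p
  tw <- 0.1 * dia
  r0 <- dia / 2 - tw
  amp <- ifelse(r <= r0, 1,
                ifelse(r <= dia / 2, 0.5 * (1 + cos(pi * (r - r0) / tw)), 0))
  phase <- defocusRad * (r / (dia / 2))^2
  field <- amp * exp(1i * phase)
  field <- field * sqrt(totalPhotons / sum(Mod(field)^2))
  new("Probe", field = field, totalPhotons = totalPhotons,
      pixelSizeNm = p * 1e9)
}

# Map scan positions (metres) to probe windows on an object grid.
# Returns 1-based top-left (row, col) and sub-pixel (row, col) remainders.
scanWindows <- function(scan, pixelSizeNm, objectDim, probePx,
                        snapToGrid = FALSE) {
  pM <- pixelSizeNm * 1e-9
  rowC <- (objectDim[1] + 1) / 2 + scan@positions[, 2] / pM
  colC <- (objectDim[2] + 1) / 2 + scan@positions[, 1] / pM
  if (snapToGrid) { rowC <- round(rowC); colC <- round(colC) }
  r0 <- round(rowC) - probePx %/% 2
  c0 <- round(colC) - probePx %/% 2
  frac <- cbind(rowC - round(rowC), colC - round(colC))
  if (any(r0 < 1) || any(c0 < 1) || any(r0 + probePx - 1 > objectDim[1]) ||
      any(c0 + probePx - 1 > objectDim[2]))
    stop("a scan position's probe window leaves the object grid")
  list(winTopLeft = cbind(r0, c0), frac = frac)
}

#' Simulate far-field diffraction frames for one angle
#'
#' For each scan position r_j the exit wave is the product of the
#' (sub-pixel shifted) probe and the object transmission over the probe
#' window, psi_j(r) = P(r - r_j) O(r); the detector intensity is
#' I_j(q) = |F(psi_j)|^2 with an orthonormal DFT, so total counts never
#' exceed the photon budget (equality when |O| = 1 on the probe support).
#' With `noise = TRUE` each pixel is replaced by a Poisson draw, seeded
#' deterministically.
#'
#' @param projection a [ComplexProjection-class] (the object transmission;
#'   use [embedProjection()] to pad it onto a larger object grid), or a
#'   complex matrix.
#' @param probe a [Probe-class].
#' @param scan a [ScanPattern-class]; positions are relative to the centre
#'   of the object grid.
#' @param noise logical: apply Poisson counting noise.
#' @param seed integer seed for the noise stream.
#' @param snapToGrid snap scan positions to the pixel grid (avoids
#'   sub-pixel probe shifts in both simulation and reconstruction).
#' @return a [DiffractionData-class].
#' @export
simulateDiffraction <- function(projection, probe, scan, noise = FALSE,
                                seed = 1L, snapToGrid = FALSE) {
  stopifnot(is(probe, "Probe"), is(scan, "ScanPattern"))
  if (is(projection, "ComplexProjection")) {
    obj <- projection@transmission
    angle <- projection@angleDeg
    pixelSizeNm <- projection@pixelSizeNm
  } else {
    obj <- projection
    angle <- 0
    pixelSizeNm <- probe@pixelSizeNm
  }
  N <- nrow(probe@field)
  od <- dim(obj)
  w <- scanWindows(scan, pixelSizeNm, od, N, snapToGrid)
  J <- nrow(w$winTopLeft)
  psi <- array(0i, c(N, N, J))
  for (j in seq_len(J)) {
    pj <- if (any(abs(w$frac[j, ]) > 1e-12))
      cpp_fourier_shift(probe@field, w$frac[j, 1], w$frac[j, 2])
    else probe@field
    r0 <- w$winTopLeft[j, 1]; c0 <- w$winTopLeft[j, 2]
    psi[, , j] <- pj * obj[r0:(r0 + N - 1), c0:(c0 + N - 1)]
  }
  frames <- Mod(cpp_fft2_stack(psi, FALSE, TRUE))^2
  if (noise) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    frames <- array(stats::rpois(length(frames), frames), dim(frames))
  }
  new("DiffractionData", frames = frames, scan = scan, angleDeg = angle,
      pixelSizeNm = pixelSizeNm, objectDim = as.integer(od),
      winTopLeft = w$winTopLeft, frac = w$frac, noisy = noise,
      seed = as.integer(seed))
}

#' Embed a projection in a larger object grid
#'
#' Pads a complex projection with unit transmission (air) to the requested
#' grid, centring the original. The reconstruction object grid must contain
#' every probe window; padding provides the margin.
#'
#' @param projection a [ComplexProjection-class].
#' @param objectDim integer length-2 (rows, cols) of the target grid.
#' @return a [ComplexProjection-class] on the larger grid.
#' @export
embedProjection <- function(projection, objectDim) {
  stopifnot(is(projection, "ComplexProjection"))
  tr <- projection@transmission
  d <- dim(tr)
  if (any(objectDim < d)) stop("object grid smaller than the projection")
  out <- matrix(1 + 0i, objectDim[1], objectDim[2])
  r0 <- (objectDim[1] - d[1]) %/% 2
  c0 <- (objectDim[2] - d[2]) %/% 2
  out[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- tr
  new("ComplexProjection", transmission = out,
      angleDeg = projection@angleDeg, pixelSizeNm = projection@pixelSizeNm)
}
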