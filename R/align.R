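# Projection processing and sinogram alignment: ramp removal, wrap-safe
# phase derivative, vertical mass-profile alignment, centre-of-mass
# prealignment, tomographic-consistency horizontal alignment, automatic
# rejection of amplitude-corrupted projections, and angular weighting.

#' Remove a phase offset and linear ramp using the air region
#'
#' Fits a least-squares plane (offset plus two linear terms) to the image
#' over the air mask and subtracts it everywhere, so the air-region mean is
#' zero afterwards. The sample is surrounded by air on all sides of the
#' rotation axis, which anchors the absolute phase of every projection.
#' The operation is idempotent.
#'
#' @param phase numeric matrix (phase in radians, or a phase-derivative
#'   image -- any quantity expected to vanish in air).
#' @param airMask logical matrix of the same size; should be nonempty on
#'   both lateral sides of the sample.
#' @return numeric matrix with the fitted plane removed.
#' @export
removeRamp <- function(phase, airMask) {
  stopifnot(identical(dim(phase), dim(airMask)), any(airMask))
  cols <- which(colSums(airMask) > 0)
  if (min(cols) > 1 + ncol(phase) * 0.25 || max(cols) < ncol(phase) * 0.75)
    warning("air mask does not reach both lateral sides; ramp fit may be poor")
  rows <- matrix(seq_len(nrow(phase)), nrow(phase), ncol(phase))
  colsM <- matrix(seq_len(ncol(phase)), nrow(phase), ncol(phase), byrow = TRUE)
  X <- cbind(1, rows[airMask], colsM[airMask])
  beta <- stats::lm.fit(X, phase[airMask])$coefficients
  beta[is.na(beta)] <- 0
  phase - (beta[1] + beta[2] * rows + beta[3] * colsM)
}

#' Wrap-safe horizontal phase derivative of a complex projection
#'
#' d(x, y) = Arg( T(x+1, y) * Conj(T(x, y)) ): the finite difference of the
#' phase computed in the complex domain, immune to 2*pi wrapping as long as
#' the true phase changes by less than pi radians between neighbouring
#' pixels (steps of exactly 2*pi are invisible by construction). The last
#' column is zero-padded.
#'
#' @param projection a [ComplexProjection-class] or complex matrix.
#' @return numeric matrix of d(phi)/dx in rad/pixel, same dimensions.
#' @export
phaseDerivative <- function(projection) {
  tr <- if (is(projection, "ComplexProjection")) projection@transmission
        else projection
  d <- Arg(tr[, -1, drop = FALSE] * Conj(tr[, -ncol(tr), drop = FALSE]))
  cbind(d, 0)
}

# integrate a derivative image back to phase (cumulative sum along x)
integrateDerivative <- function(d) {
  t(apply(d, 1, cumsum))
}

#' Vertical alignment of a derivative sinogram
#'
#' The vertically integrated projected mass of each horizontal slice is
#' invariant under rotation, so the per-row mass profiles
#' m_theta(y) = sum_x phi_theta(x, y) (phi integrated from the derivative)
#' must agree across angles up to a vertical shift. Shifts are estimated
#' iteratively against the running mean profile by sub-pixel
#' cross-correlation and applied by Fourier shifting; the gauge is fixed by
#' constraining the mean shift to zero.
#'
#' @param derivStack H-by-W-by-nAngles array of phase derivatives.
#' @param maxIter maximum refinement passes.
#' @param tolPx convergence threshold on the largest shift update, pixels.
#' @param airCols optional logical vector over columns marking air; when
#'   given, each row's integrated phase is re-anchored to its own air
#'   baseline before summation, suppressing the random-walk noise that
#'   integration of a noisy derivative accumulates along x.
#' @param maxShiftPx per-iteration shift updates are clamped to this
#'   magnitude (default a quarter of the projection height).
#' @return list with `shifts` (per-angle dy, pixels; positive means the
#'   projection is displaced downwards), `converged`, and `iterations`.
#' @export
verticalAlign <- function(derivStack, maxIter = 12L, tolPx = 0.01,
                          airCols = NULL, maxShiftPx = NULL) {
  nA <- dim(derivStack)[3]
  if (nA < 3) stop("vertical alignment needs at least 3 angles")
  if (is.null(maxShiftPx)) maxShiftPx <- dim(derivStack)[1] / 4
  profileOf <- function(a) {
    phi <- integrateDerivative(derivStack[, , a])
    if (is.null(airCols)) return(rowSums(phi))
    base <- rowMeans(phi[, airCols, drop = FALSE])
    rowSums(phi[, !airCols, drop = FALSE] - base)
  }
  m <- vapply(seq_len(nA), profileOf, numeric(dim(derivStack)[1]))
  s <- numeric(nA)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    aligned <- vapply(seq_len(nA),
                      function(a) applyProfileShift(m[, a], -s[a]),
                      numeric(nrow(m)))
    ref <- rowMeans(aligned)
    upd <- vapply(seq_len(nA),
                  function(a) registerProfile(ref, aligned[, a]),
                  numeric(1))
    upd <- pmax(pmin(upd, maxShiftPx), -maxShiftPx)
    s <- s + upd
    s <- s - mean(s)
    if (max(abs(upd)) < tolPx) { converged <- TRUE; break }
  }
  list(shifts = s, converged = converged, iterations = it)
}

#' Centre-of-mass horizontal prealignment
#'
#' The horizontal centre of mass of the projected sample follows
#' A*cos(theta + phi0) + c as the sample rotates. Per-angle centres of mass
#' of the integrated phase are fitted to that sinusoid by least squares;
#' the residuals are the horizontal misalignments. Used to initialize the
#' tomographic-consistency refinement.
#'
#' @param derivStack H-by-W-by-nAngles array of phase derivatives.
#' @param angles angles in degrees.
#' @return list with `shifts` (per-angle dx residuals, pixels),
#'   `amplitude` (fitted |A| in pixels: the sample-centre offset from the
#'   rotation axis), `center` (fitted c), and `fitted` values.
#' @export
comPrealign <- function(derivStack, angles) {
  nA <- dim(derivStack)[3]
  if (nA < 3) stop("centre-of-mass prealignment needs at least 3 angles")
  stopifnot(length(angles) == nA)
  com <- vapply(seq_len(nA), function(a) {
    phi <- integrateDerivative(derivStack[, , a])
    w <- pmax(-colSums(phi), 0)   # projected mass per column (phase < 0 in matter)
    if (sum(w) <= 0) return(NA_real_)
    sum(seq_along(w) * w) / sum(w)
  }, numeric(1))
  ok <- is.finite(com)
  th <- angles[ok] * pi / 180
  fit <- stats::lm.fit(cbind(1, cos(th), sin(th)), com[ok])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  fitted <- rep(NA_real_, nA)
  fitted[ok] <- beta[1] + beta[2] * cos(th) + beta[3] * sin(th)
  shifts <- ifelse(ok, com - fitted, 0)
  list(shifts = as.numeric(shifts),
       amplitude = sqrt(beta[2]^2 + beta[3]^2),
       center = beta[1], fitted = fitted)
}

#' Horizontal alignment by tomographic consistency
#'
#' Iterates: reconstruct a central slab from the currently corrected
#' sinogram (derivative-domain filtered back-projection), reproject it at
#' all angles, register each measured projection to its reprojection by
#' upsampled sub-pixel cross-correlation (default quantization 0.01 px),
#' and update the per-angle horizontal shifts (zero-mean gauge). Stops when
#' the largest update falls below `tolPx` or after `nOuter` passes;
#' divergence (residual growing three consecutive passes) returns the best
#' state with a flag.
#'
#' @param derivStack H-by-W-by-nAngles array of phase derivatives
#'   (vertically aligned).
#' @param angles angles in degrees.
#' @param shiftsInit initial dx estimates (e.g. from [comPrealign()]).
#' @param weights per-angle weights for the slab reconstruction.
#' @param slabRows integer rows used for the consistency slab; default a
#'   central band of up to 16 rows.
#' @param nOuter maximum outer iterations.
#' @param tolPx stopping threshold on the largest shift update.
#' @param upsample registration upsampling factor.
#' @return list with `shifts` (per-angle dx, pixels), `converged`, `flag`
#'   (0 ok, 1 divergence), and `residualHistory` (largest update per pass).
#' @export
consistencyAlign <- function(derivStack, angles, shiftsInit = NULL,
                             weights = NULL, slabRows = NULL, nOuter = 10L,
                             tolPx = 0.05, upsample = 100) {
  d <- dim(derivStack)
  nA <- d[3]
  stopifnot(length(angles) == nA)
  if (is.null(shiftsInit)) shiftsInit <- numeric(nA)
  if (is.null(weights)) weights <- angularWeights(angles)
  if (is.null(slabRows)) {
    half <- min(8L, d[1] %/% 2)
    slabRows <- (d[1] %/% 2 - half + 1L):(d[1] %/% 2 + half)
  }
  s <- shiftsInit
  best <- s
  bestRes <- Inf
  resHist <- numeric(0)
  growing <- 0L
  converged <- FALSE
  flag <- 0L
  for (outer in seq_len(nOuter)) {
    slab <- array(0, c(length(slabRows), d[2], nA))
    for (a in seq_len(nA))
      slab[, , a] <- applyImageShift(derivStack[slabRows, , a], 0, -s[a])
    vol <- fbpDerivativeCore(slab, angles, weights)
    upd <- numeric(nA)
    for (a in seq_len(nA)) {
      reproj <- projectVolumeY(vol, angles[a])
      dre <- cbind(reproj[, -1, drop = FALSE] - reproj[, -ncol(reproj), drop = FALSE], 0)
      upd[a] <- registerTranslation(dre, slab[, , a], upsample)[2]
    }
    upd <- upd - mean(upd)
    s <- s + upd
    res <- max(abs(upd))
    resHist <- c(resHist, res)
    if (res < bestRes) { bestRes <- res; best <- s; growing <- 0L }
    else growing <- growing + 1L
    if (res < tolPx) { converged <- TRUE; break }
    if (growing >= 3L) { flag <- 1L; s <- best; break }
  }
  list(shifts = s, converged = converged, flag = flag,
       residualHistory = resHist)
}

# 5x5 boxcar local mean via integral image
boxMean <- function(img, half = 2L) {
  n <- 2L * half + 1L
  pad <- img[c(rep(1, half), seq_len(nrow(img)), rep(nrow(img), half)),
             c(rep(1, half), seq_len(ncol(img)), rep(ncol(img), half))]
  S <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, t(S)))
  r <- seq_len(nrow(img)); cc <- seq_len(ncol(img))
  (S[r + n, cc + n] - S[r, cc + n] - S[r + n, cc] + S[r, cc]) / n^2
}

#' Flag projections with localized transmissivity loss
#'
#' Grazing-incidence reflection from the sample edge can cause a localized
#' apparent loss of transmissivity amplitude at some angles; such
#' projections produce streaking artifacts and are removed. For each angle
#' the minimum 5x5-boxcar local mean amplitude inside the support is
#' computed; angles whose statistic falls more than `k` scaled median
#' absolute deviations below the across-angle median are flagged.
#'
#' @param amplitudes H-by-W-by-nAngles array of amplitude images |T|, or a
#'   list of [ComplexProjection-class] objects.
#' @param support logical H-by-W mask of the sample region (eroded
#'   internally to avoid edge effects); default the central half of the
#'   image.
#' @param k MAD multiplier (default 5).
#' @return integer vector of flagged angle indices (possibly empty).
#' @export
flagBadProjections <- function(amplitudes, support = NULL, k = 5) {
  if (is.list(amplitudes)) {
    amplitudes <- vapply(amplitudes, amplitudeImage,
                         matrix(0, nrow(amplitudes[[1]]@transmission),
                                ncol(amplitudes[[1]]@transmission)))
  }
  d <- dim(amplitudes)
  if (is.null(support)) {
    support <- matrix(FALSE, d[1], d[2])
    support[(d[1] %/% 4):(3 * d[1] %/% 4), (d[2] %/% 4):(3 * d[2] %/% 4)] <- TRUE
  }
  # erode the support so the boxcar window stays inside it
  er <- support
  for (i in 1:4) {
    er <- er & rbind(FALSE, er[-nrow(er), ]) & rbind(er[-1, ], FALSE) &
      cbind(FALSE, er[, -ncol(er)]) & cbind(er[, -1], FALSE)
  }
  if (!any(er)) er <- support
  stat <- vapply(seq_len(d[3]),
                 function(a) min(boxMean(amplitudes[, , a])[er]),
                 numeric(1))
  thr <- stats::median(stat) - k * stats::mad(stat)
  which(stat < thr)
}

#' Angular weights for an uneven tomographic angle distribution
#'
#' After removing problematic projections the angles are no longer evenly
#' spaced; each retained projection is weighted by the angular gap it
#' covers, w_i proportional to (theta_(i+1) - theta_(i-1))/2 with periodic
#' closure over 180 degrees, normalized so the weights sum to the number of
#' angles. Equally spaced angles give unit weights.
#'
#' @param angles strictly increasing angles in degrees, in [0, 180).
#' @return numeric vector of positive weights summing to `length(angles)`.
#' @export
angularWeights <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least 2 angles")
  if (anyDuplicated(angles)) stop("duplicate angles")
  if (is.unsorted(angles, strictly = TRUE)) stop("angles must be strictly increasing")
  if (any(angles < 0) || any(angles >= 180)) stop("angles must lie in [0, 180)")
  nxt <- c(angles[-1], angles[1] + 180)
  prv <- c(angles[n] - 180, angles[-n])
  g <- (nxt - prv) / 2
  g * n / 180
}
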