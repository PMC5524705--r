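# Ptychographic phase retrieval: difference-map iterations and
# maximum-likelihood refinement (compiled engines), plus the convergence
# metric and the ambiguity-removal comparison utility.

#' Difference-map ptychographic reconstruction
#'
#' Reconstructs complex object transmission and complex probe from one
#' angle's diffraction frames. The algorithm maintains one exit-wave
#' estimate psi_j per scan position and iterates
#' psi <- psi + P_F(2 P_O(psi) - psi) - P_O(psi),
#' where P_O is the overlap projection (object update
#' O(r) = sum_j P*(r - r_j) psi_j(r) / max(sum_j |P(r - r_j)|^2, eps), probe
#' update symmetric, both recomputed every iteration) and P_F replaces each
#' Fourier amplitude with the measured sqrt(I_j) while preserving phase
#' (pixels whose estimated amplitude is zero keep their value). The probe
#' update is frozen for the first `probeFreeze` iterations to stabilize
#' early convergence. The relaxation is the classic beta = 1 difference
#' map. The per-iteration Fourier error is recorded.
#'
#' @param data a [DiffractionData-class] for one angle.
#' @param nIter number of difference-map iterations (>= 1).
#' @param objectInit complex matrix initial object; default unit
#'   transmission on the object grid.
#' @param probeInit a [Probe-class] or complex matrix initial probe;
#'   typically [makeProbe()] output.
#' @param probeFreeze number of initial iterations with the probe held
#'   fixed (default 10).
#' @param updateProbe logical; set FALSE to keep the probe fixed
#'   throughout.
#' @param epsRel relative regularization of the overlap denominators
#'   (floor at epsRel * max, default 1e-8).
#' @return a [PtychoResult-class].
#' @seealso [mlRefine()], [fourierError()]
#' @export
dmReconstruct <- function(data, nIter, objectInit = NULL, probeInit,
                          probeFreeze = 10L, updateProbe = TRUE,
                          epsRel = 1e-8) {
  stopifnot(is(data, "DiffractionData"), nIter >= 1)
  if (is(probeInit, "Probe")) probeInit <- probeInit@field
  od <- data@objectDim
  if (is.null(objectInit)) objectInit <- matrix(1 + 0i, od[1], od[2])
  stopifnot(identical(dim(objectInit), as.integer(od)))
  res <- cpp_dm_engine(data@frames, objectInit, probeInit,
                       data@winTopLeft - 1L, data@frac, as.integer(nIter),
                       as.integer(probeFreeze), isTRUE(updateProbe), epsRel)
  new("PtychoResult", object = res$object, probe = res$probe,
      errorHistory = as.numeric(res$error), likelihoodHistory = numeric(),
      iterationsRun = c(dm = as.integer(nIter), ml = 0L), mlFlag = 0L)
}

#' Maximum-likelihood refinement of a ptychographic reconstruction
#'
#' Polishes a difference-map solution by minimizing the Poisson negative
#' log-likelihood
#' L = sum_jq \[ |Psi_j(q)|^2 - I_j(q) log(|Psi_j(q)|^2 + eps) \],
#' Psi_j = F(P(. - r_j) O(.)), by preconditioned nonlinear conjugate
#' gradient (Polak-Ribiere) with analytic Wirtinger gradients with respect
#' to object and probe and a parabolic line search. L is non-increasing
#' across accepted steps; if the line search fails after bounded
#' backtracking the current state is returned with `mlFlag = 1` rather
#' than an error.
#'
#' @param result a [PtychoResult-class] (or any object/probe pair via
#'   `objectInit`/`probeInit` of [dmReconstruct()]).
#' @param data the [DiffractionData-class] the result was obtained from.
#' @param nIter maximum conjugate-gradient iterations.
#' @param updateProbe logical; refine the probe jointly with the object.
#' @param epsRel likelihood regularizer as a fraction of max(I)
#'   (default 1e-8).
#' @param gradTol relative gradient norm below which the state is declared
#'   stationary and returned unchanged.
#' @return a [PtychoResult-class] with `likelihoodHistory` appended.
#' @export
mlRefine <- function(result, data, nIter, updateProbe = TRUE,
                     epsRel = 1e-8, gradTol = 1e-10) {
  stopifnot(is(result, "PtychoResult"), is(data, "DiffractionData"))
  res <- cpp_ml_engine(data@frames, result@object, result@probe,
                       data@winTopLeft - 1L, data@frac, as.integer(nIter),
                       isTRUE(updateProbe), epsRel, gradTol)
  new("PtychoResult", object = res$object, probe = res$probe,
      errorHistory = result@errorHistory,
      likelihoodHistory = as.numeric(res$likelihood),
      iterationsRun = c(dm = result@iterationsRun[["dm"]],
                        ml = as.integer(res$iterations)),
      mlFlag = as.integer(res$flag))
}

#' Fourier error of an object/probe pair against measured frames
#'
#' sqrt( sum_jq (|Psi_j(q)| - sqrt(I_j(q)))^2 / sum_jq I_j(q) ), the
#' standard amplitude-domain convergence diagnostic. Zero for data exactly
#' reproduced; one for a zero object.
#'
#' @param object complex object transmission on the data's object grid.
#' @param probe complex probe matrix (or [Probe-class]).
#' @param data a [DiffractionData-class].
#' @return nonnegative scalar.
#' @export
fourierError <- function(object, probe, data) {
  stopifnot(is(data, "DiffractionData"))
  if (is(probe, "Probe")) probe <- probe@field
  N <- nrow(probe)
  J <- dim(data@frames)[3]
  psi <- array(0i, c(N, N, J))
  for (j in seq_len(J)) {
    pj <- if (any(abs(data@frac[j, ]) > 1e-12))
      cpp_fourier_shift(probe, data@frac[j, 1], data@frac[j, 2])
    else probe
    r0 <- data@winTopLeft[j, 1]; c0 <- data@winTopLeft[j, 2]
    psi[, , j] <- pj * object[r0:(r0 + N - 1), c0:(c0 + N - 1)]
  }
  amp <- Mod(cpp_fft2_stack(psi, FALSE, TRUE))
  sqrt(sum((amp - sqrt(data@frames))^2) / sum(data@frames))
}

#' Remove the inherent phase ambiguities before comparing reconstructions
#'
#' A ptychographic reconstruction is determined only up to a global phase
#' offset and a linear phase ramp (a lateral shift of the diffraction
#' pattern). This utility estimates both on a region of interest --
#' wrap-safely, from the phase of `rec * Conj(ref)` -- and returns the
#' corrected complex image. Comparisons of reconstructed phase against
#' ground truth are meaningful only after this correction.
#'
#' @param rec complex matrix: reconstruction.
#' @param ref complex matrix: reference (ground truth).
#' @param mask logical matrix: region over which to estimate (e.g. the
#'   probe-covered region); default all pixels.
#' @return complex matrix: `rec` with the offset and ramp removed.
#' @export
removePhaseAmbiguity <- function(rec, ref, mask = NULL) {
  stopifnot(identical(dim(rec), dim(ref)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rec), ncol(rec))
  d <- rec * Conj(ref)
  # ramp from wrapped phase increments inside the mask
  rampOf <- function(w, m) {
    num <- sum(w[m]); if (Mod(num) == 0) 0 else Arg(num)
  }
  mr <- mask[-1, ] & mask[-nrow(mask), ]
  mc <- mask[, -1] & mask[, -ncol(mask)]
  gr <- rampOf(d[-1, ] * Conj(d[-nrow(d), ]), mr)
  gc <- rampOf(d[, -1] * Conj(d[, -ncol(d)]), mc)
  rows <- matrix(seq_len(nrow(rec)), nrow(rec), ncol(rec))
  cols <- matrix(seq_len(ncol(rec)), nrow(rec), ncol(rec), byrow = TRUE)
  ramp <- exp(-1i * (gr * rows + gc * cols))
  d2 <- d * ramp
  off <- Arg(sum(d2[mask]))
  rec * ramp * exp(-1i * off)
}
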