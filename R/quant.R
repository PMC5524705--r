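# Quantitative analysis: Fourier shell correlation with the half-bit
# criterion, surface dose estimation, density-band segmentation with
# connected components, per-class feature-size statistics, and the
# depth-of-field advisory.

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Fourier shell correlation of two volumes
#'
#' FSC(k) = |sum_shell F1 F2*| / sqrt(sum_shell |F1|^2 * sum_shell |F2|^2)
#' over shells of constant spatial frequency, after both volumes are
#' apodized by a shared separable Hann window (suppressing spurious
#' correlation from the box boundary). The per-shell half-bit information
#' threshold is
#' T(k) = (0.2071 + 1.9102/sqrt(n)) / (1.2071 + 0.9102/sqrt(n)) with n the
#' voxel count of the shell; the resolution is the inverse frequency of
#' the first downward crossing, linearly interpolated. If the curve never
#' crosses, the resolution is reported as NA (beyond Nyquist).
#'
#' @param vol1,vol2 numeric 3-D arrays on identical grids (e.g. two
#'   half-tomograms from [splitHalfTomograms()], or their delta slots).
#' @param voxelSizeNm voxel size in nanometres (taken from `vol1` when it
#'   is a [Tomogram-class]).
#' @param window "hann" (default) or "none".
#' @return an [FSCResult-class].
#' @export
fourierShellCorrelation <- function(vol1, vol2, voxelSizeNm = NULL,
                                    window = c("hann", "none")) {
  window <- match.arg(window)
  if (is(vol1, "Tomogram")) {
    if (is.null(voxelSizeNm)) voxelSizeNm <- vol1@voxelSizeNm
    vol1 <- vol1@delta
  }
  if (is(vol2, "Tomogram")) vol2 <- vol2@delta
  if (is.null(voxelSizeNm)) voxelSizeNm <- 1
  if (!identical(dim(vol1), dim(vol2))) stop("volumes must share a grid")
  d <- dim(vol1)
  if (window == "hann") {
    w <- outer(outer(hannWindow(d[1]), hannWindow(d[2])), hannWindow(d[3]))
    vol1 <- vol1 * w
    vol2 <- vol2 * w
  }
  F1 <- stats::fft(vol1)
  F2 <- stats::fft(vol2)
  fy <- fftFreq(d[1]); fx <- fftFreq(d[2]); fz <- fftFreq(d[3])
  r <- sqrt(outer(outer(fy^2, fx^2, "+"), fz^2, "+"))
  db <- 1 / max(d)
  shell <- floor(r / db) + 1L
  nShell <- floor(0.5 / db) + 1L
  keep <- shell <= nShell
  sh <- shell[keep]
  x12 <- F1[keep] * Conj(F2[keep])
  num <- complex(real = rowsum(Re(x12), sh)[, 1],
                 imaginary = rowsum(Im(x12), sh)[, 1])
  s11 <- rowsum(Mod(F1[keep])^2, sh)[, 1]
  s22 <- rowsum(Mod(F2[keep])^2, sh)[, 1]
  n <- as.numeric(table(factor(sh, levels = seq_len(nShell))))
  denom <- sqrt(s11 * s22)
  fscv <- ifelse(denom > 0, Mod(num) / denom, 0)
  thr <- (0.2071 + 1.9102 / sqrt(pmax(n, 1))) /
         (1.2071 + 0.9102 / sqrt(pmax(n, 1)))
  freq <- (seq_len(nShell) - 0.5) * db
  # first downward crossing (skip the DC shell)
  res <- NA_real_
  for (k in 2:nShell) {
    if (fscv[k] < thr[k]) {
      f0 <- freq[k - 1]; f1 <- freq[k]
      g0 <- fscv[k - 1] - thr[k - 1]; g1 <- fscv[k] - thr[k]
      fc <- if (g0 > 0 && (g0 - g1) > 0) f0 + g0 * (f1 - f0) / (g0 - g1) else f1
      res <- voxelSizeNm / fc
      break
    }
  }
  if (!is.na(res)) res <- max(res, 2 * voxelSizeNm)  # Nyquist floor
  new("FSCResult", shellFreq = freq, correlation = as.numeric(fscv),
      threshold = as.numeric(thr), nVoxels = n, resolutionNm = res,
      voxelSizeNm = voxelSizeNm)
}

#' Surface dose of a weakly absorbing medium
#'
#' D = fluence x photon energy x mu/rho x nProjections, with the mass
#' attenuation coefficient mu/rho = 1/(attenuation length x density). For
#' water at 6.2 keV (attenuation length 451e-6 m, density 1000 kg/m^3) and
#' a fluence of 1e7 photons/um^2 this gives about 22 kGy per projection.
#'
#' @param fluencePerProjection photons per um^2 per projection.
#' @param photonEnergyKeV photon energy in keV.
#' @param attenuationLengthM attenuation length of the medium, metres.
#' @param mediumDensityKgM3 medium density, kg/m^3.
#' @param nProjections number of projections.
#' @return absorbed surface dose in Gray.
#' @examples
#' estimateDose(1e7, 6.2, 451e-6, 1000, 894) / 1e6  # ~20 MGy
#' @export
estimateDose <- function(fluencePerProjection, photonEnergyKeV,
                         attenuationLengthM, mediumDensityKgM3,
                         nProjections) {
  stopifnot(fluencePerProjection > 0, photonEnergyKeV > 0,
            attenuationLengthM > 0, mediumDensityKgM3 > 0,
            nProjections >= 0)
  eJ <- photonEnergyKeV * 1e3 * 1.602176634e-19
  fluenceM2 <- fluencePerProjection * 1e12
  fluenceM2 * eJ / (attenuationLengthM * mediumDensityKgM3) * nProjections
}

#' Segment a tomogram into density bands
#'
#' Assigns each voxel to the density band containing its electron density,
#' labels connected components within each band (26-connectivity), and
#' discards components below a minimum voxel count. This mirrors
#' contrast-based semi-automated segmentation of reconstructed tomograms
#' into feature classes.
#'
#' @param tomogram a [Tomogram-class], or a numeric 3-D array of electron
#'   densities.
#' @param bands data.frame with columns `name`, `lower`, `upper`
#'   (disjoint intervals; a voxel belongs to a band when
#'   lower < value <= upper).
#' @param minVoxels discard components smaller than this (default 0).
#' @return list with `labels` (integer array, 0 = unassigned; positive
#'   component ids) and `components` (data.frame: id, band, nVoxels,
#'   centroid y/x/z).
#' @export
segmentDensityBands <- function(tomogram, bands, minVoxels = 0L) {
  vol <- if (is(tomogram, "Tomogram")) electronDensity(tomogram) else tomogram
  stopifnot(is.data.frame(bands), all(c("name", "lower", "upper") %in% names(bands)))
  if (any(bands$upper <= bands$lower)) stop("bands must have upper > lower")
  o <- order(bands$lower)
  if (any(bands$lower[o][-1] < bands$upper[o][-nrow(bands)]))
    stop("density bands overlap")
  d <- dim(vol)
  labels <- array(0L, d)
  comps <- list()
  nextId <- 0L
  for (b in seq_len(nrow(bands))) {
    idx <- which(vol > bands$lower[b] & vol <= bands$upper[b])
    if (!length(idx)) next
    memb <- connectedComponents3D(idx, d)
    sizes <- tabulate(memb)
    keep <- which(sizes >= max(minVoxels, 1L))
    for (ci in keep) {
      nextId <- nextId + 1L
      vox <- idx[memb == ci]
      labels[vox] <- nextId
      iy <- (vox - 1) %% d[1] + 1
      ix <- ((vox - 1) %/% d[1]) %% d[2] + 1
      iz <- (vox - 1) %/% (d[1] * d[2]) + 1
      comps[[nextId]] <- data.frame(
        id = nextId, band = bands$name[b], nVoxels = length(vox),
        y = mean(iy), x = mean(ix), z = mean(iz))
    }
  }
  components <- if (length(comps)) do.call(rbind, comps) else
    data.frame(id = integer(), band = character(), nVoxels = integer(),
               y = numeric(), x = numeric(), z = numeric())
  list(labels = labels, components = components)
}

# 26-connectivity connected components of a voxel index set, via igraph
connectedComponents3D <- function(idx, d) {
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  iy <- (idx - 1) %% d[1] + 1
  ix <- ((idx - 1) %/% d[1]) %% d[2] + 1
  iz <- (idx - 1) %/% (d[1] * d[2]) + 1
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[seq_len(13), ]   # half the 26-neighbourhood (undirected edges)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    ny <- iy + offs$dy[k]; nx <- ix + offs$dx[k]; nz <- iz + offs$dz[k]
    ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
    nidx <- (nz[ok] - 1) * d[1] * d[2] + (nx[ok] - 1) * d[1] + ny[ok]
    nb <- pos[nidx]
    hit <- nb > 0L
    from <- c(from, pos[idx[ok]][hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < length(idx))
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
  igraph::components(g)$membership[seq_along(idx)]
}

#' Equivalent-sphere size statistics per segmented class
#'
#' For each component the equivalent-sphere diameter is
#' (6 V / pi)^(1/3) with V its voxel volume; statistics (mean, sd, count)
#' are aggregated per band/class.
#'
#' @param segmentation output of [segmentDensityBands()], or a components
#'   data.frame with columns `band` and `nVoxels`.
#' @param voxelSizeNm voxel size in nanometres.
#' @return data.frame with columns `band`, `n`, `meanDiameterUm`,
#'   `sdDiameterUm`.
#' @export
featureSizeStats <- function(segmentation, voxelSizeNm) {
  comp <- if (is.list(segmentation) && !is.data.frame(segmentation))
    segmentation$components else segmentation
  if (!nrow(comp))
    return(data.frame(band = character(), n = integer(),
                      meanDiameterUm = numeric(), sdDiameterUm = numeric()))
  diaUm <- (6 * comp$nVoxels / pi)^(1 / 3) * voxelSizeNm / 1000
  agg <- split(diaUm, comp$band)
  data.frame(
    band = names(agg),
    n = vapply(agg, length, integer(1)),
    meanDiameterUm = vapply(agg, mean, numeric(1)),
    sdDiameterUm = vapply(agg, function(x) if (length(x) > 1) stats::sd(x) else 0,
                          numeric(1)),
    row.names = NULL)
}

#' Depth-of-field advisory for the projection approximation
#'
#' The 2-D multiplicative model of the sample holds over an axial range
#' DOF = 5.2 resolution^2 / lambda. Configurations whose sample thickness
#' exceeds it are flagged (advisory only; image quality becomes suboptimal
#' rather than invalid).
#'
#' @param resolutionNm target resolution in nanometres.
#' @param wavelengthM X-ray wavelength in metres.
#' @param thicknessM sample thickness in metres.
#' @return list with `dofM` (depth of field in metres) and `flag` (TRUE
#'   when the thickness exceeds it).
#' @examples
#' depthOfFieldCheck(50, wavelengthM(6.2), 65e-6)
#' @export
depthOfFieldCheck <- function(resolutionNm, wavelengthM, thicknessM) {
  stopifnot(resolutionNm > 0, wavelengthM > 0, thicknessM > 0)
  dof <- 5.2 * (resolutionNm * 1e-9)^2 / wavelengthM
  list(dofM = dof, flag = thicknessM > dof)
}
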