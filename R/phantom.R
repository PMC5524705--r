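# Synthetic vitrified-tissue phantoms with quantitative electron density.

#' Feature-class label codes of a tissue phantom
#'
#' Integer codes of the voxel label grid. The classes emulate chemically
#' fixed, sucrose/PVP-infused brain tissue: embedding medium (cryoprotectant
#' solution), cytoplasm with an internal nucleus, myelinated axons (lipid
#' sheath around an axoplasm core), and pigmented autophagic vacuoles (a
#' low-density lipid sphere with a dense pigment sub-inclusion).
#'
#' @return named integer vector mapping class name to label code.
#' @export
phantomLabelTable <- function() {
  c(air = 0L, medium = 1L, cytoplasm = 2L, axoplasm = 3L, myelin = 4L,
    nucleus = 5L, vacuole_lipid = 6L, vacuole_pigment = 7L)
}

#' Default electron densities of the phantom feature classes
#'
#' Electrons per cubic Angstrom. The field-reported orderings these encode:
#' myelin below the surrounding sucrose-infused medium; vacuole lipid below
#' both myelin and medium; nucleus below cytoplasm; the pigment inclusion
#' densest of all.
#'
#' @return named numeric vector (electrons/Angstrom^3), one entry per
#'   non-air class.
#' @export
defaultDensityTable <- function() {
  c(medium = 0.40, cytoplasm = 0.37, axoplasm = 0.36, myelin = 0.34,
    nucleus = 0.35, vacuole_lipid = 0.31, vacuole_pigment = 0.45)
}

#' Describe a tissue phantom to be generated
#'
#' Collects the grid, support, feature counts/sizes and per-class electron
#' densities from which [buildPhantom()] generates a voxelized phantom.
#' Defaults describe a 25.6 x 25.6 x 12.8 um block at 200 nm voxels,
#' containing myelinated axons, two cells with nuclei, and three ~3 um
#' pigmented vacuoles, all strictly inside a cylindrical support surrounded
#' by air.
#'
#' @param gridDim integer length-3 (ny, nx, nz): vertical size first.
#' @param voxelSizeNm voxel side, nanometres.
#' @param supportShape "cylinder" or "box" lateral support cross-section.
#' @param supportRadiusFrac support radius (or half-width) as a fraction of
#'   the smaller transverse grid dimension; must leave air on all sides.
#' @param densities named numeric vector of electron densities per class
#'   (electrons/Angstrom^3); see [defaultDensityTable()].
#' @param nAxons,nCells,nVacuoles feature counts.
#' @param axonOuterRadiusUm length-2 range of axon outer radii, um.
#' @param sheathThicknessUm length-2 range of myelin sheath thicknesses, um.
#' @param cellRadiusUm cytoplasm sphere radius, um.
#' @param nucleusSemiAxesUm length-3 nucleus ellipsoid semi-axes (y, x, z), um.
#' @param vacuoleDiameterUm mean vacuole diameter, um (~3 um as observed for
#'   pigmented autophagic vacuoles).
#' @param vacuoleDiameterSdUm standard deviation of the vacuole diameter, um.
#' @param pigmentDiameterFrac pigment sub-sphere diameter as a fraction of
#'   its vacuole's diameter.
#' @param betaOverDelta absorption-to-phase ratio beta/delta used when
#'   projecting the phantom (phase contrast dominant).
#' @return a list of class `phantomSpec`.
#' @seealso [buildPhantom()]
#' @export
phantomSpec <- function(gridDim = c(64L, 128L, 128L), voxelSizeNm = 200,
                        supportShape = c("cylinder", "box"),
                        supportRadiusFrac = 0.43,
                        densities = defaultDensityTable(),
                        nAxons = 4L, nCells = 2L, nVacuoles = 3L,
                        axonOuterRadiusUm = c(1.6, 2.4),
                        sheathThicknessUm = c(1.0, 1.4),
                        cellRadiusUm = 4.5,
                        nucleusSemiAxesUm = c(1.8, 2.5, 1.8),
                        vacuoleDiameterUm = 3.0, vacuoleDiameterSdUm = 0.15,
                        pigmentDiameterFrac = 0.4, betaOverDelta = 0.005) {
  supportShape <- match.arg(supportShape)
  stopifnot(length(gridDim) == 3, all(gridDim >= 4), voxelSizeNm > 0,
            supportRadiusFrac > 0, supportRadiusFrac < 0.5,
            all(densities >= 0), betaOverDelta >= 0, betaOverDelta <= 0.1)
  needed <- names(defaultDensityTable())
  if (!all(needed %in% names(densities)))
    stop("densities must name all classes: ", paste(needed, collapse = ", "))
  structure(list(
    gridDim = as.integer(gridDim), voxelSizeNm = voxelSizeNm,
    supportShape = supportShape, supportRadiusFrac = supportRadiusFrac,
    densities = densities[needed], nAxons = as.integer(nAxons),
    nCells = as.integer(nCells), nVacuoles = as.integer(nVacuoles),
    axonOuterRadiusUm = axonOuterRadiusUm,
    sheathThicknessUm = sheathThicknessUm, cellRadiusUm = cellRadiusUm,
    nucleusSemiAxesUm = nucleusSemiAxesUm,
    vacuoleDiameterUm = vacuoleDiameterUm,
    vacuoleDiameterSdUm = vacuoleDiameterSdUm,
    pigmentDiameterFrac = pigmentDiameterFrac,
    betaOverDelta = betaOverDelta), class = "phantomSpec")
}

# sphere / ellipsoid voxel mask over a bounding box, returned as global indices
sphereVoxels <- function(d, center, semi) {
  lo <- pmax(1L, floor(center - semi)); hi <- pmin(d, ceiling(center + semi))
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  u2 <- ((ys - center[1]) / semi[1])^2
  v2 <- ((xs - center[2]) / semi[2])^2
  w2 <- ((zs - center[3]) / semi[3])^2
  m <- outer(outer(u2, v2, "+"), w2, "+") <= 1
  idx <- which(m)
  iy <- ys[(idx - 1) %% length(ys) + 1]
  rest <- (idx - 1) %/% length(ys)
  ix <- xs[rest %% length(xs) + 1]
  iz <- zs[rest %/% length(xs) + 1]
  (iz - 1) * d[1] * d[2] + (ix - 1) * d[1] + iy
}

# vertical cylinder (all y) with annulus radii [rin, rout] in the (x, z) plane
cylinderVoxels <- function(d, cx, cz, rout, rin = 0) {
  xs <- seq_len(d[2]) - cx; zs <- seq_len(d[3]) - cz
  r2 <- outer(xs^2, zs^2, "+")
  m <- which(r2 <= rout^2 & r2 >= rin^2)
  ix <- (m - 1) %% d[2] + 1
  iz <- (m - 1) %/% d[2] + 1
  plane <- (iz - 1) * d[1] * d[2] + (ix - 1) * d[1]
  as.vector(outer(seq_len(d[1]), plane, "+"))
}

#' Generate a voxelized tissue phantom
#'
#' Builds the label grid and electron-density grid described by a
#' [phantomSpec()]: a support cylinder (or box) of embedding medium strictly
#' surrounded by air, containing vertical myelinated axons (annular lipid
#' sheath around an axoplasm core, randomized sheath thickness), cells
#' (cytoplasm spheres with an internal nucleus ellipsoid), and spherical
#' vacuoles with a dense pigment sub-sphere. Overlapping features are
#' resolved by a fixed precedence (pigment > vacuole > nucleus > myelin >
#' axoplasm > cytoplasm > medium), implemented by painting classes in
#' increasing precedence order.
#'
#' @param spec a [phantomSpec()].
#' @param seed integer seed; generation is deterministic given (spec, seed).
#' @return a [TissuePhantom-class].
#' @examples
#' ph <- buildPhantom(phantomSpec(gridDim = c(16L, 48L, 48L), nAxons = 1L,
#'                                nCells = 0L, nVacuoles = 1L), seed = 1)
#' table(featureLabels(ph))
#' @export
buildPhantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$gridDim
  vox <- spec$voxelSizeNm
  px <- function(um) um * 1000 / vox   # micrometres -> voxels
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  cx <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  Rs <- spec$supportRadiusFrac * min(d[2], d[3])
  if (Rs >= min(d[2], d[3]) / 2 - 1)
    stop("support does not leave air on all sides of the rotation axis")
  xs <- seq_len(d[2]) - cx; zs <- seq_len(d[3]) - cz
  support <- if (spec$supportShape == "cylinder") {
    outer(xs^2, zs^2, "+") <= Rs^2
  } else {
    outer(abs(xs) <= Rs, abs(zs) <= Rs, "&")
  }

  lab <- phantomLabelTable()
  labels <- array(lab["air"], d)
  labels[rep(support, each = d[1])] <- lab["medium"]

  features <- list()
  # random centre inside the support with a lateral margin (voxels)
  drawCenter <- function(marginXY, marginY) {
    for (i in 1:400) {
      x <- stats::runif(1, cx - Rs + marginXY, cx + Rs - marginXY)
      z <- stats::runif(1, cz - Rs + marginXY, cz + Rs - marginXY)
      y <- stats::runif(1, 1 + marginY, d[1] - marginY)
      if (sqrt((x - cx)^2 + (z - cz)^2) <= Rs - marginXY) return(c(y, x, z))
    }
    stop("could not place a feature inside the support")
  }
  checkFits <- function(sizePx, what) {
    if (sizePx < 2) stop(what, " smaller than 2 voxels")
    if (2 * sizePx >= 2 * Rs) stop(what, " exceeds the support cross-section")
    if (sizePx * 2 >= d[1] && what != "axon radius")
      stop(what, " exceeds the grid height")
  }

  # cells: cytoplasm spheres with internal nucleus ellipsoids
  if (spec$nCells > 0) for (i in seq_len(spec$nCells)) {
    rc <- px(spec$cellRadiusUm)
    checkFits(rc, "cell radius")
    ctr <- drawCenter(rc * 0.6 + 1, min(rc, d[1] / 4))
    labels[sphereVoxels(d, ctr, rep(rc, 3))] <- lab["cytoplasm"]
    semi <- px(spec$nucleusSemiAxesUm)
    off <- stats::runif(3, -0.15, 0.15) * rc
    labels[sphereVoxels(d, ctr + off, semi)] <- NA  # placeholder, painted later
    features[[length(features) + 1]] <-
      data.frame(type = "cell", y = ctr[1], x = ctr[2], z = ctr[3], sizePx = rc)
    features[[length(features) + 1]] <-
      data.frame(type = "nucleus", y = ctr[1] + off[1], x = ctr[2] + off[2],
                 z = ctr[3] + off[3], sizePx = mean(semi))
  }
  nucleusMask <- which(is.na(labels))

  # axons: vertical myelin annuli with axoplasm cores
  if (spec$nAxons > 0) for (i in seq_len(spec$nAxons)) {
    rout <- px(stats::runif(1, spec$axonOuterRadiusUm[1], spec$axonOuterRadiusUm[2]))
    thick <- px(stats::runif(1, spec$sheathThicknessUm[1], spec$sheathThicknessUm[2]))
    rin <- max(rout - thick, 1)
    checkFits(rout, "axon radius")
    ctr <- drawCenter(rout + 1, 0)
    labels[cylinderVoxels(d, ctr[2], ctr[3], rout)] <- lab["axoplasm"]
    labels[cylinderVoxels(d, ctr[2], ctr[3], rout, rin)] <- lab["myelin"]
    features[[length(features) + 1]] <-
      data.frame(type = "axon", y = NA, x = ctr[2], z = ctr[3], sizePx = rout)
  }

  labels[nucleusMask] <- lab["nucleus"]

  # vacuoles: lipid spheres with a dense pigment sub-sphere
  if (spec$nVacuoles > 0) for (i in seq_len(spec$nVacuoles)) {
    dia <- max(stats::rnorm(1, spec$vacuoleDiameterUm, spec$vacuoleDiameterSdUm),
               0.3 * spec$vacuoleDiameterUm)
    rv <- px(dia) / 2
    checkFits(rv, "vacuole radius")
    ctr <- drawCenter(rv + 1, rv + 1)
    labels[sphereVoxels(d, ctr, rep(rv, 3))] <- lab["vacuole_lipid"]
    rp <- rv * spec$pigmentDiameterFrac
    poff <- stats::runif(3, -0.5, 0.5) * (rv - rp)
    labels[sphereVoxels(d, ctr + poff, rep(rp, 3))] <- lab["vacuole_pigment"]
    features[[length(features) + 1]] <-
      data.frame(type = "vacuole", y = ctr[1], x = ctr[2], z = ctr[3], sizePx = rv)
  }

  # clip features to the support and assign densities
  airMask <- !rep(support, each = d[1])
  labels[airMask] <- lab["air"]
  dens <- c(0, spec$densities[c("medium", "cytoplasm", "axoplasm", "myelin",
                                "nucleus", "vacuole_lipid", "vacuole_pigment")])
  ne <- array(dens[labels + 1L], d)

  feat <- if (length(features)) do.call(rbind, features) else
    data.frame(type = character(), y = numeric(), x = numeric(),
               z = numeric(), sizePx = numeric())
  new("TissuePhantom", electronDensity = ne, labels = labels,
      voxelSizeNm = vox, supportMask = support,
      densityTable = spec$densities, features = feat,
      seed = as.integer(seed))
}

#' Refractive-index decrement and absorption index from electron density
#'
#' delta = r_e lambda^2 n_e / (2 pi) elementwise, with n_e in
#' electrons/Angstrom^3 and lambda in metres; beta = betaOverDelta * delta.
#' Both maps are linear in the density.
#'
#' @param electronDensity numeric array/vector, electrons/Angstrom^3 (>= 0).
#' @param wavelengthM X-ray wavelength in metres.
#' @param betaOverDelta ratio beta/delta in [0, 0.1]; default 0.005 (phase
#'   contrast dominant at multi-keV energies).
#' @return list with elements `delta` and `beta`, same shape as the input.
#' @examples
#' deltaBetaFromElectronDensity(0.3344, wavelengthM(6.20))$delta  # ~6e-6
#' @export
deltaBetaFromElectronDensity <- function(electronDensity, wavelengthM,
                                         betaOverDelta = 0.005) {
  stopifnot(wavelengthM > 0, betaOverDelta >= 0, betaOverDelta <= 0.1)
  if (any(electronDensity < 0)) stop("electron density must be nonnegative")
  neM3 <- electronDensity * 1e30          # e/A^3 -> e/m^3
  delta <- .const$electronRadiusM * wavelengthM^2 * neM3 / (2 * pi)
  list(delta = delta, beta = betaOverDelta * delta)
}

#' Mass density from electron density
#'
#' rho_m = n_e * (1.86 g/mol) / N_A, with units reconciled so that an input
#' in electrons/Angstrom^3 yields g/cm^3. The 1.86 g/mol molar mass per
#' electron describes hydrated biological material (water, lipid, protein,
#' chromatin); for pure water the true ratio is 1.80 g/mol, so tissue-wide
#' the conversion is accurate to within a few percent.
#'
#' @param electronDensity numeric array/vector, electrons/Angstrom^3 (>= 0).
#' @return mass density in g/cm^3, same shape as the input.
#' @examples
#' massDensityFromElectronDensity(0.3344)  # ~1.033 g/cm^3
#' @export
massDensityFromElectronDensity <- function(electronDensity) {
  if (any(electronDensity < 0)) stop("electron density must be nonnegative")
  electronDensity * 1e24 * .const$molarMassPerElectron / .const$avogadro
}

#' Ground-truth complex projection of a phantom
#'
#' Rotates the phantom about the vertical axis by the requested angle
#' (bilinear interpolation, zero padding), integrates delta and beta along
#' the beam, and forms the complex transmission under the projection
#' approximation:
#' T = exp(-(2 pi / lambda) int beta dz) * exp(-1i (2 pi / lambda) int delta dz).
#' Denser material gives more negative phase.
#'
#' @param phantom a [TissuePhantom-class].
#' @param angleDeg angle in degrees, in [0, 180).
#' @param wavelengthM X-ray wavelength in metres (or an [OpticsConfig-class],
#'   from which the wavelength is taken; its pixel size must then match the
#'   phantom voxel size to within 1%).
#' @param betaOverDelta absorption-to-phase ratio.
#' @return a [ComplexProjection-class] of dimensions (ny, nx).
#' @export
groundTruthProjection <- function(phantom, angleDeg, wavelengthM,
                                  betaOverDelta = 0.005) {
  stopifnot(is(phantom, "TissuePhantom"))
  if (angleDeg < 0 || angleDeg >= 180) stop("angle must lie in [0, 180)")
  if (is(wavelengthM, "OpticsConfig")) {
    opt <- wavelengthM
    p <- reconstructionPixelSize(opt)
    if (abs(p - phantom@voxelSizeNm) > 0.01 * phantom@voxelSizeNm)
      stop("phantom voxel size does not match the reconstruction pixel size")
    wavelengthM <- wavelengthM(opt)
  }
  db <- deltaBetaFromElectronDensity(phantom@electronDensity, wavelengthM,
                                     betaOverDelta)
  pathDelta <- projectVolumeY(db$delta, angleDeg) * phantom@voxelSizeNm * 1e-9
  k <- 2 * pi / wavelengthM
  trans <- exp(-k * betaOverDelta * pathDelta) * exp(-1i * k * pathDelta)
  new("ComplexProjection", transmission = trans, angleDeg = angleDeg,
      pixelSizeNm = phantom@voxelSizeNm)
}
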