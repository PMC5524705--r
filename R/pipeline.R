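# End-to-end orchestration: configuration profiles, deterministic per-stage
# seeding, the full phantom -> simulate -> reconstruct -> align -> tomogram
# -> quantify chain, and miniature fixture generation.

#' Deterministic per-stage seed derivation
#'
#' Derives a stage seed from the master seed, the stage name, and an
#' optional index (e.g. angle number) by a rolling multiplicative hash
#' modulo 2^31 - 1, so inserting stages never silently changes other
#' stages' random streams.
#'
#' @param master master seed (integer).
#' @param stage stage name (character).
#' @param index optional integer index within the stage.
#' @return integer seed in \[1, 2^31 - 2\].
#' @export
stageSeed <- function(master, stage, index = 0L) {
  m <- 2147483647
  h <- as.numeric(master) %% m
  for (c in utf8ToInt(stage)) h <- (h * 48271 + c) %% m
  h <- (h * 48271 + as.numeric(index)) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Build a pipeline run configuration
#'
#' Collects everything a reproducible end-to-end run needs: acquisition
#' geometry, phantom description, scan parameters, solver iteration
#' counts, alignment settings, dose parameters and the master seed. Two
#' ready-made profiles exist: [deskProfile()] (a desk-scale study that
#' runs in minutes) and [beamlineGeometryProfile()] (the full beamline
#' geometry, for its derived quantities).
#'
#' @param name profile name.
#' @param optics list of [opticsConfig()] arguments.
#' @param phantom list of [phantomSpec()] arguments.
#' @param scan list: `fieldOfViewM` (length 2), `stepM`, `snapToGrid`.
#' @param nAngles number of equally spaced angles over \[0, 180).
#' @param noise logical: Poisson counting noise.
#' @param solver list: `nIterDm`, `nIterMl`, `probeFreeze`, `defocusRad`.
#' @param align list: `cropWidth` (analysis window width), `badK` (MAD
#'   multiplier for projection rejection), `removeOverride` (manual
#'   removal list), `nOuter`, `upsample`.
#' @param dose list: `attenuationLengthM`, `mediumDensityKgM3`.
#' @param seed master seed.
#' @return a list of class `pxctConfig`.
#' @export
runConfig <- function(name = "custom", optics, phantom = list(),
                      scan, nAngles = 60L, noise = FALSE,
                      solver = list(), align = list(), dose = list(),
                      seed = 1L) {
  solver <- utils::modifyList(
    list(nIterDm = 150L, nIterMl = 30L, probeFreeze = 10L, defocusRad = 2),
    solver)
  align <- utils::modifyList(
    list(cropWidth = NA_integer_, badK = 5, removeOverride = integer(),
         nOuter = 10L, upsample = 100, tolPx = 0.05), align)
  dose <- utils::modifyList(
    list(attenuationLengthM = 451e-6, mediumDensityKgM3 = 1000), dose)
  structure(list(name = name, optics = optics, phantom = phantom,
                 scan = scan, nAngles = as.integer(nAngles),
                 noise = isTRUE(noise), solver = solver, align = align,
                 dose = dose, seed = as.integer(seed)),
            class = "pxctConfig")
}

#' Desk-scale end-to-end profile
#'
#' A complete study that runs on one CPU in minutes: 6.2 keV optics scaled
#' to a 64-pixel detector region (200 nm reconstruction pixels), a
#' 128 x 128 x 64 voxel phantom, a 31-pixel (6.2 um) probe scanned on a
#' Fermat spiral over the sample (~40 positions per angle), 60 angles over
#' \[0, 180), and 150 difference-map plus 30 maximum-likelihood iterations
#' per projection.
#'
#' @param noise logical: Poisson counting noise (default FALSE).
#' @param seed master seed.
#' @param nAngles number of angles (default 60).
#' @return a `pxctConfig`.
#' @export
deskProfile <- function(noise = FALSE, seed = 1L, nAngles = 60L) {
  # 6.2 keV, 64 px of 75 um pitch at 4.8006 m -> 200.0 nm pixels
  optics <- list(photonEnergyKeV = 6.2, detectorDistanceM = 4.8006,
                 detectorPixelPitchM = 75e-6, detectorRegionPx = 64L,
                 probeDiameterM = 6.2e-6, fluencePerProjection = 1e7)
  p <- 200e-9
  # the scan reaches 1.6 um past the sample on each side so the air margin
  # used for phase anchoring is properly illuminated
  runConfig(
    name = "desk", optics = optics,
    phantom = list(gridDim = c(64L, 128L, 128L), voxelSizeNm = 200),
    scan = list(fieldOfViewM = c(144 * p, 64 * p), stepM = 3.0e-6,
                snapToGrid = TRUE),
    nAngles = nAngles, noise = noise,
    align = list(cropWidth = 144L),
    seed = seed)
}

#' Reference beamline geometry profile
#'
#' The full-scale acquisition geometry used for thick brainstem tissue:
#' 6.20 keV, detector at 7.33 m with 75 um pitch, a 452-pixel region
#' (43.2 nm voxels), ~7 um probe, 2.2 um Fermat-spiral steps, ~1e7
#' photons/um^2 per projection, and 446 / 894 / 785 projections for
#' samples A / B / C. Used for geometry- and dose-derived quantities; the
#' measurement itself is simulated only at desk scale.
#'
#' @param sample "A", "B" or "C".
#' @param seed master seed.
#' @return a `pxctConfig`.
#' @export
beamlineGeometryProfile <- function(sample = c("A", "B", "C"), seed = 1L) {
  sample <- match.arg(sample)
  nProj <- c(A = 446L, B = 894L, C = 785L)[[sample]]
  iters <- if (sample == "A") list(nIterDm = 800L, nIterMl = 150L)
           else list(nIterDm = 600L, nIterMl = 100L)
  fov <- if (sample == "C") c(50e-6, 15e-6) else c(100e-6, 20e-6)
  runConfig(
    name = paste0("beamline-", sample),
    optics = list(photonEnergyKeV = 6.20, detectorDistanceM = 7.33,
                  detectorPixelPitchM = 75e-6, detectorRegionPx = 452L,
                  probeDiameterM = 7e-6, fluencePerProjection = 1e7),
    phantom = list(),
    scan = list(fieldOfViewM = fov, stepM = 2.2e-6, snapToGrid = FALSE),
    nAngles = nProj, solver = iters, seed = seed)
}

#' Write / read a run configuration as YAML
#'
#' The configuration is fully serializable; serialize -> parse ->
#' serialize is the identity.
#'
#' @param config a `pxctConfig`.
#' @param path file path.
#' @return `readRunConfig` returns a `pxctConfig`;
#'   `writeRunConfig` returns `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "pxctConfig"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$nAngles <- as.integer(x$nAngles)
  x$seed <- as.integer(x$seed)
  structure(x, class = "pxctConfig")
}

# angles equally spaced over [0, 180)
pipelineAngles <- function(n) (seq_len(n) - 1) * 180 / n

#' Run the full cryo-PXCT pipeline
#'
#' Executes every stage in order -- phantom generation, per-angle
#' ground-truth projection and diffraction simulation, per-angle
#' difference-map + maximum-likelihood phase retrieval, projection
#' processing (derivative, air-region ramp removal), bad-projection
#' removal, vertical and horizontal (tomographic-consistency) alignment,
#' angular weighting, derivative filtered back-projection, and
#' quantitative analysis (density recovery per feature class, FSC
#' resolution from half-tomograms, dose estimate, density-band
#' segmentation) -- and returns a run report. Intermediate artifacts are
#' persisted as RDS files when `outputDir` is given, making the run
#' resumable stage by stage.
#'
#' @param config a `pxctConfig` (see [deskProfile()]).
#' @param outputDir optional directory for stage artifacts.
#' @param verbose print stage progress and timings.
#' @return a list of class `pxctReport`: configuration echoes, per-stage
#'   metrics, recovered-density table, FSC resolution, dose, segmentation
#'   statistics, and timings.
#' @export
runPipeline <- function(config, outputDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pxctConfig"))
  t0 <- proc.time()[3]
  timings <- c()
  say <- function(...) if (verbose) message(sprintf(...))
  clock <- function(stage) {
    el <- proc.time()[3] - t0
    timings[stage] <<- el - sum(timings)
    say("[%s] %s done (%.1f s)", config$name, stage, timings[stage])
  }
  persist <- function(x, name) {
    if (!is.null(outputDir)) {
      dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(x, file.path(outputDir, paste0(name, ".rds")))
    }
  }

  optics <- do.call(opticsConfig, config$optics)
  pNm <- reconstructionPixelSize(optics)
  lam <- wavelengthM(optics)

  spec <- do.call(phantomSpec, config$phantom)
  if (abs(spec$voxelSizeNm - pNm) > 0.01 * pNm)
    stop("phantom voxel size must match the reconstruction pixel size")
  phantom <- buildPhantom(spec, seed = stageSeed(config$seed, "phantom"))
  persist(phantom, "phantom")
  clock("phantom")

  angles <- pipelineAngles(config$nAngles)
  scan <- fermatSpiral(config$scan$fieldOfViewM, config$scan$stepM)
  nPos <- nrow(scan@positions)
  areaUm2 <- prod(config$scan$fieldOfViewM) * 1e12
  totalPhotons <- optics@fluencePerProjection * areaUm2 / nPos
  probe <- makeProbe(optics, totalPhotons, config$solver$defocusRad)

  d <- dim(phantom@electronDensity)
  N <- optics@detectorRegionPx
  fovPx <- ceiling(config$scan$fieldOfViewM / (pNm * 1e-9))
  objectDim <- c(max(d[1], fovPx[2]) + N + 6L, max(d[2], fovPx[1]) + N + 6L)
  W2 <- config$align$cropWidth
  if (is.na(W2)) W2 <- d[2]
  rowSel <- ((objectDim[1] - d[1]) %/% 2 + 1):((objectDim[1] - d[1]) %/% 2 + d[1])
  colSel <- ((objectDim[2] - W2) %/% 2 + 1):((objectDim[2] - W2) %/% 2 + W2)

  # air columns: outside the support radius at every angle
  supRad <- {
    sm <- phantom@supportMask
    ctr <- (dim(sm) + 1) / 2
    idx <- which(sm, arr.ind = TRUE)
    max(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
  }
  colDist <- abs(seq_len(W2) - (W2 + 1) / 2)
  airMask <- matrix(rep(colDist > supRad + 4, each = d[1]), d[1], W2)
  support2D <- matrix(rep(colDist <= supRad - 2, each = d[1]), d[1], W2)

  nA <- length(angles)
  derivStack <- array(0, c(d[1], W2, nA))
  ampStack <- array(0, c(d[1], W2, nA))
  ferr <- numeric(nA)
  mlFlags <- integer(nA)
  for (a in seq_len(nA)) {
    proj <- groundTruthProjection(phantom, angles[a], lam, spec$betaOverDelta)
    emb <- embedProjection(proj, objectDim)
    data <- simulateDiffraction(emb, probe, scan, noise = config$noise,
                                seed = stageSeed(config$seed, "noise", a),
                                snapToGrid = isTRUE(config$scan$snapToGrid))
    rec <- dmReconstruct(data, config$solver$nIterDm, probeInit = probe,
                         probeFreeze = config$solver$probeFreeze)
    if (config$solver$nIterMl > 0)
      rec <- mlRefine(rec, data, config$solver$nIterMl)
    ferr[a] <- utils::tail(rec@errorHistory, 1)
    mlFlags[a] <- rec@mlFlag
    crop <- rec@object[rowSel, colSel]
    ampStack[, , a] <- Mod(crop)
    derivStack[, , a] <- removeRamp(phaseDerivative(crop), airMask)
    if (verbose && (a %% max(1, nA %/% 6) == 0))
      say("  reconstructed %d/%d projections", a, nA)
  }
  clock("ptycho")

  removed <- sort(unique(c(flagBadProjections(ampStack, support2D,
                                              k = config$align$badK),
                           as.integer(config$align$removeOverride))))
  keep <- setdiff(seq_len(nA), removed)
  derivStack <- derivStack[, , keep, drop = FALSE]
  anglesKept <- angles[keep]
  say("  removed %d problematic projections", length(removed))

  va <- verticalAlign(derivStack, airCols = airMask[1, ], maxShiftPx = 5)
  for (a in seq_along(keep))
    derivStack[, , a] <- applyImageShift(derivStack[, , a], -va$shifts[a], 0)
  pre <- comPrealign(derivStack, anglesKept)
  ca <- consistencyAlign(derivStack, anglesKept, shiftsInit = pre$shifts,
                         nOuter = config$align$nOuter,
                         tolPx = config$align$tolPx,
                         upsample = config$align$upsample)
  for (a in seq_along(keep))
    derivStack[, , a] <- applyImageShift(derivStack[, , a], 0, -ca$shifts[a])
  weights <- angularWeights(anglesKept)
  sino <- new("AlignedSinogram", derivative = derivStack, angles = anglesKept,
              shifts = cbind(dy = va$shifts, dx = ca$shifts),
              weights = weights, removedIndices = as.integer(removed),
              pixelSizeNm = pNm)
  persist(sino, "sinogram")
  clock("align")

  tomo <- derivativeFBP(sino, wavelengthM = lam)
  persist(tomo, "tomogram")
  ne <- electronDensity(tomo)
  clock("tomo")

  halves <- splitHalfTomograms(sino, wavelengthM = lam)
  fsc <- fourierShellCorrelation(halves$even, halves$odd)
  dosePerProj <- estimateDose(optics@fluencePerProjection,
                              optics@photonEnergyKeV,
                              config$dose$attenuationLengthM,
                              config$dose$mediumDensityKgM3, 1)
  doseGy <- dosePerProj * config$nAngles

  # density recovery per feature class (2-voxel interior erosion)
  colSel0 <- ((W2 - d[2]) %/% 2 + 1):((W2 - d[2]) %/% 2 + d[2])
  neCrop <- ne[, colSel0, colSel0, drop = FALSE]
  lab <- phantomLabelTable()
  recov <- lapply(names(lab)[-1], function(cl) {
    m <- phantom@labels == lab[[cl]]
    m <- erode3D(m, 2L)
    if (!any(m)) return(NULL)
    assigned <- phantom@densityTable[[cl]]
    med <- stats::median(neCrop[m])
    data.frame(class = cl, assigned = assigned, recovered = med,
               relErrPct = 100 * (med - assigned) / assigned,
               nVoxels = sum(m))
  })
  densityTable <- do.call(rbind, recov)

  # density-band segmentation between the class densities
  dt <- phantom@densityTable
  bands <- data.frame(
    name = c("vacuole", "myelin", "nucleus"),
    lower = c(mean(c(dt[["vacuole_lipid"]], 0)),
              mean(c(dt[["myelin"]], dt[["vacuole_lipid"]])),
              mean(c(dt[["nucleus"]], dt[["myelin"]]))),
    upper = c(mean(c(dt[["vacuole_lipid"]], dt[["myelin"]])),
              mean(c(dt[["myelin"]], dt[["nucleus"]])),
              mean(c(dt[["nucleus"]], dt[["axoplasm"]]))))
  # confine segmentation to the support interior (the partial-volume ring
  # at the air boundary sweeps through every density band)
  neSeg <- neCrop
  supInt <- erode3D(array(rep(phantom@supportMask, each = d[1]), d), 3L)
  neSeg[!supInt] <- -1
  # minimum component: ~1/3 the volume of the smallest expected vacuole,
  # well above partial-volume debris at class boundaries
  seg <- segmentDensityBands(neSeg, bands, minVoxels = 400L)
  sizes <- featureSizeStats(seg, pNm)
  clock("quant")

  report <- structure(list(
    name = config$name, seed = config$seed,
    pixelSizeNm = pNm, wavelengthM = lam,
    nAngles = config$nAngles, nPositions = nPos,
    totalPhotons = totalPhotons,
    removedProjections = removed,
    meanFourierError = mean(ferr), mlFlags = sum(mlFlags),
    verticalShiftRangePx = range(va$shifts),
    horizontalShiftRangePx = range(ca$shifts),
    alignConverged = ca$converged,
    densityTable = densityTable,
    orderingOk = {
      rv <- stats::setNames(densityTable$recovered, densityTable$class)
      all(c("vacuole_lipid", "myelin", "medium", "nucleus", "cytoplasm")
          %in% names(rv)) &&
        rv[["vacuole_lipid"]] < rv[["myelin"]] &&
        rv[["myelin"]] < rv[["medium"]] &&
        rv[["nucleus"]] < rv[["cytoplasm"]]
    },
    fscResolutionNm = fsc@resolutionNm,
    doseGy = doseGy, dosePerProjectionGy = dosePerProj,
    segmentation = sizes,
    vacuoleCount = sum(seg$components$band == "vacuole"),
    timings = timings,
    phantom = phantom, tomogram = tomo, sinogram = sino, fsc = fsc),
    class = "pxctReport")
  persist(report, "report")
  clock("report")
  report
}

#' @export
print.pxctReport <- function(x, ...) {
  cat("cryo-PXCT run report --", x$name, "(seed", x$seed, ")\n")
  cat(sprintf("  pixel size: %.2f nm; %d angles x %d positions\n",
              x$pixelSizeNm, x$nAngles, x$nPositions))
  cat(sprintf("  dose: %.1f MGy (%.1f kGy/projection)\n",
              x$doseGy / 1e6, x$dosePerProjectionGy / 1e3))
  cat(sprintf("  FSC resolution: %s\n",
              if (is.na(x$fscResolutionNm)) "beyond Nyquist"
              else sprintf("%.0f nm", x$fscResolutionNm)))
  cat(sprintf("  removed projections: %d; alignment converged: %s\n",
              length(x$removedProjections), x$alignConverged))
  cat("  recovered electron densities (e/A^3):\n")
  print(x$densityTable, row.names = FALSE, digits = 3)
  cat(sprintf("  density ordering (vacuole < myelin < medium; nucleus < cytoplasm): %s\n",
              x$orderingOk))
  invisible(x)
}

# 6-neighbourhood binary erosion, iterated
erode3D <- function(mask, iterations = 1L) {
  d <- dim(mask)
  for (i in seq_len(iterations)) {
    m <- mask
    m[-1, , ] <- m[-1, , ] & mask[-d[1], , ]
    m[-d[1], , ] <- m[-d[1], , ] & mask[-1, , ]
    m[, -1, ] <- m[, -1, ] & mask[, -d[2], ]
    m[, -d[2], ] <- m[, -d[2], ] & mask[, -1, ]
    m[, , -1] <- m[, , -1] & mask[, , -d[3]]
    m[, , -d[3]] <- m[, , -d[3]] & mask[, , -1]
    m[1, , ] <- FALSE; m[d[1], , ] <- FALSE
    m[, 1, ] <- FALSE; m[, d[2], ] <- FALSE
    m[, , 1] <- FALSE; m[, , d[3]] <- FALSE
    mask <- m
  }
  mask
}

#' Generate a miniature packaged dataset
#'
#' Builds a small, fully simulated dataset (phantom, configuration,
#' per-angle diffraction data and ground-truth projections) for tests and
#' examples, and optionally stores it as RDS files. The "unit" profile
#' completes in seconds (9 scan positions, 16 angles, 32-pixel frames);
#' "desk" and "noisy-desk" are the [deskProfile()] without / with Poisson
#' noise.
#'
#' @param profile one of "unit", "desk", "noisy-desk".
#' @param seed master seed.
#' @param dir optional output directory.
#' @return list with `config`, `phantom`, `projections` (ground truth) and
#'   `data` (list of [DiffractionData-class], one per angle), invisibly
#'   written to `dir` when given.
#' @export
makeFixture <- function(profile = c("unit", "desk", "noisy-desk"),
                        seed = 1L, dir = NULL) {
  profile <- tryCatch(match.arg(profile), error = function(e)
    stop("unknown profile; available: unit, desk, noisy-desk"))
  config <- switch(profile,
    "unit" = {
      p <- 400e-9
      runConfig(
        name = "unit",
        optics = list(photonEnergyKeV = 6.2,
                      detectorDistanceM = p * 32 * 75e-6 / wavelengthM(6.2),
                      detectorPixelPitchM = 75e-6, detectorRegionPx = 32L,
                      probeDiameterM = 14 * p, fluencePerProjection = 1e7),
        phantom = list(gridDim = c(24L, 48L, 48L), voxelSizeNm = 400,
                       nAxons = 1L, nCells = 1L, nVacuoles = 1L,
                       cellRadiusUm = 4, nucleusSemiAxesUm = c(2, 2.6, 2),
                       vacuoleDiameterUm = 4, axonOuterRadiusUm = c(1.5, 2.2),
                       sheathThicknessUm = c(0.5, 0.9)),
        scan = list(fieldOfViewM = c(48 * p, 24 * p), stepM = 7.2e-6,
                    snapToGrid = TRUE),
        nAngles = 16L, solver = list(nIterDm = 30L, nIterMl = 5L),
        seed = seed)
    },
    "desk" = deskProfile(noise = FALSE, seed = seed),
    "noisy-desk" = deskProfile(noise = TRUE, seed = seed))

  optics <- do.call(opticsConfig, config$optics)
  lam <- wavelengthM(optics)
  spec <- do.call(phantomSpec, config$phantom)
  phantom <- buildPhantom(spec, seed = stageSeed(config$seed, "phantom"))
  angles <- pipelineAngles(config$nAngles)
  scan <- fermatSpiral(config$scan$fieldOfViewM, config$scan$stepM)
  areaUm2 <- prod(config$scan$fieldOfViewM) * 1e12
  totalPhotons <- optics@fluencePerProjection * areaUm2 / nrow(scan@positions)
  probe <- makeProbe(optics, totalPhotons, config$solver$defocusRad)
  d <- dim(phantom@electronDensity)
  fovPx <- ceiling(config$scan$fieldOfViewM /
                   (reconstructionPixelSize(optics) * 1e-9))
  objectDim <- c(max(d[1], fovPx[2]) + optics@detectorRegionPx + 6L,
                 max(d[2], fovPx[1]) + optics@detectorRegionPx + 6L)
  projections <- list(); data <- list()
  for (a in seq_along(angles)) {
    proj <- groundTruthProjection(phantom, angles[a], lam, spec$betaOverDelta)
    emb <- embedProjection(proj, objectDim)
    projections[[a]] <- proj
    data[[a]] <- simulateDiffraction(emb, probe, scan, noise = config$noise,
                                     seed = stageSeed(config$seed, "noise", a),
                                     snapToGrid = isTRUE(config$scan$snapToGrid))
  }
  out <- list(config = config, phantom = phantom, probe = probe,
              projections = projections, data = data)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeRunConfig(config, file.path(dir, "config.yaml"))
    saveRDS(phantom, file.path(dir, "phantom.rds"))
    saveRDS(probe, file.path(dir, "probe.rds"))
    saveRDS(projections, file.path(dir, "projections.rds"))
    saveRDS(data, file.path(dir, "diffraction.rds"))
  }
  out
}
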