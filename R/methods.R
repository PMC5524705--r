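# Accessors and show methods for the S4 containers.

#' @describeIn voxelSize voxel size of a phantom
#' @export
setMethod("voxelSize", "TissuePhantom", function(x) x@voxelSizeNm)
#' @describeIn voxelSize voxel size of a tomogram
#' @export
setMethod("voxelSize", "Tomogram", function(x) x@voxelSizeNm)
#' @describeIn voxelSize pixel size of a projection
#' @export
setMethod("voxelSize", "ComplexProjection", function(x) x@pixelSizeNm)
#' @describeIn voxelSize pixel size of a sinogram
#' @export
setMethod("voxelSize", "AlignedSinogram", function(x) x@pixelSizeNm)

#' @describeIn electronDensity assigned density grid of a phantom
#' @export
setMethod("electronDensity", "TissuePhantom", function(x) x@electronDensity)
#' @describeIn electronDensity density derived from the reconstructed
#'   refractive-index decrement, n_e = 2 pi delta / (r_e lambda^2)
#' @export
setMethod("electronDensity", "Tomogram", function(x)
  electronDensityFromDelta(x@delta, x@wavelengthM))

#' @describeIn massDensity mass density of a phantom
#' @export
setMethod("massDensity", "TissuePhantom", function(x)
  massDensityFromElectronDensity(electronDensity(x)))
#' @describeIn massDensity mass density of a tomogram
#' @export
setMethod("massDensity", "Tomogram", function(x)
  massDensityFromElectronDensity(electronDensity(x)))

#' @describeIn featureLabels label grid of a phantom
#' @export
setMethod("featureLabels", "TissuePhantom", function(x) x@labels)

#' @describeIn phaseImage wrapped phase Arg(T)
#' @export
setMethod("phaseImage", "ComplexProjection", function(x) Arg(x@transmission))
#' @describeIn amplitudeImage amplitude |T|
#' @export
setMethod("amplitudeImage", "ComplexProjection", function(x) Mod(x@transmission))

#' @describeIn scanPositions positions of a scan pattern
#' @export
setMethod("scanPositions", "ScanPattern", function(x) x@positions)
#' @describeIn scanPositions positions behind a diffraction dataset
#' @export
setMethod("scanPositions", "DiffractionData", function(x) x@scan@positions)

#' @describeIn probeField field of a probe
#' @export
setMethod("probeField", "Probe", function(x) x@field)
#' @describeIn probeField retrieved probe of a reconstruction
#' @export
setMethod("probeField", "PtychoResult", function(x) x@probe)

#' @describeIn objectTransmission retrieved object of a reconstruction
#' @export
setMethod("objectTransmission", "PtychoResult", function(x) x@object)

#' @describeIn errorHistory Fourier error per difference-map iteration
#' @export
setMethod("errorHistory", "PtychoResult", function(x) x@errorHistory)

#' @describeIn anglesDeg angles of a sinogram
#' @export
setMethod("anglesDeg", "AlignedSinogram", function(x) x@angles)

#' @describeIn angleWeights weights of a sinogram
#' @export
setMethod("angleWeights", "AlignedSinogram", function(x) x@weights)

#' @describeIn resolutionNm resolution at the half-bit crossing
#' @export
setMethod("resolutionNm", "FSCResult", function(x) x@resolutionNm)

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig:", object@photonEnergyKeV, "keV,",
      object@detectorDistanceM, "m,",
      object@detectorRegionPx, "px region,",
      format(object@detectorPixelPitchM * 1e6), "um pitch\n")
  cat("  wavelength:", format(wavelengthM(object), digits = 6), "m;",
      "pixel size:", format(reconstructionPixelSize(object), digits = 4), "nm\n")
  cat("  probe:", object@probeDiameterM * 1e6, "um; fluence:",
      format(object@fluencePerProjection, digits = 3), "ph/um^2\n")
})

setMethod("show", "TissuePhantom", function(object) {
  d <- dim(object@electronDensity)
  cat("TissuePhantom:", paste(d, collapse = " x "), "voxels,",
      object@voxelSizeNm, "nm/voxel (seed", object@seed, ")\n")
  tab <- table(factor(object@labels, levels = seq_along(phantomLabelTable()) - 1L,
                      labels = names(phantomLabelTable())))
  print(tab)
})

setMethod("show", "ComplexProjection", function(object) {
  cat("ComplexProjection at", object@angleDeg, "deg:",
      paste(dim(object@transmission), collapse = " x "), "px,",
      object@pixelSizeNm, "nm/px\n")
  cat("  phase range:", paste(format(range(Arg(object@transmission)), digits = 3),
                              collapse = " .. "), "rad\n")
})

setMethod("show", "ScanPattern", function(object) {
  cat("ScanPattern:", nrow(object@positions), "positions, step",
      object@nominalStepM * 1e6, "um, FOV",
      paste(format(object@fieldOfViewM * 1e6, digits = 3), collapse = " x "), "um\n")
})

setMethod("show", "Probe", function(object) {
  cat("Probe:", paste(dim(object@field), collapse = " x "), "px,",
      format(object@totalPhotons, digits = 4), "photons/exposure\n")
})

setMethod("show", "DiffractionData", function(object) {
  d <- dim(object@frames)
  cat("DiffractionData at", object@angleDeg, "deg:", d[3], "frames of",
      d[1], "x", d[2], if (object@noisy) "(Poisson counts)" else "(noiseless)", "\n")
})

setMethod("show", "PtychoResult", function(object) {
  cat("PtychoResult:", paste(dim(object@object), collapse = " x "), "object,",
      object@iterationsRun["dm"], "DM +", object@iterationsRun["ml"], "ML iterations\n")
  if (length(object@errorHistory))
    cat("  final Fourier error:",
        format(utils::tail(object@errorHistory, 1), digits = 4), "\n")
})

setMethod("show", "AlignedSinogram", function(object) {
  d <- dim(object@derivative)
  cat("AlignedSinogram:", d[3], "angles,", d[1], "x", d[2], "px/projection;",
      length(object@removedIndices), "removed\n")
})

setMethod("show", "Tomogram", function(object) {
  cat("Tomogram:", paste(dim(object@delta), collapse = " x "), "voxels,",
      object@voxelSizeNm, "nm/voxel\n")
  cat("  delta range:", paste(format(range(object@delta), digits = 3),
                              collapse = " .. "), "\n")
})

setMethod("show", "FSCResult", function(object) {
  cat("FSCResult:", length(object@shellFreq), "shells; resolution:",
      if (is.na(object@resolutionNm)) "beyond Nyquist"
      else paste(format(object@resolutionNm, digits = 4), "nm"), "\n")
})
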