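#' Voxel or pixel size in nanometres
#' @param x an object carrying a grid spacing.
#' @return numeric scalar, nanometres.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Electron density of an object, electrons per cubic Angstrom
#' @param x a [TissuePhantom-class] or [Tomogram-class].
#' @return numeric array in electrons/Angstrom^3.
#' @export
setGeneric("electronDensity", function(x) standardGeneric("electronDensity"))

#' Mass density of an object, g/cm^3
#'
#' Conversion from electron density uses the molar-mass-per-electron ratio
#' of 1.86 g/mol adopted for hydrated biological material (water, lipid,
#' protein, chromatin mixture).
#' @param x a [TissuePhantom-class] or [Tomogram-class].
#' @return numeric array in g/cm^3.
#' @export
setGeneric("massDensity", function(x) standardGeneric("massDensity"))

#' Feature-class label volume of a phantom
#' @param x a [TissuePhantom-class].
#' @return integer 3-D array of label codes; see [phantomLabelTable()].
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' Phase of a complex projection, radians
#' @param x a [ComplexProjection-class].
#' @return numeric matrix of wrapped phase in radians.
#' @export
setGeneric("phaseImage", function(x) standardGeneric("phaseImage"))

#' Amplitude attenuation of a complex projection
#' @param x a [ComplexProjection-class].
#' @return numeric matrix of |T| in [0, 1].
#' @export
setGeneric("amplitudeImage", function(x) standardGeneric("amplitudeImage"))

#' Scan positions in metres
#' @param x a [ScanPattern-class] or [DiffractionData-class].
#' @return n-by-2 matrix of (x, y) positions.
#' @export
setGeneric("scanPositions", function(x) standardGeneric("scanPositions"))

#' Complex probe field
#' @param x a [Probe-class] or [PtychoResult-class].
#' @return complex matrix.
#' @export
setGeneric("probeField", function(x) standardGeneric("probeField"))

#' Complex object transmission estimate
#' @param x a [PtychoResult-class].
#' @return complex matrix.
#' @export
setGeneric("objectTransmission", function(x) standardGeneric("objectTransmission"))

#' Convergence error history
#' @param x a [PtychoResult-class].
#' @return numeric vector of per-iteration Fourier errors.
#' @export
setGeneric("errorHistory", function(x) standardGeneric("errorHistory"))

#' Tomographic angles in degrees
#' @param x an [AlignedSinogram-class].
#' @return numeric vector.
#' @export
setGeneric("anglesDeg", function(x) standardGeneric("anglesDeg"))

#' Per-angle weights of a sinogram
#' @param x an [AlignedSinogram-class].
#' @return numeric vector summing to the number of angles.
#' @export
setGeneric("angleWeights", function(x) standardGeneric("angleWeights"))

#' Resolution estimate in nanometres
#' @param x an [FSCResult-class].
#' @return numeric scalar (NA when the curve never crosses the threshold).
#' @export
setGeneric("resolutionNm", function(x) standardGeneric("resolutionNm"))
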