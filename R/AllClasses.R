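#' @import methods
NULL

#' Beamline and detector geometry
#'
#' Holds the acquisition geometry from which the reconstruction pixel size
#' derives: photon energy, sample-detector distance, detector pixel pitch,
#' the square detector region used for reconstruction, the probe diameter
#' on the sample, and the photon fluence delivered per projection.
#'
#' All lengths are stored in metres; energies in keV; fluence in
#' photons/um^2. The X-ray wavelength is derived as lambda = hc/E and the
#' reconstruction pixel size as p = lambda * distance / (N * pitch).
#'
#' @slot photonEnergyKeV photon energy in keV.
#' @slot detectorDistanceM sample-detector distance in metres.
#' @slot detectorPixelPitchM detector pixel pitch in metres.
#' @slot detectorRegionPx side length N of the square detector region, pixels.
#' @slot probeDiameterM nominal probe diameter on the sample, metres.
#' @slot fluencePerProjection incident photons per um^2 per projection.
#' @seealso [opticsConfig()], [reconstructionPixelSize()], [wavelengthM()]
#' @export
setClass("OpticsConfig",
  representation(photonEnergyKeV = "numeric", detectorDistanceM = "numeric",
                 detectorPixelPitchM = "numeric", detectorRegionPx = "integer",
                 probeDiameterM = "numeric", fluencePerProjection = "numeric"),
  validity = function(object) {
    v <- c(object@photonEnergyKeV, object@detectorDistanceM,
           object@detectorPixelPitchM, object@detectorRegionPx,
           object@probeDiameterM, object@fluencePerProjection)
    if (any(!is.finite(v)) || any(v <= 0))
      return("all geometry fields must be finite and strictly positive")
    TRUE
  })

#' Voxelized tissue phantom with quantitative electron density
#'
#' A 3-D block of vitrified, cryoprotectant-infused tissue represented on a
#' regular voxel grid. Arrays are indexed (y, x, z) with y the vertical
#' rotation axis and the beam along +z at 0 degrees. Each voxel carries an
#' electron density (electrons per cubic Angstrom) and a feature-class
#' label; the lateral support cross-section is surrounded by air on all
#' sides of the rotation axis.
#'
#' @slot electronDensity 3-D array, electrons/Angstrom^3; zero exactly where
#'   the label is air.
#' @slot labels 3-D integer array of feature classes (see
#'   [phantomLabelTable()]).
#' @slot voxelSizeNm voxel side length in nanometres.
#' @slot supportMask nx-by-nz logical matrix: the lateral footprint of the
#'   sample (air outside).
#' @slot densityTable named numeric vector: nominal electron density per
#'   feature class.
#' @slot features data.frame describing the generated features (type,
#'   centre, size), used as ground truth by downstream checks.
#' @slot seed integer seed the phantom was generated from.
#' @seealso [buildPhantom()], [phantomSpec()]
#' @export
setClass("TissuePhantom",
  representation(electronDensity = "array", labels = "array",
                 voxelSizeNm = "numeric", supportMask = "matrix",
                 densityTable = "numeric", features = "data.frame",
                 seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@electronDensity), dim(object@labels)))
      return("electronDensity and labels must share dimensions")
    if (any(object@electronDensity < 0))
      return("electron density must be nonnegative")
    if (any(object@electronDensity[object@labels == 0L] != 0))
      return("electron density must be exactly zero in air")
    d <- dim(object@electronDensity)
    if (!identical(dim(object@supportMask), d[2:3]))
      return("supportMask must be nx-by-nz")
    # support strictly inside the grid in both transverse directions
    if (any(object@supportMask[c(1, d[2]), ]) || any(object@supportMask[, c(1, d[3])]))
      return("support must be strictly inside the grid (air on all sides)")
    TRUE
  })

#' Complex-valued projection of a sample
#'
#' The complex transmission T(y, x) of the sample at one tomographic angle
#' under the projection (multiplicative) approximation:
#' T = exp(-(2*pi/lambda) * int beta dz) * exp(-1i * (2*pi/lambda) * int delta dz).
#' Denser material gives more negative phase; |T| <= 1 for a passive sample.
#'
#' @slot transmission complex matrix (rows y, columns x).
#' @slot angleDeg tomographic angle in degrees, in [0, 180).
#' @slot pixelSizeNm pixel size in nanometres.
#' @seealso [groundTruthProjection()], [phaseImage()], [amplitudeImage()]
#' @export
setClass("ComplexProjection",
  representation(transmission = "matrix", angleDeg = "numeric",
                 pixelSizeNm = "numeric"),
  validity = function(object) {
    if (!is.complex(object@transmission))
      return("transmission must be a complex matrix")
    if (object@angleDeg < 0 || object@angleDeg >= 180)
      return("angle must lie in [0, 180)")
    TRUE
  })

#' Fermat-spiral scan pattern
#'
#' Probe positions on the sample plane, ordered by generation index.
#' Positions are continuous coordinates in metres relative to the scan
#' centre; column 1 is x (horizontal), column 2 is y (vertical).
#'
#' @slot positions n-by-2 matrix of (x, y) positions in metres.
#' @slot nominalStepM nominal step size in metres.
#' @slot fieldOfViewM length-2 numeric (width, height) in metres.
#' @seealso [fermatSpiral()]
#' @export
setClass("ScanPattern",
  representation(positions = "matrix", nominalStepM = "numeric",
                 fieldOfViewM = "numeric"),
  validity = function(object) {
    p <- object@positions
    if (ncol(p) != 2) return("positions must have two columns (x, y)")
    f <- object@fieldOfViewM
    if (length(f) != 2 || any(f <= 0)) return("fieldOfViewM must be two positive lengths")
    if (any(abs(p[, 1]) > f[1] / 2 + 1e-12) || any(abs(p[, 2]) > f[2] / 2 + 1e-12))
      return("all positions must lie inside the field of view")
    TRUE
  })

#' Complex illumination (probe)
#'
#' The coherent illumination field on the reconstruction pixel grid,
#' normalized so that sum(|field|^2) equals the photon budget per exposure.
#'
#' @slot field N-by-N complex matrix.
#' @slot totalPhotons photons per exposure.
#' @slot pixelSizeNm reconstruction pixel size in nanometres.
#' @seealso [makeProbe()]
#' @export
setClass("Probe",
  representation(field = "matrix", totalPhotons = "numeric",
                 pixelSizeNm = "numeric"),
  validity = function(object) {
    if (!is.complex(object@field)) return("field must be complex")
    pw <- sum(Mod(object@field)^2)
    if (abs(pw - object@totalPhotons) > 1e-6 * object@totalPhotons)
      return("probe power must equal totalPhotons")
    TRUE
  })

#' One angle's diffraction frames
#'
#' Far-field intensity frames recorded (or simulated) at each scan position
#' of one tomographic angle, together with the window geometry that places
#' each probe position on the object reconstruction grid.
#'
#' @slot frames N-by-N-by-nPositions array of nonnegative intensities
#'   (integer-valued counts when Poisson noise was applied).
#' @slot scan the [ScanPattern-class] used.
#' @slot angleDeg tomographic angle in degrees.
#' @slot pixelSizeNm reconstruction pixel size in nanometres.
#' @slot objectDim integer length-2: rows/cols of the object grid.
#' @slot winTopLeft nPositions-by-2 integer matrix of 1-based top-left
#'   (row, col) of each probe window in the object grid.
#' @slot frac nPositions-by-2 matrix of sub-pixel (row, col) offsets.
#' @slot noisy logical: whether Poisson counting noise was applied.
#' @slot seed integer RNG seed used for the noise.
#' @seealso [simulateDiffraction()], [dmReconstruct()]
#' @export
setClass("DiffractionData",
  representation(frames = "array", scan = "ScanPattern", angleDeg = "numeric",
                 pixelSizeNm = "numeric", objectDim = "integer",
                 winTopLeft = "matrix", frac = "matrix", noisy = "logical",
                 seed = "integer"),
  validity = function(object) {
    d <- dim(object@frames)
    if (length(d) != 3) return("frames must be a 3-D array [N, N, nPositions]")
    if (d[3] != nrow(object@winTopLeft))
      return("frame count must equal the number of scan positions")
    if (any(object@frames < 0)) return("intensities must be nonnegative")
    TRUE
  })

#' Ptychographic reconstruction of one projection
#'
#' Complex object transmission and complex probe retrieved from one angle's
#' diffraction frames, with per-iteration convergence diagnostics.
#'
#' @slot object complex matrix: object transmission estimate on the object
#'   grid.
#' @slot probe complex N-by-N matrix: retrieved illumination.
#' @slot errorHistory per-iteration Fourier error of the difference-map
#'   stage.
#' @slot likelihoodHistory Poisson negative log-likelihood per accepted
#'   maximum-likelihood iteration (empty if refinement was not run).
#' @slot iterationsRun named integer vector c(dm = ..., ml = ...).
#' @slot mlFlag integer; 1 when the maximum-likelihood line search stopped
#'   early, 0 otherwise.
#' @seealso [dmReconstruct()], [mlRefine()]
#' @export
setClass("PtychoResult",
  representation(object = "matrix", probe = "matrix", errorHistory = "numeric",
                 likelihoodHistory = "numeric", iterationsRun = "integer",
                 mlFlag = "integer"),
  validity = function(object) {
    if (!is.complex(object@object) || !is.complex(object@probe))
      return("object and probe must be complex matrices")
    if (any(!is.finite(object@errorHistory)))
      return("error history must be finite")
    TRUE
  })

#' Aligned phase-derivative sinogram
#'
#' Stack of horizontal phase-derivative projections (rad/pixel) after ramp
#' removal and alignment, with per-angle shifts, angular weights, and the
#' indices of removed (problematic) projections.
#'
#' @slot derivative H-by-W-by-nAngles array of d(phi)/dx in rad/pixel.
#' @slot angles angles in degrees, strictly increasing in [0, 180).
#' @slot shifts nAngles-by-2 matrix of applied (dy, dx) corrections, pixels.
#' @slot weights per-angle nonnegative weights summing to nAngles.
#' @slot removedIndices integer indices (into the original series) of
#'   projections removed before reconstruction.
#' @slot pixelSizeNm pixel size in nanometres.
#' @export
setClass("AlignedSinogram",
  representation(derivative = "array", angles = "numeric", shifts = "matrix",
                 weights = "numeric", removedIndices = "integer",
                 pixelSizeNm = "numeric"),
  validity = function(object) {
    n <- length(object@angles)
    if (dim(object@derivative)[3] != n)
      return("derivative stack depth must equal the number of angles")
    if (is.unsorted(object@angles, strictly = TRUE))
      return("angles must be strictly increasing")
    if (any(object@angles < 0) || any(object@angles >= 180))
      return("angles must lie in [0, 180)")
    if (any(object@weights <= 0)) return("weights must be positive")
    if (abs(sum(object@weights) - n) > 1e-8 * n)
      return("weights must sum to the number of angles")
    TRUE
  })

#' Reconstructed tomogram
#'
#' 3-D refractive-index-decrement volume delta(y, x, z) on an isotropic
#' voxel grid, convertible to electron density via
#' n_e = 2*pi*delta / (r_e * lambda^2) and to mass density via the molar
#' mass per electron ratio.
#'
#' @slot delta 3-D array of the refractive index decrement (dimensionless).
#' @slot voxelSizeNm voxel side in nanometres.
#' @slot wavelengthM X-ray wavelength in metres.
#' @slot provenance list of reconstruction settings (angles, weights,
#'   shifts, removed indices) for reproducibility.
#' @seealso [derivativeFBP()], [electronDensity()], [massDensity()]
#' @export
setClass("Tomogram",
  representation(delta = "array", voxelSizeNm = "numeric",
                 wavelengthM = "numeric", provenance = "list"),
  validity = function(object) {
    if (length(dim(object@delta)) != 3) return("delta must be a 3-D array")
    if (object@voxelSizeNm <= 0 || object@wavelengthM <= 0)
      return("voxel size and wavelength must be positive")
    TRUE
  })

#' Fourier shell correlation curve and resolution
#'
#' @slot shellFreq shell centre frequencies in cycles/voxel.
#' @slot correlation FSC per shell, in [-1, 1] up to numerical round-off.
#' @slot threshold half-bit significance threshold per shell.
#' @slot nVoxels voxel count per shell.
#' @slot resolutionNm resolution at the first threshold crossing in
#'   nanometres; NA when the curve never crosses (beyond Nyquist).
#' @slot voxelSizeNm voxel size of the correlated volumes.
#' @seealso [fourierShellCorrelation()]
#' @export
setClass("FSCResult",
  representation(shellFreq = "numeric", correlation = "numeric",
                 threshold = "numeric", nVoxels = "numeric",
                 resolutionNm = "numeric", voxelSizeNm = "numeric"),
  validity = function(object) {
    n <- length(object@shellFreq)
    if (length(object@correlation) != n || length(object@threshold) != n)
      return("shellFreq, correlation and threshold must have equal length")
    TRUE
  })
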