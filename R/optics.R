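#' Construct an acquisition geometry
#'
#' @param photonEnergyKeV photon energy in keV.
#' @param detectorDistanceM sample-detector distance, metres.
#' @param detectorPixelPitchM detector pixel pitch, metres.
#' @param detectorRegionPx side length N of the square detector region used
#'   for reconstruction, pixels.
#' @param probeDiameterM probe diameter on the sample, metres.
#' @param fluencePerProjection incident photons per um^2 per projection.
#' @return an [OpticsConfig-class].
#' @examples
#' opt <- opticsConfig(6.20, 7.33, 75e-6, 452L, 7e-6, 1e7)
#' reconstructionPixelSize(opt)  # ~43.2 nm
#' @export
opticsConfig <- function(photonEnergyKeV, detectorDistanceM, detectorPixelPitchM,
                         detectorRegionPx, probeDiameterM = 7e-6,
                         fluencePerProjection = 1e7) {
  new("OpticsConfig", photonEnergyKeV = photonEnergyKeV,
      detectorDistanceM = detectorDistanceM,
      detectorPixelPitchM = detectorPixelPitchM,
      detectorRegionPx = as.integer(detectorRegionPx),
      probeDiameterM = probeDiameterM,
      fluencePerProjection = fluencePerProjection)
}

#' X-ray wavelength of a photon energy
#'
#' lambda = hc / E with hc = 1.23984193e-9 keV m.
#'
#' @param x an [OpticsConfig-class] or a photon energy in keV.
#' @return wavelength in metres.
#' @examples
#' wavelengthM(6.20)  # ~2.0e-10 m
#' @export
wavelengthM <- function(x) {
  e <- if (is(x, "OpticsConfig")) x@photonEnergyKeV else x
  stopifnot(is.numeric(e), all(e > 0))
  .const$hcKeVm / e
}

#' Reconstruction pixel size of a ptychographic geometry
#'
#' The real-space pixel of the reconstruction is fixed by the detector
#' geometry: p = lambda * distance / (N * pitch). With 6.20 keV photons, a
#' detector 7.33 m downstream, a 452-pixel region and 75 um pitch this gives
#' about 43.2 nm per pixel.
#'
#' @param optics an [OpticsConfig-class].
#' @return pixel size in nanometres.
#' @export
reconstructionPixelSize <- function(optics) {
  stopifnot(is(optics, "OpticsConfig"))
  p <- wavelengthM(optics) * optics@detectorDistanceM /
    (optics@detectorRegionPx * optics@detectorPixelPitchM)
  p * 1e9
}

# pixel size in metres (internal)
pixelSizeM <- function(optics) reconstructionPixelSize(optics) * 1e-9
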