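# Export of volumes and projections for external inspection.

#' Export a volume as a multi-page TIFF of axial slices
#'
#' Writes one 16-bit grayscale page per slice along the rotation (y) axis.
#' Values are mapped linearly from `range` to \[0, 1\]; the range used is
#' returned so intensities can be mapped back.
#'
#' @param vol numeric 3-D array (y, x, z), or a [Tomogram-class] /
#'   [TissuePhantom-class] (its delta / electron-density grid is written).
#' @param path output file path.
#' @param range length-2 numeric mapped to black/white; default the volume
#'   range.
#' @return invisibly, the range used.
#' @export
writeVolumeTIFF <- function(vol, path, range = NULL) {
  if (is(vol, "Tomogram")) vol <- vol@delta
  if (is(vol, "TissuePhantom")) vol <- vol@electronDensity
  stopifnot(length(dim(vol)) == 3)
  if (is.null(range)) range <- base::range(vol)
  if (diff(range) == 0) range <- range + c(0, 1)
  pages <- lapply(seq_len(dim(vol)[1]), function(y) {
    m <- (vol[y, , ] - range[1]) / diff(range)
    pmin(pmax(m, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(range)
}

#' Export projection images as a multi-page TIFF
#'
#' Writes the phase (or amplitude) of a list of projections, one page per
#' angle, normalized over the whole stack.
#'
#' @param projections list of [ComplexProjection-class] objects.
#' @param path output file path.
#' @param what "phase" or "amplitude".
#' @return invisibly, the range used.
#' @export
writeProjectionsTIFF <- function(projections, path,
                                 what = c("phase", "amplitude")) {
  what <- match.arg(what)
  imgs <- lapply(projections, if (what == "phase") phaseImage else amplitudeImage)
  rng <- range(unlist(lapply(imgs, range)))
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  pages <- lapply(imgs, function(m) pmin(pmax((m - rng[1]) / diff(rng), 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(rng)
}
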