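# Rotation about the vertical (y) axis and parallel-beam forward projection.
#
# Grid convention (fixed repo-wide): arrays are indexed (y, x, z); y is the
# rotation axis, the beam travels along +z at 0 degrees, the system is
# right-handed, angles are in degrees on the half-open interval [0, 180).
# Rotation uses bilinear interpolation with zero padding outside the grid.

# Bilinear gather weights for rotating (x, z) planes by angleDeg.
# Returns indices into an (nx * nz + 1)-column layout where the last column
# is a zero sentinel for out-of-grid samples.
rotationGather <- function(nx, nz, angleDeg) {
  a <- angleDeg * pi / 180
  cx <- (nx + 1) / 2; cz <- (nz + 1) / 2
  xo <- rep(seq_len(nx) - cx, times = nz)
  zo <- rep(seq_len(nz) - cz, each = nx)
  xs <- cx + xo * cos(a) - zo * sin(a)
  zs <- cz + xo * sin(a) + zo * cos(a)
  i0 <- floor(xs); k0 <- floor(zs)
  fx <- xs - i0; fz <- zs - k0
  colIdx <- function(i, k) {
    ok <- i >= 1 & i <= nx & k >= 1 & k <= nz
    ifelse(ok, (k - 1) * nx + i, nx * nz + 1L)
  }
  list(
    c00 = colIdx(i0, k0),     w00 = (1 - fx) * (1 - fz),
    c10 = colIdx(i0 + 1, k0), w10 = fx * (1 - fz),
    c01 = colIdx(i0, k0 + 1), w01 = (1 - fx) * fz,
    c11 = colIdx(i0 + 1, k0 + 1), w11 = fx * fz
  )
}

# Rotate a (ny, nx, nz) volume about y by angleDeg (bilinear, zero-padded).
rotateVolumeY <- function(vol, angleDeg) {
  d <- dim(vol)
  g <- rotationGather(d[2], d[3], angleDeg)
  M <- cbind(matrix(vol, d[1], d[2] * d[3]), 0)
  out <- M[, g$c00, drop = FALSE] * rep(g$w00, each = d[1]) +
         M[, g$c10, drop = FALSE] * rep(g$w10, each = d[1]) +
         M[, g$c01, drop = FALSE] * rep(g$w01, each = d[1]) +
         M[, g$c11, drop = FALSE] * rep(g$w11, each = d[1])
  array(out, d)
}

# Line integrals along the beam (z) of the volume rotated by angleDeg.
# Returns a (ny, nx) matrix in units of value * voxel (path in voxels).
projectVolumeY <- function(vol, angleDeg) {
  rot <- rotateVolumeY(vol, angleDeg)
  rowSums(rot, dims = 2)
}
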