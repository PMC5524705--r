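test_that("derivative FBP recovers the analytic disc quantitatively", {
  cs <- cachedScene("cylSino", cylinderSinogram())
  tom <- derivativeFBP(cs$sino, angles = cs$angles, pixelSizeNm = cs$voxNm,
                       wavelengthM = cs$wavelengthM)
  sl <- tom@delta[1, , ]
  xs <- matrix(seq_len(cs$W) - cs$ctr, cs$W, cs$W)
  zs <- t(xs)
  rr <- sqrt((xs - cs$x0)^2 + (zs - cs$z0)^2)
  interior <- rr < cs$R - 3
  exterior <- rr > cs$R + 3
  expect_lt(max(abs(sl[interior] / cs$delta0 - 1)), 0.02)
  expect_lt(mean(abs(sl[exterior])) / cs$delta0, 0.02)
  # air mean is essentially zero
  expect_lt(abs(mean(sl[exterior])) / cs$delta0, 0.005)
})

test_that("FBP is linear", {
  cs <- cachedScene("cylSino", cylinderSinogram())
  sub <- cs$sino[, , seq(1, 90, by = 3), drop = FALSE]
  ang <- cs$angles[seq(1, 90, by = 3)]
  t1 <- derivativeFBP(sub, angles = ang, pixelSizeNm = cs$voxNm,
                      wavelengthM = cs$wavelengthM)
  t2 <- derivativeFBP(2 * sub, angles = ang, pixelSizeNm = cs$voxNm,
                      wavelengthM = cs$wavelengthM)
  expect_equal(t2@delta, 2 * t1@delta, tolerance = 1e-12)
  set.seed(8)
  other <- array(rnorm(length(sub), 0, 1e-4), dim(sub))
  t3 <- derivativeFBP(sub + other, angles = ang, pixelSizeNm = cs$voxNm,
                      wavelengthM = cs$wavelengthM)
  t4 <- derivativeFBP(other, angles = ang, pixelSizeNm = cs$voxNm,
                      wavelengthM = cs$wavelengthM)
  expect_equal(t3@delta, t1@delta + t4@delta, tolerance = 1e-10)
  zero <- derivativeFBP(0 * sub, angles = ang, pixelSizeNm = cs$voxNm,
                        wavelengthM = cs$wavelengthM)
  expect_true(all(zero@delta == 0))
})

test_that("electron density and decrement are exact inverses", {
  lam <- wavelengthM(6.2)
  set.seed(9)
  ne <- array(runif(4 * 5 * 6, 0, 0.5), c(4, 5, 6))
  delta <- deltaBetaFromElectronDensity(ne, lam)$delta
  expect_equal(electronDensityFromDelta(delta, lam), ne, tolerance = 1e-12)
  expect_equal(electronDensityFromDelta(6.0e-6, 1.99975e-10), 0.3345,
               tolerance = 1e-3)
  expect_equal(electronDensityFromDelta(0, lam), 0)
})

test_that("half-tomogram split partitions the angles", {
  cs <- cachedScene("cylSino", cylinderSinogram())
  nA <- length(cs$angles)
  halves <- splitHalfTomograms(cs$sino, angles = cs$angles,
                               pixelSizeNm = cs$voxNm,
                               wavelengthM = cs$wavelengthM)
  iE <- seq(1, nA, by = 2); iO <- seq(2, nA, by = 2)
  expect_setequal(c(halves$even@provenance$angles,
                    halves$odd@provenance$angles), cs$angles)
  expect_length(intersect(halves$even@provenance$angles,
                          halves$odd@provenance$angles), 0)
  # duplicated input: both halves see identical data -> identical volumes
  dup <- cs$sino[, , rep(seq(1, nA, by = 6), each = 2), drop = FALSE]
  dupAng <- rep(cs$angles[seq(1, nA, by = 6)], each = 2)
  hd <- suppressWarnings(   # 12-degree gaps in the sparse duplicated set
    splitHalfTomograms(dup, angles = dupAng, pixelSizeNm = cs$voxNm,
                       wavelengthM = cs$wavelengthM))
  expect_identical(hd$even@delta, hd$odd@delta)
  expect_error(splitHalfTomograms(cs$sino[, , 1:6, drop = FALSE],
                                  angles = cs$angles[1:6],
                                  pixelSizeNm = cs$voxNm,
                                  wavelengthM = cs$wavelengthM), "8 angles")
})

test_that("a rotationally symmetric phantom reconstructs symmetrically", {
  sp <- phantomSpec(gridDim = c(6L, 64L, 64L), voxelSizeNm = 200,
                    nAxons = 0L, nCells = 0L, nVacuoles = 0L,
                    supportRadiusFrac = 0.35)
  ph <- buildPhantom(sp, seed = 1)
  lam <- wavelengthM(6.2)
  nA <- 60
  angles <- (0:(nA - 1)) * 3
  st <- array(0, c(6, 64, nA))
  for (a in seq_len(nA))
    st[, , a] <- phaseDerivative(groundTruthProjection(ph, angles[a], lam))
  tom <- derivativeFBP(st, angles = angles, pixelSizeNm = 200,
                       wavelengthM = lam)
  sl <- tom@delta[3, , ]
  xs <- matrix(seq_len(64) - 32.5, 64, 64); zs <- t(xs)
  rr <- sqrt(xs^2 + zs^2)
  interior <- rr < 0.35 * 64 - 3
  # azimuthal coefficient of variation inside the support
  expect_lt(stats::sd(sl[interior]) / mean(sl[interior]), 0.03)
})

test_that("large angular gaps produce a warning", {
  cs <- cachedScene("cylSino", cylinderSinogram())
  idx <- c(1:20, 40:90)
  expect_warning(derivativeFBP(cs$sino[, , idx], angles = cs$angles[idx],
                               pixelSizeNm = cs$voxNm,
                               wavelengthM = cs$wavelengthM), "gap")
})
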