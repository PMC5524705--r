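test_that("FSC of identical volumes is unity at every shell", {
  set.seed(10)
  v <- array(rnorm(32^3), c(32, 32, 32))
  f <- fourierShellCorrelation(v, v, 10)
  expect_true(all(abs(f@correlation - 1) < 1e-9))
  expect_true(is.na(resolutionNm(f)))
})

test_that("independent noise volumes decorrelate at the expected level", {
  set.seed(1)
  v1 <- array(rnorm(40^3), c(40, 40, 40))
  v2 <- array(rnorm(40^3), c(40, 40, 40))
  f <- fourierShellCorrelation(v1, v2, 1, window = "none")
  m <- f@nVoxels > 100
  expect_true(all(f@correlation[m] < 3 / sqrt(f@nVoxels[m])))
})

test_that("FSC is symmetric and invariant to a shared scale", {
  set.seed(11)
  base <- array(rnorm(24^3), c(24, 24, 24))
  v1 <- base + array(rnorm(24^3, 0, 0.5), c(24, 24, 24))
  v2 <- base + array(rnorm(24^3, 0, 0.5), c(24, 24, 24))
  f12 <- fourierShellCorrelation(v1, v2, 5)
  f21 <- fourierShellCorrelation(v2, v1, 5)
  expect_equal(f12@correlation, f21@correlation, tolerance = 1e-12)
  fs <- fourierShellCorrelation(3.7 * v1, 3.7 * v2, 5)
  expect_equal(fs@correlation, f12@correlation, tolerance = 1e-9)
  expect_error(fourierShellCorrelation(v1, v2[1:12, , ], 5), "grid")
})

test_that("resolution crossing behaves with controlled correlation decay", {
  # shared low-frequency signal + independent noise: resolution must be
  # finite, above the Nyquist floor, and degrade as the noise grows
  set.seed(12)
  mk <- function(sigma) {
    sig <- array(rnorm(32^3), c(32, 32, 32))
    lp <- outer(outer(exp(-(cryoPXCT:::fftFreq(32) * 8)^2),
                      exp(-(cryoPXCT:::fftFreq(32) * 8)^2)),
                exp(-(cryoPXCT:::fftFreq(32) * 8)^2))
    sig <- Re(stats::fft(stats::fft(sig) * lp, inverse = TRUE)) / 32^3
    sig <- sig / stats::sd(sig)
    list(a = sig + array(rnorm(32^3, 0, sigma), c(32, 32, 32)),
         b = sig + array(rnorm(32^3, 0, sigma), c(32, 32, 32)))
  }
  lo <- mk(0.5); hi <- mk(2.5)
  rLo <- resolutionNm(fourierShellCorrelation(lo$a, lo$b, 10))
  rHi <- resolutionNm(fourierShellCorrelation(hi$a, hi$b, 10))
  expect_gte(rLo, 20)          # Nyquist floor: 2 voxels
  expect_gt(rHi, rLo)          # noisier halves resolve worse
})

test_that("dose follows the closed form and the reported MGy figures", {
  expect_equal(estimateDose(1e7, 6.2, 451e-6, 1000, 0), 0)
  perProj <- estimateDose(1e7, 6.2, 451e-6, 1000, 1)
  expect_equal(perProj, 22.0e3, tolerance = 0.01)
  # linear in fluence and projection count
  set.seed(13)
  k <- runif(1, 0.5, 4)
  expect_equal(estimateDose(k * 1e7, 6.2, 451e-6, 1000, 100),
               k * estimateDose(1e7, 6.2, 451e-6, 1000, 100))
  expect_equal(estimateDose(1e7, 6.2, 451e-6, 1000, 300) * 2,
               estimateDose(1e7, 6.2, 451e-6, 1000, 600))
})

test_that("density-band segmentation separates disjoint features", {
  vol <- array(0.40, c(24, 24, 24))
  mk <- function(c0, r) {
    idx <- as.matrix(expand.grid(1:24, 1:24, 1:24))
    which(sqrt(rowSums(sweep(idx, 2, c0)^2)) <= r)
  }
  vol[mk(c(7, 7, 7), 3)] <- 0.31
  vol[mk(c(17, 17, 17), 4)] <- 0.45
  bands <- data.frame(name = c("low", "high"),
                      lower = c(0.28, 0.43), upper = c(0.34, 0.47))
  seg <- segmentDensityBands(vol, bands)
  expect_equal(nrow(seg$components), 2)
  low <- seg$components[seg$components$band == "low", ]
  expect_equal(c(low$y, low$x, low$z), c(7, 7, 7), tolerance = 0.05)
  # a min-size filter larger than any component empties the labelling
  segEmpty <- segmentDensityBands(vol, bands, minVoxels = 1e6)
  expect_equal(nrow(segEmpty$components), 0)
  expect_true(all(segEmpty$labels == 0))
  bad <- data.frame(name = c("a", "b"), lower = c(0.1, 0.2), upper = c(0.3, 0.4))
  expect_error(segmentDensityBands(vol, bad), "overlap")
})

test_that("equivalent-sphere diameters recover a voxelized sphere", {
  vol <- array(0, c(28, 28, 28))
  idx <- as.matrix(expand.grid(1:28, 1:28, 1:28))
  vol[which(sqrt(rowSums(sweep(idx, 2, c(14, 14, 14))^2)) <= 10)] <- 1
  bands <- data.frame(name = "s", lower = 0.5, upper = 1.5)
  seg <- segmentDensityBands(vol, bands)
  st <- featureSizeStats(seg, voxelSizeNm = 1000)
  expect_equal(st$n, 1L)
  expect_equal(st$meanDiameterUm, 20 / 1000 * 1000, tolerance = 0.05)
  empty <- featureSizeStats(list(components = seg$components[0, ]), 1000)
  expect_equal(nrow(empty), 0)
})

test_that("depth-of-field advisory follows 5.2 r^2 / lambda", {
  d1 <- depthOfFieldCheck(50, 2e-10, 100e-6)
  expect_equal(d1$dofM, 65e-6, tolerance = 1e-6)
  expect_true(d1$flag)
  d2 <- depthOfFieldCheck(100, 2e-10, 10e-6)
  expect_equal(d2$dofM, 260e-6, tolerance = 1e-6)
  expect_false(d2$flag)
  expect_false(depthOfFieldCheck(1e6, 2e-10, 100e-6)$flag)
})

test_that("segmentation of the phantom's own labels recovers vacuole sizes", {
  ph <- defaultPhantom()
  lab <- phantomLabelTable()
  vac <- array(as.numeric(featureLabels(ph) %in%
                            c(lab[["vacuole_lipid"]], lab[["vacuole_pigment"]])),
               dim(featureLabels(ph)))
  seg <- segmentDensityBands(vac, data.frame(name = "vacuole", lower = 0.5,
                                             upper = 1.5), minVoxels = 100L)
  st <- featureSizeStats(seg, voxelSize(ph))
  truth <- ph@features[ph@features$type == "vacuole", ]
  expect_equal(st$n, nrow(truth))
  expect_equal(st$meanDiameterUm,
               mean(2 * truth$sizePx) * voxelSize(ph) / 1000,
               tolerance = 0.05)
})
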