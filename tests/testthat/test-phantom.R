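test_that("featureless spec yields a uniform medium block", {
  sp <- phantomSpec(gridDim = c(12L, 32L, 32L), voxelSizeNm = 200,
                    nAxons = 0L, nCells = 0L, nVacuoles = 0L)
  ph <- buildPhantom(sp, seed = 1)
  lab <- phantomLabelTable()
  expect_setequal(unique(as.vector(featureLabels(ph))),
                  c(lab[["air"]], lab[["medium"]]))
  expect_true(all(electronDensity(ph)[featureLabels(ph) == lab[["medium"]]] == 0.40))
  expect_true(all(electronDensity(ph)[featureLabels(ph) == lab[["air"]]] == 0))
})

test_that("generation is deterministic for a fixed seed", {
  sp <- phantomSpec(gridDim = c(24L, 48L, 48L), voxelSizeNm = 400,
                    nAxons = 2L, nCells = 1L, nVacuoles = 1L,
                    cellRadiusUm = 4, nucleusSemiAxesUm = c(2, 2.6, 2),
                    vacuoleDiameterUm = 4, axonOuterRadiusUm = c(1.5, 2.2),
                    sheathThicknessUm = c(0.5, 0.9))
  a <- buildPhantom(sp, seed = 42)
  b <- buildPhantom(sp, seed = 42)
  expect_identical(electronDensity(a), electronDensity(b))
  expect_identical(featureLabels(a), featureLabels(b))
  c <- buildPhantom(sp, seed = 43)
  expect_false(identical(featureLabels(a), featureLabels(c)))
})

test_that("default phantom honours the observed density orderings", {
  ph <- defaultPhantom()
  lab <- phantomLabelTable()
  med <- vapply(names(lab)[-1], function(cl)
    stats::median(electronDensity(ph)[featureLabels(ph) == lab[[cl]]]),
    numeric(1))
  expect_lt(med[["vacuole_lipid"]], med[["myelin"]])
  expect_lt(med[["myelin"]], med[["medium"]])
  expect_lt(med[["nucleus"]], med[["cytoplasm"]])
  expect_true(all(electronDensity(ph) >= 0))
})

test_that("oversized features are rejected with a sizing error", {
  sp <- phantomSpec(gridDim = c(16L, 48L, 48L), nCells = 1L,
                    cellRadiusUm = 6)  # 30 px radius in a 48 px support
  expect_error(buildPhantom(sp, seed = 1), "exceeds|fit")
})

test_that("delta/beta conversion matches the closed form and is linear", {
  lam <- wavelengthM(6.20)
  db <- deltaBetaFromElectronDensity(0.3344, lam)
  expect_equal(db$delta, 6.0e-6, tolerance = 1e-3)
  expect_equal(db$beta, 0.005 * db$delta)
  expect_equal(deltaBetaFromElectronDensity(0, lam)$delta, 0)
  set.seed(1)
  ne <- runif(20, 0, 0.5)
  k <- runif(1, 0.5, 3)
  expect_equal(deltaBetaFromElectronDensity(k * ne, lam)$delta,
               k * deltaBetaFromElectronDensity(ne, lam)$delta)
  expect_error(deltaBetaFromElectronDensity(-0.1, lam), "nonnegative")
})

test_that("mass density conversion uses the 1.86 g/mol ratio", {
  expect_equal(massDensityFromElectronDensity(0), 0)
  expect_equal(massDensityFromElectronDensity(0.3344), 1.033, tolerance = 1e-3)
  expect_equal(massDensityFromElectronDensity(0.40), 1.235, tolerance = 1e-3)
  set.seed(2)
  ne <- runif(10, 0, 1)
  expect_equal(massDensityFromElectronDensity(2 * ne),
               2 * massDensityFromElectronDensity(ne))
})

test_that("projection of a uniform cylinder matches the chord formula", {
  sp <- phantomSpec(gridDim = c(8L, 64L, 64L), voxelSizeNm = 200,
                    nAxons = 0L, nCells = 0L, nVacuoles = 0L,
                    supportRadiusFrac = 0.4)
  ph <- buildPhantom(sp, seed = 1)
  lam <- wavelengthM(6.2)
  pr <- groundTruthProjection(ph, 0, lam)
  phi <- phaseImage(pr)[4, ]
  R <- 0.4 * 64
  delta0 <- deltaBetaFromElectronDensity(0.40, lam)$delta
  x <- seq_len(64) - (64 + 1) / 2
  chord <- ifelse(abs(x) < R, 2 * sqrt(pmax(R^2 - x^2, 0)), 0)
  expected <- -(2 * pi / lam) * delta0 * chord * 200e-9
  inner <- abs(x) < 0.8 * R
  expect_lt(max(abs(phi[inner] - expected[inner]) / max(abs(expected))), 0.02)
  # maximal (most negative) on the axis (ties possible on an even grid)
  expect_lte(abs(which.min(phi) - (64 + 1) / 2), 2)
})

test_that("empty phantom projects to unit transmission", {
  dens <- defaultDensityTable(); dens[] <- 0
  sp <- phantomSpec(gridDim = c(6L, 24L, 24L), nAxons = 0L, nCells = 0L,
                    nVacuoles = 0L, densities = dens)
  ph <- buildPhantom(sp, seed = 1)
  pr <- groundTruthProjection(ph, 30, wavelengthM(6.2))
  expect_equal(pr@transmission, matrix(1 + 0i, 6, 24), tolerance = 1e-12)
})

test_that("projected mass is conserved across angles", {
  ph <- defaultPhantom()
  lam <- wavelengthM(6.2)
  db <- deltaBetaFromElectronDensity(electronDensity(ph), lam)
  tots <- vapply(c(0, 17.3, 45, 90, 133.7, 179),
                 function(a) sum(cryoPXCT:::projectVolumeY(db$delta, a)),
                 numeric(1))
  expect_lt(diff(range(tots)) / mean(tots), 1e-3)
})

test_that("rotation by 180 degrees mirrors the volume", {
  ph <- defaultPhantom()
  vol <- electronDensity(ph)
  rot <- cryoPXCT:::rotateVolumeY(vol, 180)
  mir <- vol[, rev(seq_len(dim(vol)[2])), rev(seq_len(dim(vol)[3]))]
  expect_lt(mean(abs(rot - mir)), 1e-6 * max(vol))
})

test_that("passive sample: |T| <= 1 everywhere", {
  ph <- defaultPhantom()
  pr <- groundTruthProjection(ph, 63.4, wavelengthM(6.2))
  expect_true(all(amplitudeImage(pr) <= 1 + 1e-12))
})
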