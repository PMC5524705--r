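test_that("Fermat spiral starts at the origin and fills area uniformly", {
  sc <- fermatSpiral(c(20e-6, 20e-6), 2.2e-6)
  pos <- scanPositions(sc)
  expect_equal(pos[1, ], c(x = 0, y = 0))
  # point count ~ area / step^2 = 82.6
  expect_lt(abs(nrow(pos) - 400 / 2.2^2) / (400 / 2.2^2), 0.10)
  # nearest-neighbour statistics: mean near the step, low dispersion
  nn <- vapply(seq_len(nrow(pos)), function(i) {
    d <- sqrt(rowSums((pos[-i, , drop = FALSE] -
                       matrix(pos[i, ], nrow(pos) - 1, 2, byrow = TRUE))^2))
    min(d)
  }, numeric(1))
  expect_lt(abs(mean(nn) - 2.2e-6) / 2.2e-6, 0.15)
  expect_lt(stats::sd(nn) / mean(nn), 0.3)
})

test_that("Fermat spiral is scale invariant", {
  a <- fermatSpiral(c(20e-6, 12e-6), 2.2e-6)
  b <- fermatSpiral(c(40e-6, 24e-6), 4.4e-6)
  expect_equal(nrow(scanPositions(a)), nrow(scanPositions(b)))
  expect_equal(scanPositions(b), scanPositions(a) * 2)
})

test_that("a step larger than the field of view is rejected", {
  expect_error(fermatSpiral(c(5e-6, 5e-6), 6e-6), "overlap")
})

test_that("probe is normalized and has the configured support", {
  opt <- opticsConfig(6.2, 4.8006, 75e-6, 64L, 6.2e-6, 1e7)
  pr <- makeProbe(opt, totalPhotons = 3.7e5)
  expect_equal(sum(Mod(probeField(pr))^2), 3.7e5, tolerance = 1e-10)
  # full width at 10% of max intensity within 20% of the nominal diameter
  inten <- Mod(probeField(pr))^2
  prof <- inten[33, ]
  wpx <- sum(prof > 0.1 * max(prof))
  wm <- wpx * cryoPXCT:::pixelSizeM(opt)
  expect_lt(abs(wm - 6.2e-6) / 6.2e-6, 0.2)
})

test_that("zero defocus gives a real nonnegative field", {
  opt <- testOptics32()
  pr <- makeProbe(opt, 1, defocusRad = 0)
  expect_true(all(Im(probeField(pr)) == 0))
  expect_true(all(Re(probeField(pr)) >= 0))
})

test_that("oversized or undersized probes are rejected", {
  p <- 400e-9
  expect_error(makeProbe(opticsConfig(6.2, p * 32 * 75e-6 / wavelengthM(6.2),
                                      75e-6, 32L, 40 * p, 1e7)), "grid")
  expect_error(makeProbe(opticsConfig(6.2, p * 32 * 75e-6 / wavelengthM(6.2),
                                      75e-6, 32L, 2 * p, 1e7)), "4 pixels")
})

test_that("empty object: frames equal the probe's diffraction, energy conserved", {
  sc <- ptychoScene()
  obj1 <- matrix(1 + 0i, 96, 96)
  dd <- simulateDiffraction(obj1, sc$probe, sc$scan, snapToGrid = TRUE)
  ref <- Mod(stats::fft(probeField(sc$probe)))^2 / (32 * 32)
  for (j in c(1, 5, nrow(dd@winTopLeft)))
    expect_equal(dd@frames[, , j], ref, tolerance = 1e-10)
  expect_equal(sum(dd@frames[, , 1]), 1e6, tolerance = 1e-8)
})

test_that("passivity: counts never exceed the photon budget", {
  sc <- ptychoScene()
  tot <- apply(sc$data@frames, 3, sum)
  expect_true(all(tot <= 1e6 * (1 + 1e-9)))
})

test_that("Poisson noise has the right variance and is seeded", {
  sc <- ptychoScene()
  # small photon budget so relative fluctuations are visible
  probe <- makeProbe(sc$optics, totalPhotons = 1e4, defocusRad = 2)
  clean <- simulateDiffraction(sc$object, probe, sc$scan, noise = FALSE,
                               snapToGrid = TRUE)
  noisy <- simulateDiffraction(sc$object, probe, sc$scan, noise = TRUE,
                               seed = 5, snapToGrid = TRUE)
  noisy2 <- simulateDiffraction(sc$object, probe, sc$scan, noise = TRUE,
                                seed = 5, snapToGrid = TRUE)
  expect_identical(noisy@frames, noisy2@frames)
  lam <- clean@frames
  big <- lam > 1      # avoid tiny-rate cells in the normalized statistic
  chi2 <- mean((noisy@frames[big] - lam[big])^2 / lam[big])
  expect_lt(abs(chi2 - 1), 0.1)
  expect_true(all(noisy@frames == round(noisy@frames)))
})

test_that("scan positions outside the object grid are rejected", {
  sc <- ptychoScene()
  wide <- fermatSpiral(c(200 * 400e-9, 200 * 400e-9), 20 * 400e-9)
  expect_error(simulateDiffraction(sc$object, sc$probe, wide), "leaves")
})
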