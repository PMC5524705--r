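test_that("the truth is a fixed point of the difference map", {
  sc <- ptychoScene()
  r <- dmReconstruct(sc$data, nIter = 1, objectInit = sc$object,
                     probeInit = sc$probe)
  expect_lt(utils::tail(errorHistory(r), 1), 1e-10)
})

test_that("difference map converges on noiseless data", {
  sc <- ptychoScene()
  r <- dmReconstruct(sc$data, nIter = 200, probeInit = sc$probe)
  expect_lt(utils::tail(errorHistory(r), 1), 1e-2)
  expect_lt(phaseRmse(objectTransmission(r), sc$object, sc$covered), 0.02)
  # retrieved probe power within 5% of the simulated budget
  expect_lt(abs(sum(Mod(probeField(r))^2) / 1e6 - 1), 0.05)
})

test_that("reconstruction is deterministic", {
  sc <- ptychoScene()
  a <- dmReconstruct(sc$data, nIter = 40, probeInit = sc$probe)
  b <- dmReconstruct(sc$data, nIter = 40, probeInit = sc$probe)
  expect_identical(errorHistory(a), errorHistory(b))
  expect_identical(objectTransmission(a), objectTransmission(b))
})

test_that("degenerate frames are rejected", {
  sc <- ptychoScene()
  bad <- sc$data
  bad@frames[] <- 0
  expect_error(dmReconstruct(bad, nIter = 1, probeInit = sc$probe), "zero")
  nf <- sc$data
  nf@frames[1] <- NaN
  expect_error(dmReconstruct(nf, nIter = 1, probeInit = sc$probe),
               "non-finite")
})

test_that("maximum likelihood is stationary at the noiseless truth", {
  sc <- ptychoScene()
  init <- new("PtychoResult", object = sc$object, probe = probeField(sc$probe),
              errorHistory = 0, likelihoodHistory = numeric(),
              iterationsRun = c(dm = 0L, ml = 0L), mlFlag = 0L)
  r <- mlRefine(init, sc$data, nIter = 5, gradTol = 1e-8)
  # the state does not move: at most round-off scale drift of object and L
  expect_lte(r@iterationsRun[["ml"]], 1L)
  # movement is negligible at reconstruction scale (the regularized
  # optimum sits within ~1e-3 of the exact truth)
  expect_lt(max(Mod(objectTransmission(r) - sc$object)), 2e-3)
  L <- r@likelihoodHistory
  expect_lt(abs(utils::tail(L, 1) - L[1]), 1e-9 * abs(L[1]))
})

test_that("maximum likelihood monotonically decreases the Poisson objective", {
  scn <- cachedScene("noisyScene", ptychoScene(noise = TRUE, seed = 3))
  dm <- cachedScene("noisyDm",
                    dmReconstruct(scn$data, nIter = 150, probeInit = scn$probe))
  ml <- cachedScene("noisyMl", mlRefine(dm, scn$data, nIter = 30))
  L <- ml@likelihoodHistory
  expect_gt(length(L), 2)
  expect_true(all(diff(L) <= 1e-9 * abs(L[1])))
  expect_identical(ml@mlFlag, 0L)
  # refinement does not degrade the object
  rDm <- phaseRmse(objectTransmission(dm), scn$object, scn$covered)
  rMl <- phaseRmse(objectTransmission(ml), scn$object, scn$covered)
  expect_lte(rMl, rDm * 1.02)
})

test_that("the likelihood regularizer is not load-bearing", {
  scn <- cachedScene("noisyScene", ptychoScene(noise = TRUE, seed = 3))
  dm <- cachedScene("noisyDm",
                    dmReconstruct(scn$data, nIter = 150, probeInit = scn$probe))
  l1 <- utils::tail(mlRefine(dm, scn$data, nIter = 10,
                             epsRel = 1e-8)@likelihoodHistory, 1)
  l2 <- utils::tail(mlRefine(dm, scn$data, nIter = 10,
                             epsRel = 2e-8)@likelihoodHistory, 1)
  expect_lt(abs(l1 - l2) / abs(l1), 1e-3)
})

test_that("Fourier error is zero for exact data and one for a zero object", {
  sc <- ptychoScene()
  expect_lt(fourierError(sc$object, sc$probe, sc$data), 1e-12)
  zero <- matrix(0i, 96, 96)
  expect_equal(fourierError(zero, sc$probe, sc$data), 1)
})

test_that("ambiguity removal cancels a global offset and linear ramp", {
  sc <- ptychoScene()
  rows <- matrix(seq_len(96), 96, 96)
  cols <- t(rows)
  warped <- sc$object * exp(1i * (0.7 + 0.02 * rows - 0.013 * cols))
  fixed <- removePhaseAmbiguity(warped, sc$object)
  expect_lt(sqrt(mean(Arg(fixed * Conj(sc$object))^2)), 1e-6)
})

test_that("continuous scan positions reconstruct via fractional probe shifts", {
  p <- 400e-9
  opt <- testOptics32(probePx = 16)
  probe <- makeProbe(opt, totalPhotons = 1e6, defocusRad = 2)
  obj <- smoothTestObject(96, 96, seed = 15)
  scan <- fermatSpiral(c(48 * p, 48 * p), 7 * p)
  data <- simulateDiffraction(obj, probe, scan)   # no grid snapping
  expect_gt(max(abs(data@frac)), 0.05)            # genuinely sub-pixel
  rec <- dmReconstruct(data, nIter = 150, probeInit = probe)
  rec <- mlRefine(rec, data, nIter = 15)
  illum <- matrix(0, 96, 96)
  pw <- Mod(probeField(probe))^2
  for (j in seq_len(nrow(data@winTopLeft))) {
    r <- data@winTopLeft[j, 1]; c <- data@winTopLeft[j, 2]
    illum[r:(r + 31), c:(c + 31)] <- illum[r:(r + 31), c:(c + 31)] + pw
  }
  covered <- illum > 0.1 * max(illum)
  expect_lt(phaseRmse(objectTransmission(rec), obj, covered), 0.02)
})
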