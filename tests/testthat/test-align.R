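test_that("ramp removal zeroes a pure plane and is idempotent", {
  rows <- matrix(seq_len(40), 40, 60)
  cols <- matrix(seq_len(60), 40, 60, byrow = TRUE)
  plane <- 0.3 + 0.02 * rows - 0.011 * cols
  air <- matrix(FALSE, 40, 60)
  air[, c(1:8, 53:60)] <- TRUE
  out <- removeRamp(plane, air)
  expect_lt(max(abs(out)), 1e-9)
  # inject a ramp on structured content; air region must return to zero
  set.seed(1)
  img <- matrix(0, 40, 60)
  img[10:30, 20:40] <- -1.5
  rec <- removeRamp(img + 0.01 * cols, air)
  expect_lt(sqrt(mean((rec - img)[air]^2)), 1e-6)
  expect_equal(removeRamp(rec, air), rec, tolerance = 1e-10)
})

test_that("phase derivative is wrap-safe", {
  H <- 8; W <- 32
  expect_equal(phaseDerivative(matrix(exp(1i * 0.7), H, W)),
               matrix(0, H, W))
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  lin <- exp(1i * 0.1 * cols)
  d <- phaseDerivative(lin)
  expect_equal(d[, -W], matrix(0.1, H, W - 1), tolerance = 1e-12)
  # a 2-pi step between pixels is invisible to the wrapped difference
  step <- exp(1i * 2 * pi * (cols >= W / 2))
  expect_equal(phaseDerivative(step), matrix(0, H, W), tolerance = 1e-12)
  # wrapping in the underlying phase does not corrupt the derivative
  big <- exp(1i * 0.5 * cols)   # phase spans 16 rad
  expect_equal(phaseDerivative(big)[, -W], matrix(0.5, H, W - 1),
               tolerance = 1e-12)
})

test_that("vertical alignment recovers injected shifts to sub-pixel accuracy", {
  ps <- phantomSinogram(48L)
  nA <- length(ps$angles)
  va0 <- verticalAlign(ps$stack)
  expect_lt(max(abs(va0$shifts)), 0.02)
  set.seed(4)
  dy <- runif(nA, -3, 3); dy <- dy - mean(dy)
  shifted <- ps$stack
  for (a in seq_len(nA))
    shifted[, , a] <- applyImageShift(ps$stack[, , a], dy[a], 0)
  va <- verticalAlign(shifted)
  expect_lt(sqrt(mean((va$shifts - dy)^2)), 0.1)
  # gauge: adding a constant leaves the zero-mean estimate unchanged
  shifted2 <- ps$stack
  for (a in seq_len(nA))
    shifted2[, , a] <- applyImageShift(ps$stack[, , a], dy[a] + 1.5, 0)
  va2 <- verticalAlign(shifted2)
  expect_lt(sqrt(mean((va2$shifts - va$shifts)^2)), 0.05)
})

test_that("centre-of-mass prealignment sees the rotation-centre offset", {
  ps <- phantomSinogram(48L)
  pre0 <- comPrealign(ps$stack, ps$angles)
  expect_lt(pre0$amplitude, 1.0)   # phantom is built around the axis
  # displace the sample: COM follows A cos(theta + phi0) with A = 5 px
  nA <- length(ps$angles)
  th <- ps$angles * pi / 180
  shifted <- ps$stack
  for (a in seq_len(nA))
    shifted[, , a] <- applyImageShift(ps$stack[, , a], 0, 5 * cos(th[a]))
  pre <- comPrealign(shifted, ps$angles)
  # the fitted sinusoid absorbs the injected 5 cos(theta) displacement
  delta <- pre$fitted - pre0$fitted
  fit <- stats::lm.fit(cbind(1, cos(th), sin(th)), delta)$coefficients
  expect_equal(sqrt(fit[[2]]^2 + fit[[3]]^2), 5, tolerance = 0.1)
  # residual shifts exclude the consistent sinusoid
  expect_lt(stats::sd(pre$shifts - pre0$shifts), 0.2)
})

test_that("tomographic consistency recovers inconsistent shifts", {
  ps <- phantomSinogram(48L)
  nA <- length(ps$angles)
  ca0 <- consistencyAlign(ps$stack, ps$angles, nOuter = 2L)
  expect_true(ca0$converged)
  expect_lt(max(abs(ca0$shifts)), 0.05)
  set.seed(5)
  dx <- runif(nA, -4, 4); dx <- dx - mean(dx)
  shifted <- ps$stack
  for (a in seq_len(nA))
    shifted[, , a] <- applyImageShift(ps$stack[, , a], 0, dx[a])
  pre <- comPrealign(shifted, ps$angles)
  ca <- consistencyAlign(shifted, ps$angles, shiftsInit = pre$shifts)
  err <- ca$shifts - dx
  X <- cbind(1, cos(ps$angles * pi / 180), sin(ps$angles * pi / 180))
  resid <- err - X %*% qr.solve(X, err)
  expect_lt(sqrt(mean(resid^2)), 0.1)
  # reconstruction from the recovered alignment is as good as never
  # misaligned, once the unobservable rigid gauge of the recovered shifts
  # is pinned to that of the injected field
  lam <- ps$wavelengthM
  gauge <- X %*% qr.solve(X, err)
  corr <- shifted
  for (a in seq_len(nA))
    corr[, , a] <- applyImageShift(shifted[, , a], 0,
                                   -(ca$shifts[a] - gauge[a]))
  tomRef <- derivativeFBP(ps$stack, angles = ps$angles,
                          pixelSizeNm = ps$pixelSizeNm, wavelengthM = lam)
  tomRec <- derivativeFBP(corr, angles = ps$angles,
                          pixelSizeNm = ps$pixelSizeNm, wavelengthM = lam)
  truthNe <- electronDensity(ps$phantom)
  d <- dim(truthNe); W2 <- dim(ps$stack)[2]
  sel <- ((W2 - d[2]) %/% 2 + 1):((W2 - d[2]) %/% 2 + d[2])
  rmseOf <- function(t) {
    ne <- electronDensity(t)[, sel, sel]
    sup <- array(rep(ps$phantom@supportMask, each = d[1]), d)
    sqrt(mean((ne - truthNe)[sup]^2))
  }
  expect_lt(rmseOf(tomRec), rmseOf(tomRef) * 1.10)
})

test_that("amplitude-corrupted projections are flagged exactly", {
  ps <- phantomSinogram(48L)
  nA <- length(ps$angles)
  d <- dim(electronDensity(ps$phantom))
  W2 <- dim(ps$stack)[2]
  lam <- ps$wavelengthM
  amp <- array(1, c(d[1], W2, nA))
  c0 <- (W2 - d[2]) %/% 2
  for (a in seq_len(nA)) {
    pr <- groundTruthProjection(ps$phantom, ps$angles[a], lam)
    amp[, c0 + seq_len(d[2]), a] <- amplitudeImage(pr)
  }
  colD <- abs(seq_len(W2) - (W2 + 1) / 2)
  sup <- matrix(rep(colD <= 53, each = d[1]), d[1], W2)
  expect_length(flagBadProjections(amp, sup, k = 5), 0)
  set.seed(6)
  bad <- sort(sample(nA, 3))
  for (b in bad) {
    cs <- sample(30:100, 1)
    amp[, cs:(cs + 9), b] <- amp[, cs:(cs + 9), b] * 0.5
  }
  expect_identical(flagBadProjections(amp, sup, k = 5), bad)
  expect_length(flagBadProjections(amp, sup, k = 1e9), 0)
})

test_that("angular weights cover uneven gaps and stay normalized", {
  eq <- angularWeights((0:89) * 2)
  expect_equal(eq, rep(1, 90))
  ang <- ((0:89) * 2)[-31]
  w <- angularWeights(ang)
  expect_equal(sum(w), 89)
  expect_equal(w[30] / w[1], 1.5)
  expect_equal(w[31] / w[1], 1.5)
  expect_equal(unique(round(w[-c(30, 31)] / w[1], 10)), 1)
  expect_error(angularWeights(c(0, 10, 10, 20)), "duplicate")
  set.seed(7)
  ang2 <- sort(runif(25, 0, 179))
  expect_equal(sum(angularWeights(ang2)), 25)
})
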