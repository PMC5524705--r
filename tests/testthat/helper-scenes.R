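# Shared fixtures, built lazily and cached for the whole test run.

.sceneCache <- new.env(parent = emptyenv())

cachedScene <- function(name, expr) {
  if (!exists(name, envir = .sceneCache)) {
    assign(name, force(expr), envir = .sceneCache)
  }
  get(name, envir = .sceneCache)
}

# small acquisition geometry: 32-px frames, 400 nm pixels
testOptics32 <- function(probePx = 16) {
  p <- 400e-9
  opticsConfig(6.2, p * 32 * 75e-6 / wavelengthM(6.2), 75e-6, 32L,
               probePx * p, 1e7)
}

# smooth complex test object: band-limited random phase, mild absorption
smoothTestObject <- function(H, W, seed = 7, phaseMax = 1.2) {
  set.seed(seed)
  ph <- matrix(stats::rnorm(H * W), H, W)
  lp <- outer(exp(-(cryoPXCT:::fftFreq(H) * 18)^2),
              exp(-(cryoPXCT:::fftFreq(W) * 18)^2))
  ph <- Re(stats::fft(stats::fft(ph) * lp, inverse = TRUE)) / length(ph)
  ph <- ph / max(abs(ph)) * phaseMax
  amp <- 1 - 0.1 * (ph - min(ph)) / diff(range(ph))
  amp * exp(1i * ph)
}

# ptychography scene with good overlap (~57 positions, 32-px frames)
ptychoScene <- function(noise = FALSE, seed = 3, nPosScale = 1) {
  p <- 400e-9
  opt <- testOptics32(probePx = 16)
  probe <- makeProbe(opt, totalPhotons = 1e6, defocusRad = 2)
  obj <- smoothTestObject(96, 96)
  scan <- fermatSpiral(c(52 * p, 52 * p) * sqrt(nPosScale), 7 * p)
  data <- simulateDiffraction(obj, probe, scan, noise = noise, seed = seed,
                              snapToGrid = TRUE)
  # illumination-weighted coverage mask for comparisons
  illum <- matrix(0, 96, 96)
  pw <- Mod(probeField(probe))^2
  for (j in seq_len(nrow(data@winTopLeft))) {
    r <- data@winTopLeft[j, 1]; c <- data@winTopLeft[j, 2]
    illum[r:(r + 31), c:(c + 31)] <- illum[r:(r + 31), c:(c + 31)] + pw
  }
  list(optics = opt, probe = probe, object = obj, scan = scan, data = data,
       covered = illum > 0.1 * max(illum))
}

phaseRmse <- function(rec, truth, mask) {
  cor <- removePhaseAmbiguity(rec, truth, mask)
  sqrt(mean((Arg(cor * Conj(truth))[mask])^2))
}

# default phantom (the generator's own study conditions), seed 1
defaultPhantom <- function() {
  cachedScene("phantom", buildPhantom(phantomSpec(), seed = 1))
}

# derivative sinogram of the default phantom on a 144-px window
phantomSinogram <- function(nAngles = 90L) {
  key <- paste0("sino", nAngles)
  cachedScene(key, {
    ph <- defaultPhantom()
    lam <- wavelengthM(6.2)
    d <- dim(electronDensity(ph))
    W2 <- 144L
    angles <- (seq_len(nAngles) - 1) * 180 / nAngles
    st <- array(0, c(d[1], W2, nAngles))
    c0 <- (W2 - d[2]) %/% 2
    for (a in seq_len(nAngles)) {
      pr <- groundTruthProjection(ph, angles[a], lam)
      tr <- matrix(1 + 0i, d[1], W2)
      tr[, c0 + seq_len(d[2])] <- pr@transmission
      st[, , a] <- phaseDerivative(tr)
    }
    list(stack = st, angles = angles, phantom = ph, wavelengthM = lam,
         pixelSizeNm = voxelSize(ph))
  })
}

# area-averaged analytic disc sinogram (phase-derivative domain)
cylinderSinogram <- function(W = 96L, H = 2L, R = 30, delta0 = 6e-6,
                             x0 = 4.5, z0 = -7.2, nAngles = 90L,
                             voxNm = 200, supersample = 8L) {
  lam <- wavelengthM(6.2)
  angles <- (seq_len(nAngles) - 1) * 180 / nAngles
  ctr <- (W + 1) / 2
  ss <- supersample
  sino <- array(0, c(H, W, nAngles))
  for (a in seq_len(nAngles)) {
    th <- angles[a] * pi / 180
    t0 <- x0 * cos(th) + z0 * sin(th)
    xf <- rep(seq_len(W), each = ss) +
      (rep(seq_len(ss), W) - (ss + 1) / 2) / ss - ctr - t0
    chordf <- ifelse(abs(xf) < R, 2 * sqrt(pmax(R^2 - xf^2, 0)), 0)
    chord <- colMeans(matrix(chordf, ss, W))
    phi <- -(2 * pi / lam) * delta0 * chord * voxNm * 1e-9
    sino[, , a] <- matrix(rep(c(diff(phi), 0), each = H), H, W)
  }
  list(sino = sino, angles = angles, wavelengthM = lam, voxNm = voxNm,
       R = R, delta0 = delta0, x0 = x0, z0 = z0, ctr = ctr, W = W)
}

# small noisy end-to-end configuration for resolution-vs-photons checks
miniNoisyConfig <- function(photonsPerFrame, seed = 1L) {
  p <- 400e-9
  # fluence chosen so each exposure carries the requested photon budget
  scanFov <- c(64 * p, 32 * p)
  step <- 9 * p
  nPos <- nrow(scanPositions(fermatSpiral(scanFov, step)))
  fluence <- photonsPerFrame * nPos / (prod(scanFov) * 1e12)
  runConfig(
    name = sprintf("mini-%g", photonsPerFrame),
    optics = list(photonEnergyKeV = 6.2,
                  detectorDistanceM = p * 32 * 75e-6 / wavelengthM(6.2),
                  detectorPixelPitchM = 75e-6, detectorRegionPx = 32L,
                  probeDiameterM = 20 * p, fluencePerProjection = fluence),
    phantom = list(gridDim = c(32L, 64L, 64L), voxelSizeNm = 400,
                   nAxons = 2L, nCells = 1L, nVacuoles = 1L,
                   cellRadiusUm = 4.5, nucleusSemiAxesUm = c(2.2, 2.8, 2.2),
                   vacuoleDiameterUm = 4, axonOuterRadiusUm = c(1.8, 2.6),
                   sheathThicknessUm = c(1.0, 1.4)),
    scan = list(fieldOfViewM = scanFov, stepM = step, snapToGrid = TRUE),
    nAngles = 48L, noise = TRUE,
    solver = list(nIterDm = 60L, nIterMl = 10L),
    align = list(cropWidth = 72L),
    seed = seed)
}

# the full desk-profile end-to-end run (expensive; cached across tests)
deskReport <- function() {
  cachedScene("deskReport", runPipeline(deskProfile(seed = 1), verbose = FALSE))
}
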