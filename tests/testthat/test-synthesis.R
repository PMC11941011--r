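# Narrow-band extraction, SAVE compositing, the Cauchy-Lorentz density and
# the fast-annealing optimizer.

flatCube <- function(level, h = 3, w = 4, wl = spectralGrid()) {
  spectralCube(wl, array(level, c(h, w, length(wl))))
}

test_that("band extraction uses a unit-sum filter and degenerates to a slice", {
  cube <- flatCube(0.37)
  img <- extractBandImage(cube, 540, 30)
  expect_equal(img, matrix(0.37, 3, 4), tolerance = 1e-12)

  # fwhm at or below the grid step: nearest-band slice
  set.seed(9)
  wl <- spectralGrid()
  vals <- array(runif(2 * 2 * length(wl)), c(2, 2, length(wl)))
  cube2 <- spectralCube(wl, vals)
  expect_equal(extractBandImage(cube2, 600.3, 0.5), vals[, , wl == 600])

  # brute-force per-pixel weighted-sum oracle
  sd <- 30 / (2 * sqrt(2 * log(2)))
  g <- exp(-0.5 * ((wl - 540) / sd)^2); g <- g / sum(g)
  want <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) want[i, j] <- sum(vals[i, j, ] * g)
  expect_equal(extractBandImage(cube2, 540, 30), want, tolerance = 1e-12)

  expect_error(extractBandImage(cube2, 300, 30), "outside")

  # extraction commutes with spatial cropping
  crop <- function(m) m[1:2, 1:2]
  cube3 <- spectralCube(wl, array(runif(4 * 4 * length(wl)), c(4, 4, length(wl))))
  cropped <- spectralCube(wl, cubeValues(cube3)[1:2, 1:2, , drop = FALSE])
  expect_equal(extractBandImage(cropped, 415, 30),
               crop(extractBandImage(cube3, 415, 30)), tolerance = 1e-12)
})

test_that("SAVE compositing follows the display mapping and is homogeneous", {
  # spectrally flat cube + channel-balanced weights -> gray image
  balanced <- bandSet(c(415, 540), c(30, 30), c(1, 1), list(c("B", "G"), "R"))
  img <- synthesizeSaveImage(flatCube(0.42), balanced)
  expect_equal(img[, , 1], img[, , 2], tolerance = 1e-12)
  expect_equal(img[, , 2], img[, , 3], tolerance = 1e-12)
  expect_equal(img[1, 1, 1], 0.42, tolerance = 1e-12)

  # zero reflectance around 415 nm: blue and green vanish, red unaffected
  wl <- spectralGrid()
  v <- rep(0.5, length(wl)); v[wl <= 470] <- 0
  cube <- spectralCube(wl, array(rep(v, each = 4), c(2, 2, length(wl))))
  img2 <- synthesizeSaveImage(cube, balanced)
  expect_lt(max(img2[, , 2:3]), 1e-4)
  expect_equal(img2[1, 1, 1], 0.5, tolerance = 1e-3)

  # positive homogeneity before clipping
  set.seed(13)
  cube3 <- spectralCube(wl, array(runif(4 * length(wl), 0, 0.5),
                                  c(2, 2, length(wl))))
  b1 <- defaultBandSet()
  b2 <- b1; bandWeights(b2) <- 2 * bandWeights(b1)
  expect_equal(synthesizeSaveImage(cube3, b2, clip = FALSE),
               2 * synthesizeSaveImage(cube3, b1, clip = FALSE),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(bandSet(415, 30, 1, list(c("B", "G"))), "every display channel")
})

test_that("SAVE enhances lesion contrast beyond the sRGB rendering", {
  sc <- makeLesionScene(size = 32, lesionRadius = 8, seed = 20240714)
  lum <- function(a) 0.2126729 * a[, , 1] + 0.7151522 * a[, , 2] +
    0.0721750 * a[, , 3]
  # brute-force region-mean Weber contrast
  weber <- function(img, m) abs(mean(img[m]) - mean(img[!m])) / mean(img[!m])
  saveImg <- synthesizeSaveImage(sc$cube)
  wl <- wavelengths(sc$cube)
  flat <- t(matrix(cubeValues(sc$cube), 32 * 32, length(wl)))
  rgb <- xyzToSrgb(spectrumToXYZ(spectra(wl, flat)))
  srgbImg <- array(t(pmin(pmax(rgb, 0), 1)), c(32, 32, 3))
  expect_gt(weber(lum(saveImg), sc$mask), weber(lum(srgbImg), sc$mask))
})

test_that("Cauchy-Lorentz density has the right mode, symmetry and mass", {
  g <- 0.7
  expect_equal(cauchyLorentzPDF(2, 2, g), 1 / (pi * g))
  d <- seq(0.1, 5, by = 0.3)
  expect_equal(cauchyLorentzPDF(2 + d, 2, g), cauchyLorentzPDF(2 - d, 2, g))
  # quadrature oracle: total probability mass
  mass <- stats::integrate(cauchyLorentzPDF, -Inf, Inf, x0 = 0,
                           gamma = g, rel.tol = 1e-8)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  # matches the base Cauchy density
  expect_equal(cauchyLorentzPDF(d, 1, g), dcauchy(d, 1, g), tolerance = 1e-12)
  expect_error(cauchyLorentzPDF(0, 0, -1), "positive")
})

test_that("fast annealing recovers a quadratic minimum and keeps its contracts", {
  # known-minimum recovery averaged over 5 seeds
  err <- vapply(1:5, function(s) {
    res <- fsaOptimize(function(x) (x - 3)^2, 0,
                       fsaParams(maxIter = 2000, seed = s))
    abs(res$par - 3)
  }, numeric(1))
  expect_lt(mean(err), 0.05)

  # constant objective: value unchanged, every proposal accepted
  resC <- fsaOptimize(function(x) 1.5, c(0, 0), fsaParams(maxIter = 200, seed = 2))
  expect_equal(resC$value, 1.5)
  expect_equal(resC$acceptRate, 1)

  # determinism: same seed -> bitwise-identical trace
  r1 <- fsaOptimize(function(x) sum(x^2), c(1, -2), fsaParams(seed = 99, maxIter = 500))
  r2 <- fsaOptimize(function(x) sum(x^2), c(1, -2), fsaParams(seed = 99, maxIter = 500))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$par, r2$par)

  # best-so-far trace is non-increasing
  expect_monotone_nonincreasing(r1$trace)

  # zero temperature reduces to greedy descent: starting at the minimum of a
  # strictly convex objective, no proposal is ever accepted
  rg <- fsaOptimize(function(x) sum(x^2), c(0, 0),
                    fsaParams(initialTemp = 0, maxIter = 300, seed = 7))
  expect_equal(rg$acceptRate, 0)
  expect_equal(rg$par, c(0, 0))

  expect_error(fsaOptimize(function(x) NaN, 0), "finite")
})

test_that("band-weight calibration reaches a self-consistent optimum", {
  rig <- calibrationRig()
  recon <- nonNegative(rig$recon)

  # identifiable 3-band set (disjoint display channels): hidden weights are
  # recovered and the objective matches an independent re-evaluation
  bands3 <- bandSet(c(415, 540, 620), c(30, 30, 25), c(1, 1, 1),
                    list("B", "G", "R"))
  wStar <- c(0.9, 0.6, 0.4)
  hidden <- bands3; bandWeights(hidden) <- wStar
  # self-consistent noiseless target: rendered from the very spectra being
  # composited, so the optimum is exactly recoverable
  target <- savePatchColors(recon, hidden)$xyz
  res <- calibrateBandWeights(recon, target, bands = bands3,
                              params = fsaParams(maxIter = 2000, seed = 11))
  expect_lt(res$meanDeltaE, 0.5)
  wGot <- bandWeights(res$bands)
  expect_lt(max(abs(wGot / (sum(wGot) / sum(wStar)) - wStar) / wStar), 0.10)
  reEval <- meanColorDifference(savePatchColors(recon, res$bands)$xyz, target)
  expect_equal(res$meanDeltaE, as.numeric(reEval), tolerance = 1e-12)

  # an already-optimal initialisation is never made worse
  resOpt <- calibrateBandWeights(recon, savePatchColors(recon, bands3)$xyz,
                                 bands = bands3,
                                 params = fsaParams(maxIter = 300, seed = 3))
  expect_lte(resOpt$meanDeltaE, resOpt$initialDeltaE + 1e-12)

  # degenerate target warns but converges
  expect_warning(
    calibrateBandWeights(recon, matrix(50, 3, 24), bands = bands3,
                         params = fsaParams(maxIter = 50, seed = 5)),
    "degenerate")
})

test_that("linear colour matching aligns exactly under an exact linear map", {
  set.seed(17)
  g <- matrix(runif(72, 10, 90), 3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  t1 <- A %*% g
  res <- matchColorsLinear(g, t1)
  expect_lt(res$meanDeltaE, 1e-8)
  expect_equal(res$A, A, tolerance = 1e-8)
})
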