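# Variable-matrix expansion, pseudoinverse fits, PCA basis and spectral
# reconstruction.

test_that("variable matrix enumerates the complete degree-<=3 monomial basis", {
  # brute-force enumeration oracle: all monomials R^i G^j B^k, 1 <= i+j+k <= 3,
  # plus the constant term
  nMonomials <- sum(vapply(0:3, function(i) sum(vapply(0:3, function(j)
    sum(0:3 + i + j >= 1 & 0:3 + i + j <= 3), numeric(1))), numeric(1)))
  expect_equal(nMonomials + 1, 20)
  expect_length(variableTermLabels(3), 20)
  expect_length(variableTermLabels(2), 10)
  expect_length(variableTermLabels(1), 4)

  v0 <- buildVariableMatrix(c(0, 0, 0), 3)
  expect_equal(unname(v0[, 1]), c(rep(0, 19), 1))
  vr <- buildVariableMatrix(c(1, 0, 0), 3)
  expect_equal(unname(which(vr[, 1] != 0)),
               which(rownames(vr) %in% c("R", "R2", "R3", "const")))
  expect_true(all(vr[vr[, 1] != 0, 1] == 1))

  # first-order rows carry the raw linear RGB; every term matches its label
  set.seed(21)
  rgb <- matrix(runif(30, 0, 1.3), 3)
  v <- buildVariableMatrix(rgb, 3)
  expect_equal(unname(v[c("R", "G", "B"), ]), unname(rgb))
  R <- rgb[1, ]; G <- rgb[2, ]; B <- rgb[3, ]
  expect_equal(v["G2B", ], G^2 * B)
  expect_equal(v["RGB", ], R * G * B)
  expect_error(buildVariableMatrix(rgb, 4), "order")
})

test_that("correction-matrix fit recovers an exact linear model and ground truth", {
  set.seed(31)
  rgb24 <- matrix(runif(72, 0.05, 0.95), 3)
  v <- buildVariableMatrix(rgb24, 3)

  # XYZ an exact linear map of RGB lies in the model span
  A <- matrix(rnorm(9), 3)
  xyz <- A %*% rgb24
  C <- fitCorrectionMatrix(xyz, v)
  expect_lt(max(abs(applyCorrection(C, v) - xyz)), 1e-8)

  # duplicating every patch leaves the fit unchanged
  C2 <- fitCorrectionMatrix(cbind(xyz, xyz), cbind(v, v))
  expect_equal(unclass(C2)[, ], unclass(C)[, ], tolerance = 1e-8)

  # parameter recovery with more independent columns than terms
  rgb40 <- matrix(runif(120, 0.05, 0.95), 3)
  v40 <- buildVariableMatrix(rgb40, 3)
  Cstar <- matrix(rnorm(60), 3)
  Cfit <- fitCorrectionMatrix(Cstar %*% v40, v40)
  expect_lt(max(abs(unclass(Cfit) - Cstar)), 1e-6)

  expect_equal(unname(applyCorrection(matrix(0, 3, 20), v)[, ]),
               matrix(0, 3, 24))
  # brute-force triple-loop product oracle
  got <- applyCorrection(Cstar, v)
  want <- matrix(0, 3, ncol(v))
  for (i in 1:3) for (j in seq_len(ncol(v))) for (k in seq_len(nrow(v)))
    want[i, j] <- want[i, j] + Cstar[i, k] * v[k, j]
  expect_equal(unname(got[, ]), want, tolerance = 1e-12)
  expect_error(applyCorrection(Cstar, v[1:5, ]), "dimensions")
})

test_that("PCA basis is orthonormal, ordered and matches a Gram-matrix oracle", {
  wl <- spectralGrid()
  # rank-6 data: mean + random combinations of 6 fixed orthonormal loadings
  set.seed(41)
  L <- qr.Q(qr(matrix(rnorm(length(wl) * 6), ncol = 6)))
  mu <- 0.5 + 0.1 * sin(wl / 60)
  sc <- matrix(rnorm(6 * 24, 0, 0.05), 6)
  sp <- spectra(wl, pmax(mu + L %*% sc, 0))
  basis <- fitPCABasis(sp, 6)
  expect_equal(explainedFraction(basis), 1, tolerance = 1e-9)
  scores <- pcaScores(basis, sp)
  full <- basis@meanSpectrum + basis@loadings %*% scores
  expect_lt(max(abs(full - spectraValues(sp))), 1e-8)

  # eigenvalues against an independent eigendecomposition of the centred
  # 24 x 24 Gram matrix
  ck <- makeReferenceChecker(wl)
  b2 <- fitPCABasis(reflectance(ck), 6)
  X <- spectraValues(reflectance(ck))
  Xc <- X - rowMeans(X)
  ev <- eigen(crossprod(Xc), symmetric = TRUE, only.values = TRUE)$values / 23
  expect_equal(b2@eigenvalues[1:6], ev[1:6], tolerance = 1e-9)
  expect_equal(explainedFraction(b2), sum(ev[1:6]) / sum(ev), tolerance = 1e-9)
  # ordered by descending eigenvalue; fraction non-decreasing in nComp
  expect_monotone_nonincreasing(b2@eigenvalues)
  fr <- vapply(1:8, function(k)
    explainedFraction(fitPCABasis(reflectance(ck), k)), numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
  # all 23 nontrivial components reconstruct exactly
  b23 <- fitPCABasis(reflectance(ck), 23)
  full23 <- b23@meanSpectrum + b23@loadings %*% pcaScores(b23, reflectance(ck))
  expect_lt(max(abs(full23 - X)), 1e-8)
  expect_error(fitPCABasis(spectra(wl, X[, 1:5]), 6), "at least")
})

test_that("transform fit recovers ground truth and reconstruction expands the basis", {
  wl <- spectralGrid()
  ck <- makeReferenceChecker(wl)
  basis <- fitPCABasis(reflectance(ck), 6)
  set.seed(51)
  rgb <- matrix(runif(120, 0.05, 0.95), 3)
  v <- buildVariableMatrix(rgb, 3)
  Mstar <- matrix(rnorm(120), 6)
  scores <- Mstar %*% v
  Mfit <- fitTransformMatrix(scores, v)
  expect_lt(max(abs(unclass(Mfit) - Mstar)), 1e-6)
  expect_equal(unname(unclass(fitTransformMatrix(scores * 0, v))[, ]),
               matrix(0, 6, 20))

  # noiseless realizable model: in-sample spectra reproduced to 1e-8
  spTrue <- spectra(wl, basis@meanSpectrum + basis@loadings %*% scores)
  recon <- reconstructSpectrum(Mfit, basis, v)
  expect_lt(max(patchRMSE(recon, spTrue, window = c(380, 780))), 1e-8)

  # M = 0 returns the mean spectrum; expansion matches a term-by-term oracle
  reconZero <- reconstructSpectrum(matrix(0, 6, 20), basis, v[, 1])
  expect_equal(spectraValues(reconZero)[, 1], basis@meanSpectrum)
  s1 <- drop(Mstar %*% v[, 3])
  byHand <- basis@meanSpectrum
  for (k in 1:6) byHand <- byHand + s1[k] * basis@loadings[, k]
  expect_equal(spectraValues(reconstructSpectrum(Mstar, basis, v[, 3]))[, 1],
               byHand, tolerance = 1e-12)
})

test_that("patch RMSE follows its closed forms and windowing", {
  wl <- spectralGrid()
  set.seed(61)
  a <- spectra(wl, runif(length(wl)))
  expect_equal(patchRMSE(a, a), 0)
  b <- spectra(wl, spectraValues(a) + 0.07)
  expect_equal(patchRMSE(b, a), 0.07, tolerance = 1e-12)
  # brute-force elementwise oracle over the window
  c2 <- spectra(wl, runif(length(wl)))
  idx <- wl >= 400 & wl <= 700
  want <- sqrt(mean((spectraValues(a)[idx, 1] - spectraValues(c2)[idx, 1])^2))
  expect_equal(unname(patchRMSE(a, c2)), want, tolerance = 1e-12)
  expect_error(patchRMSE(a, spectra(spectralGrid(step = 2),
                                    rep(0.5, length(spectralGrid(step = 2))))),
               "grid")
})

test_that("in-sample residual shrinks with the expansion order", {
  rig <- calibrationRig()
  ref <- referenceXYZ(rig$checker)
  res <- vapply(1:3, function(ord) {
    v <- buildVariableMatrix(cameraRGB(rig$checker), order = ord)
    C <- fitCorrectionMatrix(spectrumToXYZ(rig$measured), v)
    sqrt(mean(attr(C, "residuals")^2))
  }, numeric(1))
  expect_monotone_nonincreasing(res, tol = 1e-12)
})

test_that("calibration quality degrades monotonically with sensor noise", {
  sweep <- c(0, 0.001, 0.005, 0.01)
  rmse <- de <- numeric(length(sweep))
  for (i in seq_along(sweep)) {
    rig <- calibrationRig(seed = 42, sigma = sweep[i])
    rmse[i] <- mean(rig$rmseTrue)
    de[i] <- mean(fitReport(rig$bundle)$deltaE00)
  }
  expect_true(all(diff(rmse) >= 0))
  expect_true(all(diff(de) >= 0))
})

test_that("full-loop recovery is near-exact for data inside the model class", {
  # spectra generated as mean + loadings %*% (M* %*% V(cameraRGB)): the
  # fitted class contains the truth, so the loop must close to < 1e-3
  wl <- spectralGrid()
  ck <- makeReferenceChecker(wl)
  basis <- fitPCABasis(reflectance(ck), 6)
  set.seed(71)
  rgb <- matrix(runif(72, 0.1, 0.9), 3)
  v <- buildVariableMatrix(rgb)
  Mstar <- matrix(rnorm(120, 0, 0.05), 6)
  spTrue <- spectra(wl, pmin(pmax(
    basis@meanSpectrum + basis@loadings %*% (Mstar %*% v), 0), 1))
  bundle <- fitCalibration(cameraRGB = rgb, measuredSpectra = spTrue)
  recon <- reconstructSpectrum(transformMatrix(bundle), pcaBasis(bundle), v)
  expect_lt(max(patchRMSE(recon, spTrue)), 1e-3)
})

test_that("image-to-cube conversion matches the per-pixel loop and flags saturation", {
  rig <- calibrationRig()
  bundle <- rig$bundle
  set.seed(81)
  img <- array(runif(2 * 2 * 3, 0.05, 0.9), c(2, 2, 3))
  img[1, 1, 1] <- 1  # saturated pixel
  cube <- rgbImageToSpectralCube(img, bundle)
  expect_s4_class(cube, "SpectralCube")
  sat <- attr(cubeValues(cube), "saturated")
  expect_true(sat[1, 1]); expect_false(sat[2, 2])
  for (i in 1:2) for (j in 1:2) {
    v1 <- buildVariableMatrix(img[i, j, ], order = bundle@order)
    one <- reconstructSpectrum(transformMatrix(bundle), pcaBasis(bundle), v1)
    expect_equal(cubeValues(cube)[i, j, ],
                 pmin(pmax(spectraValues(one)[, 1], -0.1), 1.3),
                 tolerance = 1e-12)
  }
  # uniform image of one colour -> spatially constant cube
  uni <- array(rep(c(0.4, 0.3, 0.2), each = 6), c(2, 3, 3))
  cu <- rgbImageToSpectralCube(uni, bundle)
  expect_equal(max(apply(cubeValues(cu), 3, function(m) diff(range(m)))), 0)
})
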