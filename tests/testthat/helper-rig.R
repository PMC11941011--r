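# Shared synthetic calibration rig: packaged reference checker captured by
# the default virtual camera (gamma 1.05, dark 0.002, readout noise sigma)
# with spectrometer references at the same noise level. Cached per
# (seed, sigma) because several test files reuse the same rig.

.rigCache <- new.env(parent = emptyenv())

calibrationRig <- function(seed = 20240714, sigma = 0.002) {
  key <- paste0("s", seed, "_n", sigma)
  if (!is.null(.rigCache[[key]])) return(.rigCache[[key]])
  wl <- spectralGrid()
  checker <- makeReferenceChecker(wl)
  cam <- virtualCamera(wl, noiseSigma = sigma)
  checker <- simulateCameraCapture(checker, cam, seed = seed)
  measured <- simulateSpectrometer(reflectance(checker), sigma, seed = seed + 1L)
  bundle <- fitCalibration(checker, measuredSpectra = measured)
  v <- buildVariableMatrix(cameraRGB(checker))
  recon <- reconstructSpectrum(transformMatrix(bundle), pcaBasis(bundle), v)
  rig <- list(wl = wl, checker = checker, cam = cam, measured = measured,
              bundle = bundle, v = v, recon = recon,
              rmseTrue = patchRMSE(recon, reflectance(checker)))
  .rigCache[[key]] <- rig
  rig
}

# clip reconstructed spectra at zero before colorimetry
nonNegative <- function(sp) spectra(wavelengths(sp), pmax(spectraValues(sp), 0),
                                    names = colnames(spectraValues(sp)))

expect_monotone_nonincreasing <- function(x, tol = 0) {
  expect_true(all(diff(x) <= tol))
}
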