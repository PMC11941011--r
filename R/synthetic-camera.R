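## Virtual camera and virtual spectrometer: seeded forward models that stand
## in for the physical instruments of a calibration bench.

## run expr with a temporary RNG state seeded from `seed`; restores the
## caller's stream so simulations are reproducible without side effects
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a virtual RGB camera
#'
#' Smooth Gaussian channel sensitivities (default peaks 460/550/600 nm), a
#' mild power-law nonlinearity and a dark offset, so the third-order
#' polynomial correction has genuine nonlinearity to absorb. Sensitivities
#' are scaled so a perfect reflector under the camera illuminant reads 1.0
#' per channel before the nonlinearity.
#'
#' @param wavelength spectral grid in nm.
#' @param peaks channel sensitivity peaks in nm (B is the 460 nm channel by
#'   storage order R, G, B: give peaks as c(R, G, B)).
#' @param sd Gaussian sensitivity standard deviations in nm.
#' @param gamma nonlinearity exponent applied to (signal + dark).
#' @param dark dark-current offset.
#' @param noiseSigma Gaussian readout-noise standard deviation.
#' @param illuminant \linkS4class{Spectra}; default D65.
#' @return a \linkS4class{VirtualCamera}.
#' @export
virtualCamera <- function(wavelength = spectralGrid(),
                          peaks = c(600, 550, 460), sd = c(45, 40, 30),
                          gamma = 1.05, dark = 0.002, noiseSigma = 0.002,
                          illuminant = NULL) {
  if (is.null(illuminant)) illuminant <- illuminantD65(wavelength)
  stopifnot(sameGrid(wavelength, illuminant@wavelength))
  sens <- vapply(seq_len(3L), function(c.)
    exp(-0.5 * ((wavelength - peaks[c.]) / sd[c.])^2), numeric(length(wavelength)))
  colnames(sens) <- c("R", "G", "B")
  ## exposure normalisation: perfect reflector -> 1.0 per channel
  tw <- .trapzWeights(wavelength, range(wavelength))
  S <- illuminant@values[, 1L]
  for (c. in seq_len(3L)) {
    e <- sum(S[tw$idx] * sens[tw$idx, c.] * tw$w)
    sens[, c.] <- sens[, c.] / e
  }
  new("VirtualCamera", wavelength = wavelength, sensitivities = sens,
      illuminant = S, gamma = gamma, dark = dark, noiseSigma = noiseSigma)
}

## expected linear channel responses for a wavelength x n reflectance matrix
.cameraResponse <- function(cam, reflMatrix) {
  tw <- .trapzWeights(cam@wavelength, range(cam@wavelength))
  W <- cam@sensitivities[tw$idx, , drop = FALSE] * (cam@illuminant[tw$idx] * tw$w)
  t(W) %*% reflMatrix[tw$idx, , drop = FALSE]   # 3 x n
}

#' Simulate a camera capture
#'
#' Applies the camera forward model (spectral integration, dark offset,
#' nonlinearity, seeded Gaussian readout noise) to a colour checker or a
#' spectral cube. Deterministic given the seed.
#'
#' @param scene a \linkS4class{ColorChecker} or \linkS4class{SpectralCube}.
#' @param cam a \linkS4class{VirtualCamera} on the same grid.
#' @param seed integer RNG seed for the readout noise (NULL = use current RNG).
#' @return for a checker, the same checker with \code{cameraRGB} filled
#'   (3 x 24 linear RGB); for a cube, an height x width x 3 linear RGB array.
#' @export
simulateCameraCapture <- function(scene, cam, seed = 20240714) {
  if (is(scene, "ColorChecker")) {
    if (!sameGrid(scene@reflectance@wavelength, cam@wavelength))
      stop("checker and camera must share one wavelength grid")
    e <- .cameraResponse(cam, scene@reflectance@values)
    out <- (pmax(e + cam@dark, 0))^cam@gamma
    out <- withSeed(seed, out + matrix(
      stats::rnorm(length(out), 0, cam@noiseSigma), nrow = 3L))
    out <- pmax(out, 0)
    rownames(out) <- c("R", "G", "B")
    colnames(out) <- scene@patchNames
    scene@cameraRGB <- out
    validObject(scene)
    return(scene)
  }
  if (is(scene, "SpectralCube")) {
    if (!sameGrid(scene@wavelength, cam@wavelength))
      stop("cube and camera must share one wavelength grid")
    d <- dim(scene@values)
    flat <- t(matrix(scene@values, d[1L] * d[2L], d[3L]))  # nwl x npix
    e <- .cameraResponse(cam, flat)
    out <- (pmax(e + cam@dark, 0))^cam@gamma
    out <- withSeed(seed, out + matrix(
      stats::rnorm(length(out), 0, cam@noiseSigma), nrow = 3L))
    out <- pmax(out, 0)
    img <- array(t(out), dim = c(d[1L], d[2L], 3L))
    attr(img, "linear") <- TRUE
    return(img)
  }
  stop("scene must be a ColorChecker or a SpectralCube")
}

#' Simulate spectrometer measurements
#'
#' Adds seeded Gaussian noise to reflectance spectra and clips at zero
#' (a spectrometer never reports negative reflectance).
#'
#' @param sp a \linkS4class{Spectra} of true reflectances.
#' @param noiseSigma Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed (NULL = use current RNG).
#' @return a \linkS4class{Spectra} of measured reflectances.
#' @export
simulateSpectrometer <- function(sp, noiseSigma = 0.002, seed = 20240714) {
  stopifnot(is(sp, "Spectra"), noiseSigma >= 0)
  v <- withSeed(seed, sp@values + matrix(
    stats::rnorm(length(sp@values), 0, noiseSigma), nrow = nrow(sp@values)))
  spectra(sp@wavelength, pmax(v, 0), names = colnames(sp@values))
}
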