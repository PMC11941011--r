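## Synthetic pigmented-lesion scenes with known ground truth.
##
## The chromophore curves are smooth parametric stand-ins, not literature
## extinction tables: hemoglobin-like absorption is modelled as Gaussian
## bumps at its 415 nm (Soret) and 540 nm peaks, melanin-like absorption as
## a monotone exponential decay with wavelength. That is sufficient to give
## the 415/540 nm bands genuine diagnostic contrast over a skin-like base.

#' Default smooth skin base reflectance
#'
#' A smooth sigmoidal ramp from ~0.3 in the blue to ~0.65 in the red,
#' mimicking the shape of pale-skin diffuse reflectance.
#'
#' @param wavelength spectral grid in nm.
#' @return single-column \linkS4class{Spectra}.
#' @export
baseSkinSpectrum <- function(wavelength = spectralGrid()) {
  v <- 0.30 + 0.35 / (1 + exp(-(wavelength - 590) / 55))
  spectra(wavelength, v, names = "skin")
}

## unit-amplitude absorption shapes
.hemoglobinAbsorption <- function(wavelength)
  exp(-0.5 * ((wavelength - 415) / 20)^2) +
  0.45 * exp(-0.5 * ((wavelength - 540) / 25)^2)

.melaninAbsorption <- function(wavelength)
  exp(-(wavelength - 380) / 180)

#' Generate a synthetic lesion scene
#'
#' Background reflectance is the base skin spectrum attenuated by
#' hemoglobin-like absorption (Beer-Lambert, peaks near 415 and 540 nm); a
#' central disk is additionally attenuated by melanin-like absorption
#' (monotone decreasing in wavelength), so lesion contrast is strongest in
#' the blue. Optional per-pixel log-normal texture; bit-reproducible given
#' the seed.
#'
#' @param size image side in pixels.
#' @param lesionRadius lesion disk radius in pixels (< size/2).
#' @param melaninOD optical-density scale of the lesion absorption (>= 0).
#' @param hemoglobinOD optical-density scale of the background vascular
#'   absorption (>= 0).
#' @param baseSkin background \linkS4class{Spectra} (single column).
#' @param textureSigma log-normal spatial texture sd (0 = smooth scene).
#' @param wavelength spectral grid in nm.
#' @param seed integer RNG seed for the texture.
#' @return list with \code{cube} (\linkS4class{SpectralCube}), \code{mask}
#'   (logical matrix, TRUE inside the lesion), and the ground-truth
#'   \code{background}/\code{lesion} spectra.
#' @export
makeLesionScene <- function(size = 48, lesionRadius = 12, melaninOD = 1.0,
                            hemoglobinOD = 0.4,
                            baseSkin = NULL, textureSigma = 0.02,
                            wavelength = spectralGrid(), seed = 20240714) {
  stopifnot(melaninOD >= 0, hemoglobinOD >= 0, lesionRadius < size / 2)
  if (is.null(baseSkin)) baseSkin <- baseSkinSpectrum(wavelength)
  stopifnot(sameGrid(wavelength, baseSkin@wavelength))

  base <- baseSkin@values[, 1L]
  bg  <- base * exp(-hemoglobinOD * .hemoglobinAbsorption(wavelength))
  les <- bg * exp(-melaninOD * .melaninAbsorption(wavelength))

  ctr <- (size + 1) / 2
  dist2 <- outer(seq_len(size), seq_len(size),
                 function(i, j) (i - ctr)^2 + (j - ctr)^2)
  mask <- dist2 <= lesionRadius^2

  tex <- withSeed(seed, matrix(
    exp(stats::rnorm(size * size, 0, textureSigma)), size, size))

  nwl <- length(wavelength)
  vals <- array(0, dim = c(size, size, nwl))
  for (b in seq_len(nwl))
    vals[, , b] <- ifelse(mask, les[b], bg[b]) * tex
  vals <- pmin(pmax(vals, 0), 1.2)

  list(cube = spectralCube(wavelength, vals), mask = mask,
       background = spectra(wavelength, bg, names = "background"),
       lesion = spectra(wavelength, les, names = "lesion"))
}
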