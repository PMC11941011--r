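## Synthetic reference colour checker.
##
## No spectral measurement of a physical chart ships with the package; the
## reference chart is synthesized by spectral upsampling of the classic
## 24-patch chart's nominal sRGB colours into a fixed smooth band basis
## (constant + 5 broad Gaussian bumps). Real paint reflectances are smooth
## and close to a low-dimensional subspace; the construction reproduces that
## compressibility. Neutral patches are exactly spectrally flat.

.classicPatchHex <- c(
  "dark skin"     = "#735244", "light skin"    = "#C29682",
  "blue sky"      = "#627A9D", "foliage"       = "#576C43",
  "blue flower"   = "#8580B1", "bluish green"  = "#67BDAA",
  "orange"        = "#D67E2C", "purplish blue" = "#505BA6",
  "moderate red"  = "#C15A63", "purple"        = "#5E3C6C",
  "yellow green"  = "#9DBC40", "orange yellow" = "#E0A32E",
  "blue"          = "#383D96", "green"         = "#469449",
  "red"           = "#AF363C", "yellow"        = "#E7C71F",
  "magenta"       = "#BB5695", "cyan"          = "#0885A1",
  "white"         = "#F3F3F2", "neutral 8"     = "#C8C8C8",
  "neutral 6.5"   = "#A0A0A0", "neutral 5"     = "#7A7A79",
  "neutral 3.5"   = "#555555", "black"         = "#343434")

.hexToLinearRGB <- function(hex) {
  m <- grDevices::col2rgb(hex)
  apply(m, 2L, srgbToLinear) |> matrix(nrow = 3L)
}

## smooth band basis used for spectral upsampling: constant + 5 Gaussian
## bumps spanning the visible range
.upsampleBasis <- function(wavelength) {
  centers <- c(420, 490, 560, 630, 700)
  B <- cbind(1, vapply(centers, function(mu)
    exp(-0.5 * ((wavelength - mu) / 55)^2), numeric(length(wavelength))))
  colnames(B) <- c("const", paste0("g", centers))
  B
}

#' Synthetic reference colour checker
#'
#' Builds the package's 24-patch calibration chart: smooth reflectance
#' spectra whose D65 colours match the classic chart's nominal sRGB patch
#' values (18 chromatic patches via smooth spectral upsampling, 6 exactly
#' flat neutrals from white to black). Reference XYZ values are recomputed
#' from the final packaged spectra under D65, so chart colours and chart
#' spectra are exactly consistent. The set is synthetic: it emulates the
#' smoothness and low intrinsic dimensionality of measured chart spectra,
#' not any specific physical chart.
#'
#' @param wavelength spectral grid in nm (default 380--780 at 1 nm).
#' @return a \linkS4class{ColorChecker} (without camera readings).
#' @export
makeReferenceChecker <- function(wavelength = spectralGrid()) {
  hex <- .classicPatchHex
  rgbLin <- .hexToLinearRGB(hex)
  nwl <- length(wavelength)
  refl <- matrix(0, nwl, 24L, dimnames = list(NULL, names(hex)))

  B <- .upsampleBasis(wavelength)
  ## XYZ operator rows under D65 (3 x nwl), so A %*% spectrum = XYZ
  cmfs <- cie1931cmf(wavelength)
  S <- illuminantD65(wavelength)@values[, 1L]
  tw <- .trapzWeights(wavelength, c(400, 700))
  Sw <- S[tw$idx] * tw$w
  k <- 100 / sum(Sw * cmfs[tw$idx, "ybar"])
  A <- matrix(0, 3L, nwl)
  A[, tw$idx] <- t(cmfs[tw$idx, , drop = FALSE] * Sw) * k

  AB <- A %*% B                       # 3 x 6, full row rank
  ABpinv <- MASS::ginv(AB, tol = 1e-10)
  neutral <- 19:24
  for (j in seq_len(24L)) {
    if (j %in% neutral) {
      ## flat reflectance at the patch's linear grey level
      refl[, j] <- mean(rgbLin[, j])
    } else {
      target <- srgbToXYZ(rgbLin[, j])
      refl[, j] <- B %*% (ABpinv %*% target)
    }
  }
  refl <- pmin(pmax(refl, 0.02), 0.98)

  sp <- spectra(wavelength, refl, names = names(hex))
  xyz <- spectrumToXYZ(sp)
  new("ColorChecker", patchNames = names(hex), reflectance = sp,
      referenceXYZ = xyz, cameraRGB = matrix(numeric(0), 0L, 0L))
}
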