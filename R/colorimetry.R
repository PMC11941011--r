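## CIE 1931 colorimetry: tristimulus integration, sRGB, CIELAB, CIEDE2000.

## piecewise Gaussian lobe used by the analytic CMF fits
.lobe <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree colour-matching functions
#'
#' Analytic multi-lobe piecewise-Gaussian approximation to the 2-degree
#' standard observer (accurate to about 1--2\% of peak; ybar peaks at 1 near
#' 555 nm). All colorimetric quantities in the package are computed with
#' these functions, so the pipeline is internally consistent.
#'
#' @param wavelength numeric grid in nm.
#' @return matrix with columns \code{xbar}, \code{ybar}, \code{zbar} and a
#'   \code{"wavelength"} attribute.
#' @export
cie1931cmf <- function(wavelength = spectralGrid()) {
  xbar <- 1.056 * .lobe(wavelength, 599.8, 37.9, 31.0) +
          0.362 * .lobe(wavelength, 442.0, 16.0, 26.7) -
          0.065 * .lobe(wavelength, 501.1, 20.4, 26.2)
  ybar <- 0.821 * .lobe(wavelength, 568.8, 46.9, 40.5) +
          0.286 * .lobe(wavelength, 530.9, 16.3, 31.1)
  zbar <- 1.217 * .lobe(wavelength, 437.0, 11.8, 36.0) +
          0.681 * .lobe(wavelength, 459.0, 26.0, 13.8)
  m <- cbind(xbar = pmax(xbar, 0), ybar = pmax(ybar, 0), zbar = pmax(zbar, 0))
  attr(m, "wavelength") <- wavelength
  m
}

#' Standard illuminants on a wavelength grid
#'
#' \code{illuminantD65} interpolates the packaged CIE D65 relative spectral
#' power table (10 nm tabulation) to the requested grid; \code{illuminantE}
#' is the equal-energy illuminant. Both follow the CIE convention of value
#' 100 at 560 nm.
#'
#' @param wavelength numeric grid in nm.
#' @return a single-column \linkS4class{Spectra} of relative power.
#' @export
illuminantD65 <- function(wavelength = spectralGrid()) {
  path <- system.file("extdata", "illuminant_d65.csv", package = "saveHSI")
  tab <- utils::read.csv(path)
  v <- stats::approx(tab$wavelength_nm, tab$relative_power, xout = wavelength,
                     rule = 2)$y
  spectra(wavelength, v, names = "D65")
}

#' @rdname illuminantD65
#' @export
illuminantE <- function(wavelength = spectralGrid()) {
  spectra(wavelength, rep(100, length(wavelength)), names = "E")
}

## trapezoid weights over the sub-window [lo, hi] of a uniform grid
.trapzWeights <- function(wavelength, window = c(400, 700)) {
  idx <- which(wavelength >= window[1L] - 1e-9 & wavelength <= window[2L] + 1e-9)
  if (length(idx) < 2L) stop("integration window contains fewer than 2 grid points")
  w <- rep(gridStep(wavelength), length(idx))
  w[c(1L, length(idx))] <- w[1L] / 2
  list(idx = idx, w = w)
}

.asSpectraMatrix <- function(x) {
  if (is(x, "Spectra")) return(list(wl = x@wavelength, v = x@values))
  if (is.matrix(x)) return(list(wl = attr(x, "wavelength"), v = x))
  stop("expected a Spectra object or a matrix with a wavelength attribute")
}

#' Integrate reflectance spectra to CIE XYZ tristimulus values
#'
#' Trapezoid-rule integration of illuminant x reflectance x colour-matching
#' function over 400--700 nm, normalised so a perfect reflector has Y = 100
#' (k = 100 / integral of illuminant x ybar).
#'
#' @param reflectanceSpectra \linkS4class{Spectra} (reflectance in [0, 1.2]).
#' @param illuminant \linkS4class{Spectra}; default D65 on the same grid.
#' @param cmfs colour-matching function matrix from \code{\link{cie1931cmf}}.
#' @param window integration limits in nm.
#' @return 3 x n matrix, rows X, Y, Z (0--100 luminance scale).
#' @export
spectrumToXYZ <- function(reflectanceSpectra, illuminant = NULL, cmfs = NULL,
                          window = c(400, 700)) {
  sp <- .asSpectraMatrix(reflectanceSpectra)
  if (is.null(illuminant)) illuminant <- illuminantD65(sp$wl)
  if (is.null(cmfs)) cmfs <- cie1931cmf(sp$wl)
  if (!sameGrid(sp$wl, illuminant@wavelength) ||
      !sameGrid(sp$wl, attr(cmfs, "wavelength")))
    stop("reflectance, illuminant and CMFs must share one wavelength grid")
  if (min(sp$v) < 0) stop("reflectance must be non-negative")
  S <- illuminant@values[, 1L]
  tw <- .trapzWeights(sp$wl, window)
  Sw <- S[tw$idx] * tw$w
  k <- 100 / sum(Sw * cmfs[tw$idx, "ybar"])
  ## (3 x nwl_window) %*% (nwl_window x n): rows are k * sum S R cmf dl
  A <- t(cmfs[tw$idx, , drop = FALSE] * Sw) * k
  out <- A %*% sp$v[tw$idx, , drop = FALSE]
  rownames(out) <- c("X", "Y", "Z")
  out
}

#' sRGB transfer function (IEC 61966-2-1)
#'
#' \code{srgbToLinear} decodes 8-bit-scale encoded values in [0, 255] to
#' linear light in [0, 1]; \code{linearToSrgb} is its inverse.
#'
#' @param x numeric values (any shape).
#' @return numeric of the same shape.
#' @export
srgbToLinear <- function(x) {
  if (any(x < 0 | x > 255)) stop("encoded sRGB values must lie in [0, 255]")
  v <- x / 255
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' @rdname srgbToLinear
#' @export
linearToSrgb <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  255 * ifelse(x <= 0.0031308, 12.92 * x, 1.055 * x^(1 / 2.4) - 0.055)
}

## IEC 61966-2-1 / sRGB D65 primaries
.M_RGB2XYZ <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3L, byrow = TRUE)
.M_XYZ2RGB <- matrix(c(
   3.2404542, -1.5371385, -0.4985314,
  -0.9692660,  1.8760108,  0.0415560,
   0.0556434, -0.2040259,  1.0572252), nrow = 3L, byrow = TRUE)

#' Linear sRGB to CIE XYZ and back (D65)
#'
#' Standard sRGB 3x3 matrix on the 0--100 luminance scale. Out-of-gamut
#' values are returned unclipped with a \code{"gamut"} attribute marking
#' columns that left [0, 1], because the calibration regression needs
#' unclipped residuals.
#'
#' @param rgb linear RGB: length-3 vector or 3 x n matrix.
#' @param xyz XYZ: length-3 vector or 3 x n matrix (0--100 scale).
#' @return 3 x n matrix.
#' @export
srgbToXYZ <- function(rgb) {
  rgb <- .as3xn(rgb)
  out <- 100 * (.M_RGB2XYZ %*% rgb)
  rownames(out) <- c("X", "Y", "Z")
  out
}

#' @rdname srgbToXYZ
#' @export
xyzToSrgb <- function(xyz) {
  xyz <- .as3xn(xyz)
  out <- .M_XYZ2RGB %*% (xyz / 100)
  rownames(out) <- c("R", "G", "B")
  attr(out, "gamut") <- apply(out < -1e-9 | out > 1 + 1e-9, 2L, any)
  out
}

.as3xn <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 3L)
  if (nrow(x) != 3L) stop("expected a length-3 vector or a 3 x n matrix")
  x
}

#' The D65 white point of the sRGB system
#'
#' @return length-3 XYZ vector with Y = 100.
#' @export
whiteD65 <- function() drop(srgbToXYZ(c(1, 1, 1)))

#' CIE XYZ to CIELAB
#'
#' @param xyz 3 x n matrix or length-3 vector, 0--100 scale.
#' @param white reference white XYZ with Y = 100 (default sRGB D65 white).
#' @return 3 x n matrix with rows L, a, b.
#' @export
xyzToLab <- function(xyz, white = whiteD65()) {
  if (any(white <= 0)) stop("reference white must be strictly positive")
  xyz <- .as3xn(xyz)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz[1L, ] / white[1L])
  fy <- f(xyz[2L, ] / white[2L])
  fz <- f(xyz[3L, ] / white[3L])
  out <- rbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  out
}

#' CIEDE2000 colour difference
#'
#' The CIE 2000 Delta-E formula with parametric factors kL = kC = kH = 1.
#' Symmetric, non-negative, zero only for identical Lab inputs.
#'
#' @param lab1,lab2 CIELAB colours: length-3 vectors or 3 x n matrices
#'   (rows L, a, b), compared pairwise by column.
#' @return numeric vector of Delta-E00 values.
#' @export
ciede2000 <- function(lab1, lab2) {
  lab1 <- .as3xn(lab1); lab2 <- .as3xn(lab2)
  if (ncol(lab1) != ncol(lab2)) stop("lab1 and lab2 must have equal length")
  L1 <- lab1[1L, ]; a1 <- lab1[2L, ]; b1 <- lab1[3L, ]
  L2 <- lab2[1L, ]; a2 <- lab2[2L, ]; b2 <- lab2[3L, ]

  C1 <- sqrt(a1^2 + b1^2); C2 <- sqrt(a2^2 + b2^2)
  Cbar <- (C1 + C2) / 2
  G <- 0.5 * (1 - sqrt(Cbar^7 / (Cbar^7 + 25^7)))
  a1p <- (1 + G) * a1; a2p <- (1 + G) * a2
  C1p <- sqrt(a1p^2 + b1^2); C2p <- sqrt(a2p^2 + b2^2)
  hp <- function(a, b) {
    h <- atan2(b, a) * 180 / pi
    ifelse(h < 0, h + 360, h)
  }
  h1p <- ifelse(C1p == 0, 0, hp(a1p, b1))
  h2p <- ifelse(C2p == 0, 0, hp(a2p, b2))

  dLp <- L2 - L1
  dCp <- C2p - C1p
  dh <- h2p - h1p
  dhp <- ifelse(C1p * C2p == 0, 0,
         ifelse(abs(dh) <= 180, dh, ifelse(dh > 180, dh - 360, dh + 360)))
  dHp <- 2 * sqrt(C1p * C2p) * sin(dhp / 2 * pi / 180)

  Lbp <- (L1 + L2) / 2
  Cbp <- (C1p + C2p) / 2
  hsum <- h1p + h2p
  hbp <- ifelse(C1p * C2p == 0, hsum,
         ifelse(abs(h1p - h2p) <= 180, hsum / 2,
         ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  Tt <- 1 - 0.17 * cos((hbp - 30) * pi / 180) + 0.24 * cos(2 * hbp * pi / 180) +
        0.32 * cos((3 * hbp + 6) * pi / 180) - 0.20 * cos((4 * hbp - 63) * pi / 180)
  dTheta <- 30 * exp(-((hbp - 275) / 25)^2)
  RC <- 2 * sqrt(Cbp^7 / (Cbp^7 + 25^7))
  SL <- 1 + 0.015 * (Lbp - 50)^2 / sqrt(20 + (Lbp - 50)^2)
  SC <- 1 + 0.045 * Cbp
  SH <- 1 + 0.015 * Cbp * Tt
  RT <- -sin(2 * dTheta * pi / 180) * RC

  sqrt((dLp / SL)^2 + (dCp / SC)^2 + (dHp / SH)^2 +
       RT * (dCp / SC) * (dHp / SH))
}

#' Mean CIEDE2000 over paired colour sets
#'
#' Converts both XYZ sets to Lab against a shared white and averages the
#' pairwise Delta-E00. This is the "chromatic aberration" summary used for
#' calibration diagnostics.
#'
#' @param xyzA,xyzB 3 x n XYZ matrices, compared pairwise by column.
#' @param white shared reference white (Y = 100).
#' @return mean Delta-E00 (scalar), with per-pair values as attribute
#'   \code{"perPair"}.
#' @export
meanColorDifference <- function(xyzA, xyzB, white = whiteD65()) {
  xyzA <- .as3xn(xyzA); xyzB <- .as3xn(xyzB)
  if (ncol(xyzA) != ncol(xyzB)) stop("colour sets must have equal length")
  de <- ciede2000(xyzToLab(xyzA, white), xyzToLab(xyzB, white))
  out <- mean(de)
  attr(out, "perPair") <- de
  out
}
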