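#' @import methods
NULL

#' Construct a uniform spectral wavelength grid
#'
#' The working wavelength axis for all spectral objects. The default covers
#' 380--780 nm at 1 nm, wide enough to carry the 780 nm narrow band while the
#' tristimulus integration itself only uses 400--700 nm.
#'
#' @param start,stop grid end points in nm.
#' @param step positive spacing in nm.
#' @return numeric vector of wavelengths.
#' @export
spectralGrid <- function(start = 380, stop = 780, step = 1) {
  stopifnot(step > 0, stop > start)
  seq(start, stop, by = step)
}

## shared grid checks: strictly increasing, uniform, covers the XYZ
## integration window [400, 700] nm
validGrid <- function(wl) {
  if (length(wl) < 2L) return("wavelength grid needs at least 2 points")
  d <- diff(wl)
  if (any(d <= 0)) return("wavelength grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * mean(d)) return("wavelength grid must be uniform")
  if (wl[1L] > 400 || wl[length(wl)] < 700)
    return("wavelength grid must cover [400, 700] nm")
  NULL
}

gridStep <- function(wl) (wl[length(wl)] - wl[1L]) / (length(wl) - 1L)

sameGrid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(a - b)) <= tol
}

#' Spectra: one or more spectra on a common wavelength grid
#'
#' Column-oriented container: \code{values} is a wavelength-by-sample matrix,
#' one column per spectrum. Used for reflectance (dimensionless, nominally in
#' [0, 1] with mild overshoot tolerated) and for relative spectral power.
#'
#' @slot wavelength numeric grid in nm (strictly increasing, uniform,
#'   covering at least 400--700 nm).
#' @slot values numeric matrix, \code{length(wavelength)} rows.
#' @exportClass Spectra
setClass("Spectra", representation(wavelength = "numeric", values = "matrix"))

setValidity("Spectra", function(object) {
  msg <- validGrid(object@wavelength)
  if (!is.null(msg)) return(msg)
  if (nrow(object@values) != length(object@wavelength))
    return("values must have one row per wavelength")
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' Create a Spectra object
#'
#' @param wavelength numeric grid in nm.
#' @param values numeric vector (one spectrum) or wavelength-by-sample matrix.
#' @param names optional sample names.
#' @return a \linkS4class{Spectra} object.
#' @export
spectra <- function(wavelength, values, names = NULL) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (!is.null(names)) colnames(values) <- names
  new("Spectra", wavelength = as.numeric(wavelength), values = values)
}

#' @describeIn spectra wavelength accessor.
#' @param x a Spectra (or other spectral) object.
#' @export
wavelengths <- function(x) {
  if (is(x, "Spectra") || is(x, "SpectralCube") || is(x, "PCABasis") ||
      is(x, "VirtualCamera")) x@wavelength
  else attr(x, "wavelength")
}

#' @describeIn spectra value-matrix accessor.
#' @export
spectraValues <- function(x) x@values

#' @describeIn spectra number of spectra held.
#' @export
nSpectra <- function(x) ncol(x@values)

setMethod("show", "Spectra", function(object) {
  wl <- object@wavelength
  cat(sprintf("Spectra: %d spectrum/spectra on %g-%g nm (step %g)\n",
              ncol(object@values), wl[1L], wl[length(wl)], gridStep(wl)))
})

#' ColorChecker: a 24-patch calibration chart
#'
#' Holds the patch reflectance spectra, the patch colours as CIE XYZ
#' (spectrometer-side reference), and optionally the linear camera RGB
#' readings of the same patches (camera side).
#'
#' @slot patchNames character, 24 names; the final six are neutral
#'   (white through black).
#' @slot reflectance \linkS4class{Spectra} with 24 columns.
#' @slot referenceXYZ 3 x 24 matrix (rows X, Y, Z on the 0--100 scale).
#' @slot cameraRGB 3 x 24 matrix of linear camera RGB, or 0 x 0 when unset.
#' @exportClass ColorChecker
setClass("ColorChecker", representation(
  patchNames = "character", reflectance = "Spectra",
  referenceXYZ = "matrix", cameraRGB = "matrix"))

setValidity("ColorChecker", function(object) {
  n <- length(object@patchNames)
  if (n != 24L) return("a colour checker has exactly 24 patches")
  if (ncol(object@reflectance@values) != n)
    return("one reflectance spectrum per patch required")
  if (!all(dim(object@referenceXYZ) == c(3L, n)))
    return("referenceXYZ must be 3 x 24")
  if (min(object@reflectance@values) < 0 || max(object@reflectance@values) > 1.2)
    return("patch reflectance must lie in [0, 1.2]")
  if (length(object@cameraRGB) && !all(dim(object@cameraRGB) == c(3L, n)))
    return("cameraRGB must be 3 x 24 when present")
  TRUE
})

#' @describeIn makeReferenceChecker patch-name accessor.
#' @export
patchNames <- function(x) x@patchNames

#' @describeIn makeReferenceChecker patch reflectance accessor
#'   (\linkS4class{Spectra}).
#' @export
reflectance <- function(x) x@reflectance

#' @describeIn makeReferenceChecker reference XYZ accessor (3 x 24).
#' @export
referenceXYZ <- function(x) x@referenceXYZ

#' @describeIn makeReferenceChecker linear camera RGB accessor (3 x 24 or NULL).
#' @export
cameraRGB <- function(x) if (length(x@cameraRGB)) x@cameraRGB else NULL

setMethod("show", "ColorChecker", function(object) {
  cat("ColorChecker: 24 patches",
      if (length(object@cameraRGB)) "(with camera readings)" else "", "\n")
  cat("  neutrals:", paste(tail(object@patchNames, 6L), collapse = ", "), "\n")
})

#' PCABasis: low-dimensional spectral reflectance basis
#'
#' Mean spectrum plus orthonormal component loadings from a mean-centred PCA
#' of patch reflectance spectra; a reflectance spectrum is reconstructed as
#' mean + loadings \%*\% scores.
#'
#' @slot wavelength grid in nm.
#' @slot meanSpectrum numeric, mean reflectance.
#' @slot loadings wavelength x k matrix of orthonormal loadings.
#' @slot eigenvalues all PCA variances (not just the retained k).
#' @slot explainedFraction cumulative variance fraction of the retained k.
#' @exportClass PCABasis
setClass("PCABasis", representation(
  wavelength = "numeric", meanSpectrum = "numeric", loadings = "matrix",
  eigenvalues = "numeric", explainedFraction = "numeric"))

setValidity("PCABasis", function(object) {
  msg <- validGrid(object@wavelength)
  if (!is.null(msg)) return(msg)
  if (length(object@meanSpectrum) != length(object@wavelength))
    return("meanSpectrum length must match grid")
  if (nrow(object@loadings) != length(object@wavelength))
    return("loadings must have one row per wavelength")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(object@loadings)))) > 1e-8)
    return("loadings must be orthonormal")
  if (object@explainedFraction <= 0 || object@explainedFraction > 1 + 1e-12)
    return("explainedFraction must be in (0, 1]")
  TRUE
})

#' @describeIn fitPCABasis number of retained components.
#' @export
nComponents <- function(basis) ncol(basis@loadings)

#' @describeIn fitPCABasis cumulative variance fraction of retained components.
#' @export
explainedFraction <- function(basis) basis@explainedFraction

setMethod("show", "PCABasis", function(object) {
  cat(sprintf("PCABasis: %d components, %.4f%% variance explained\n",
              ncol(object@loadings), 100 * object@explainedFraction))
})

#' CalibrationBundle: the fitted RGB-to-spectrum calibration
#'
#' Everything needed to turn a linear camera RGB triple into a reflectance
#' spectrum: the polynomial expansion order, the colour correction matrix C
#' (variable matrix -> XYZ), the transform matrix M (variable matrix -> PCA
#' scores), the PCA basis, and per-patch fit diagnostics.
#'
#' @slot order polynomial order of the variable matrix (1--3).
#' @slot termLabels monomial labels of the variable-matrix rows.
#' @slot correction 3 x n_terms matrix C.
#' @slot transform k x n_terms matrix M.
#' @slot basis \linkS4class{PCABasis}.
#' @slot window evaluation window in nm for RMSE/colour diagnostics.
#' @slot fitReport data.frame of per-patch diagnostics.
#' @exportClass CalibrationBundle
setClass("CalibrationBundle", representation(
  order = "integer", termLabels = "character", correction = "matrix",
  transform = "matrix", basis = "PCABasis", window = "numeric",
  fitReport = "data.frame"))

setValidity("CalibrationBundle", function(object) {
  nt <- length(object@termLabels)
  if (!object@order %in% 1:3) return("order must be 1, 2 or 3")
  if (!all(dim(object@correction) == c(3L, nt)))
    return("correction must be 3 x n_terms")
  if (ncol(object@transform) != nt)
    return("transform must have n_terms columns")
  if (nrow(object@transform) != ncol(object@basis@loadings))
    return("transform rows must match the number of PCA components")
  if (any(!is.finite(object@correction)) || any(!is.finite(object@transform)))
    return("calibration matrices must be finite")
  TRUE
})

#' @describeIn fitCalibration correction-matrix accessor (3 x n_terms).
#' @export
correctionMatrix <- function(bundle) bundle@correction

#' @describeIn fitCalibration transform-matrix accessor (k x n_terms).
#' @export
transformMatrix <- function(bundle) bundle@transform

#' @describeIn fitCalibration PCA-basis accessor.
#' @export
pcaBasis <- function(bundle) bundle@basis

#' @describeIn fitCalibration per-patch fit diagnostics.
#' @export
fitReport <- function(bundle) bundle@fitReport

setMethod("show", "CalibrationBundle", function(object) {
  cat(sprintf("CalibrationBundle: order %d (%d terms), %d PCA components\n",
              object@order, length(object@termLabels),
              nrow(object@transform)))
  if (nrow(object@fitReport)) {
    cat(sprintf("  mean patch RMSE %.4f, mean dE00 %.3f\n",
                mean(object@fitReport$rmse), mean(object@fitReport$deltaE00)))
  }
})

#' SpectralCube: a height x width x band reflectance image
#'
#' @slot wavelength band centres in nm (the spectral grid).
#' @slot values numeric array, dim = c(height, width, bands). Reconstruction
#'   overshoot is tolerated in [-0.1, 1.3]; export clips to [0, 1].
#' @exportClass SpectralCube
setClass("SpectralCube", representation(wavelength = "numeric", values = "array"))

setValidity("SpectralCube", function(object) {
  msg <- validGrid(object@wavelength)
  if (!is.null(msg)) return(msg)
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-d array")
  if (d[3L] != length(object@wavelength))
    return("third dimension must match the wavelength grid")
  rng <- range(object@values)
  if (rng[1L] < -0.1 || rng[2L] > 1.3)
    return("cube reflectance must lie in [-0.1, 1.3]")
  TRUE
})

#' Create a SpectralCube
#'
#' @param wavelength band centres in nm.
#' @param values array of dim c(height, width, bands).
#' @return a \linkS4class{SpectralCube}.
#' @export
spectralCube <- function(wavelength, values)
  new("SpectralCube", wavelength = as.numeric(wavelength), values = values)

#' @describeIn spectralCube reflectance array accessor.
#' @param cube a SpectralCube.
#' @export
cubeValues <- function(cube) cube@values

setMethod("dim", "SpectralCube", function(x) dim(x@values))

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  wl <- object@wavelength
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1L], d[2L], d[3L], wl[1L], wl[length(wl)]))
})

#' BandSet: narrow bands and their display compositing
#'
#' Each band is a Gaussian filter (centre, FWHM) with a non-negative weight,
#' assigned to one or more display channels. The default follows the NBI
#' pseudo-colour convention: 415 nm feeds display blue and green, 540 nm (and
#' the auxiliary 600/700/780 nm bands) feed display red.
#'
#' @slot centers band centres in nm.
#' @slot fwhm full widths at half maximum in nm (> 0).
#' @slot weights non-negative band gains.
#' @slot channels list of character vectors, subset of c("R","G","B"),
#'   one entry per band.
#' @exportClass BandSet
setClass("BandSet", representation(
  centers = "numeric", fwhm = "numeric", weights = "numeric",
  channels = "list"))

setValidity("BandSet", function(object) {
  n <- length(object@centers)
  if (n == 0L) return("band set must not be empty")
  if (length(object@fwhm) != n || length(object@weights) != n ||
      length(object@channels) != n)
    return("centers, fwhm, weights, channels must have equal length")
  if (any(object@fwhm <= 0)) return("fwhm must be positive")
  if (any(object@weights < 0)) return("weights must be non-negative")
  chs <- unlist(object@channels)
  if (!all(chs %in% c("R", "G", "B"))) return("channels must be R, G or B")
  if (!all(c("R", "G", "B") %in% chs))
    return("every display channel must receive at least one band")
  TRUE
})

#' Create a BandSet
#'
#' @param centers band centres in nm.
#' @param fwhm full widths at half maximum in nm.
#' @param weights non-negative band gains.
#' @param channels list of display-channel assignments per band.
#' @return a \linkS4class{BandSet}.
#' @export
bandSet <- function(centers, fwhm, weights, channels)
  new("BandSet", centers = as.numeric(centers), fwhm = as.numeric(fwhm),
      weights = as.numeric(weights), channels = channels)

#' The default SAVE band set
#'
#' 415 and 540 nm carry the diagnostic hemoglobin contrast (FWHM 30 nm,
#' matching commercial NBI filter widths); 600, 700 and 780 nm are narrower
#' auxiliary bands (FWHM 20 nm) mixed into display red with small weights to
#' reproduce the brown cast of hardware NBI.
#'
#' @return a \linkS4class{BandSet}.
#' @export
defaultBandSet <- function()
  bandSet(centers = c(415, 540, 600, 700, 780),
          fwhm    = c(30, 30, 20, 20, 20),
          weights = c(1, 1, 0.25, 0.15, 0.1),
          channels = list(c("B", "G"), "R", "R", "R", "R"))

#' @describeIn bandSet band weights accessor.
#' @param bands a BandSet.
#' @export
bandWeights <- function(bands) bands@weights

#' @describeIn bandSet replace band weights.
#' @param value numeric replacement weights.
#' @export
`bandWeights<-` <- function(bands, value) {
  bands@weights <- as.numeric(value)
  validObject(bands)
  bands
}

setMethod("show", "BandSet", function(object) {
  cat("BandSet:\n")
  for (i in seq_along(object@centers))
    cat(sprintf("  %g nm (FWHM %g) w=%.3g -> %s\n", object@centers[i],
                object@fwhm[i], object@weights[i],
                paste(object@channels[[i]], collapse = "+")))
})

#' VirtualCamera: a forward model of an RGB camera
#'
#' Channel response = nonlinearity(integral of reflectance x illuminant x
#' sensitivity + dark) + Gaussian readout noise. Sensitivities are stored
#' pre-scaled so a perfect reflector under the camera illuminant yields 1.0
#' per channel before the nonlinearity.
#'
#' @slot wavelength grid in nm.
#' @slot sensitivities wavelength x 3 matrix (R, G, B), non-negative.
#' @slot illuminant numeric relative SPD on the grid.
#' @slot gamma nonlinearity exponent applied to (signal + dark).
#' @slot dark dark-current offset added before the nonlinearity.
#' @slot noiseSigma Gaussian readout-noise standard deviation.
#' @exportClass VirtualCamera
setClass("VirtualCamera", representation(
  wavelength = "numeric", sensitivities = "matrix", illuminant = "numeric",
  gamma = "numeric", dark = "numeric", noiseSigma = "numeric"))

setValidity("VirtualCamera", function(object) {
  msg <- validGrid(object@wavelength)
  if (!is.null(msg)) return(msg)
  if (!all(dim(object@sensitivities) == c(length(object@wavelength), 3L)))
    return("sensitivities must be wavelength x 3")
  if (min(object@sensitivities) < 0) return("sensitivities must be non-negative")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (object@gamma <= 0) return("gamma must be positive")
  TRUE
})

setMethod("show", "VirtualCamera", function(object) {
  pk <- object@wavelength[apply(object@sensitivities, 2L, which.max)]
  cat(sprintf(
    "VirtualCamera: peaks %g/%g/%g nm, gamma %.3g, dark %.3g, noise sigma %.3g\n",
    pk[1L], pk[2L], pk[3L], object@gamma, object@dark, object@noiseSigma))
})
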