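## Camera-to-spectrum calibration from a 24-patch colour checker:
## third-order polynomial variable matrix, pseudoinverse regression for the
## colour correction matrix C (V -> XYZ) and the transform matrix M (V ->
## PCA scores), and reflectance reconstruction mean + loadings %*% M %*% v.

## fixed monomial ordering of the degree-<=3 expansion; the trailing
## constant term carries the dark-current offset
.termLabelsFull <- c("R", "G", "B",
                     "R2", "G2", "B2", "RG", "GB", "RB",
                     "R3", "G3", "B3", "R2G", "R2B", "G2R", "G2B",
                     "B2R", "B2G", "RGB", "const")

#' Monomial labels of the variable-matrix expansion
#'
#' @param order polynomial order, 1, 2 or 3.
#' @return character vector of term labels (constant term last).
#' @export
variableTermLabels <- function(order = 3) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  n <- c(3L, 9L, 19L)[order]
  c(.termLabelsFull[seq_len(n)], "const")
}

#' Build the polynomial variable matrix from linear camera RGB
#'
#' Expands each RGB triple into the complete monomial basis of total degree
#' at most \code{order} (plus a constant term absorbing the dark current),
#' in the fixed order \code{\link{variableTermLabels}}. At order 3 this
#' gives 20 terms; the expansion is deliberately capped at the third order
#' to avoid over-correction.
#'
#' @param rgb linear RGB: length-3 vector or 3 x n matrix (rows R, G, B).
#' @param order polynomial order, 1, 2 or 3.
#' @return n_terms x n matrix with rownames = term labels.
#' @export
buildVariableMatrix <- function(rgb, order = 3) {
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  rgb <- .as3xn(rgb)
  R <- rgb[1L, ]; G <- rgb[2L, ]; B <- rgb[3L, ]
  rows <- list(R = R, G = G, B = B)
  if (order >= 2) rows <- c(rows, list(
    R2 = R^2, G2 = G^2, B2 = B^2, RG = R * G, GB = G * B, RB = R * B))
  if (order >= 3) rows <- c(rows, list(
    R3 = R^3, G3 = G^3, B3 = B^3, R2G = R^2 * G, R2B = R^2 * B,
    G2R = G^2 * R, G2B = G^2 * B, B2R = B^2 * R, B2G = B^2 * G,
    RGB = R * G * B))
  rows$const <- rep(1, length(R))
  do.call(rbind, rows)
}

## Moore-Penrose pseudoinverse; singular values below tol * sigma_max dropped
.pinv <- function(A, tol = 1e-10) MASS::ginv(A, tol = tol)

#' Fit the colour correction matrix C
#'
#' Least-squares map from the variable matrix to reference (spectrometer)
#' XYZ: C = XYZ_ref \%*\% pinv(V). Rank deficiency beyond the pinv tolerance
#' is reported as a warning; the fit proceeds (the pseudoinverse yields the
#' minimum-norm solution).
#'
#' @param xyzReference 3 x n matrix of reference XYZ, columns aligned to V.
#' @param v variable matrix from \code{\link{buildVariableMatrix}}.
#' @return 3 x n_terms matrix with a \code{"residuals"} attribute (3 x n).
#' @export
fitCorrectionMatrix <- function(xyzReference, v) {
  xyzReference <- .as3xn(xyzReference)
  if (ncol(xyzReference) != ncol(v))
    stop("xyzReference and v must have the same number of columns")
  sv <- svd(v, nu = 0, nv = 0)$d
  if (ncol(v) >= nrow(v) && min(sv) < 1e-10 * max(sv))
    warning("variable matrix is rank deficient; pseudoinverse fit proceeds")
  C <- xyzReference %*% .pinv(v)
  attr(C, "residuals") <- C %*% v - xyzReference
  C
}

#' Apply the colour correction matrix
#'
#' Corrected XYZ = C \%*\% V, one corrected colour per sample column.
#'
#' @param C 3 x n_terms correction matrix.
#' @param v variable matrix (n_terms x n).
#' @return 3 x n matrix of corrected XYZ.
#' @export
applyCorrection <- function(C, v) {
  if (ncol(C) != nrow(v)) stop("C and v dimensions do not agree")
  out <- C %*% v
  rownames(out) <- c("X", "Y", "Z")
  out
}

#' Fit a PCA reflectance basis
#'
#' Mean-centred principal component analysis of patch reflectance spectra
#' (singular value decomposition of the centred wavelength x sample matrix).
#' Components are ordered by descending eigenvalue; the explained fraction
#' is the retained eigenvalue sum over the total.
#'
#' @param sp \linkS4class{Spectra} with at least nComp + 1 columns.
#' @param nComp number of components to retain (default 6).
#' @return a \linkS4class{PCABasis}.
#' @export
fitPCABasis <- function(sp, nComp = 6) {
  stopifnot(is(sp, "Spectra"))
  X <- sp@values
  n <- ncol(X)
  if (n < nComp + 1) stop("need at least nComp + 1 spectra")
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- seq_len(nComp)
  new("PCABasis", wavelength = sp@wavelength, meanSpectrum = mu,
      loadings = sv$u[, keep, drop = FALSE], eigenvalues = ev,
      explainedFraction = sum(ev[keep]) / sum(ev))
}

#' PCA scores of spectra in a fitted basis
#'
#' @param basis a \linkS4class{PCABasis}.
#' @param sp \linkS4class{Spectra} on the basis grid.
#' @return nComp x n score matrix.
#' @export
pcaScores <- function(basis, sp) {
  stopifnot(sameGrid(basis@wavelength, sp@wavelength))
  t(basis@loadings) %*% (sp@values - basis@meanSpectrum)
}

#' Fit the spectral transform matrix M
#'
#' Least-squares map from the variable matrix to PCA scores:
#' M = Score \%*\% pinv(V_color). Together with the basis this turns a
#' camera RGB triple into a reflectance spectrum.
#'
#' @param scores nComp x n PCA score matrix, columns aligned to v.
#' @param v variable matrix (n_terms x n).
#' @return nComp x n_terms matrix with a \code{"residuals"} attribute.
#' @export
fitTransformMatrix <- function(scores, v) {
  if (ncol(scores) != ncol(v))
    stop("scores and v must have the same number of columns")
  M <- scores %*% .pinv(v)
  attr(M, "residuals") <- M %*% v - scores
  M
}

#' Reconstruct reflectance spectra from variable-matrix columns
#'
#' spectrum = mean + loadings \%*\% (M \%*\% v), evaluated per column.
#'
#' @param M transform matrix (nComp x n_terms).
#' @param basis \linkS4class{PCABasis}.
#' @param v variable matrix column(s) (n_terms x n).
#' @return \linkS4class{Spectra} with one column per sample.
#' @export
reconstructSpectrum <- function(M, basis, v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1L)
  vals <- basis@meanSpectrum + basis@loadings %*% (M %*% v)
  spectra(basis@wavelength, vals, names = colnames(v))
}

#' Spectral RMSE between reconstructed and reference spectra
#'
#' Root-mean-square reflectance difference per spectrum pair, evaluated over
#' a wavelength window (default 400--700 nm, where the calibration is
#' constrained; the red end beyond 700 nm is the known weak spot of
#' RGB-based reconstruction).
#'
#' @param reconstructed,reference \linkS4class{Spectra} on a common grid,
#'   compared column by column.
#' @param window evaluation window in nm.
#' @return numeric vector of per-column RMSE values.
#' @export
patchRMSE <- function(reconstructed, reference, window = c(400, 700)) {
  if (!sameGrid(reconstructed@wavelength, reference@wavelength))
    stop("spectra must share one wavelength grid")
  if (ncol(reconstructed@values) != ncol(reference@values))
    stop("spectra sets must have the same number of columns")
  idx <- which(reconstructed@wavelength >= window[1L] &
               reconstructed@wavelength <= window[2L])
  d <- reconstructed@values[idx, , drop = FALSE] -
       reference@values[idx, , drop = FALSE]
  sqrt(colMeans(d^2))
}

#' Fit the full calibration bundle from checker readings
#'
#' The complete calibration fit: builds the third-order variable matrix from
#' the linear camera RGB readings, fits the correction matrix C against the
#' spectrometer-side reference XYZ, fits the PCA basis on the measured
#' reflectance spectra, projects them to scores, fits the transform matrix
#' M, and assembles per-patch diagnostics (spectral RMSE and Delta-E00 of
#' the reconstructed patch colours, plus Delta-E00 of the corrected XYZ).
#'
#' @param checker \linkS4class{ColorChecker} with camera readings attached
#'   (see \code{\link{simulateCameraCapture}}), or NULL if \code{cameraRGB}
#'   and \code{measuredSpectra} are given directly.
#' @param measuredSpectra \linkS4class{Spectra}: spectrometer-measured patch
#'   reflectances (defaults to the checker's reflectance slot).
#' @param referenceXYZ 3 x 24 reference XYZ (defaults to XYZ of
#'   \code{measuredSpectra} under D65).
#' @param cameraRGB 3 x 24 linear camera RGB (defaults to the checker slot).
#' @param order variable-matrix order (1--3).
#' @param nComp number of PCA components (default 6).
#' @param window diagnostic evaluation window in nm.
#' @return a \linkS4class{CalibrationBundle}.
#' @export
fitCalibration <- function(checker = NULL, measuredSpectra = NULL,
                           referenceXYZ = NULL, cameraRGB = NULL,
                           order = 3, nComp = 6, window = c(400, 700)) {
  if (!is.null(checker)) {
    if (is.null(cameraRGB)) cameraRGB <- cameraRGB(checker)
    if (is.null(measuredSpectra)) measuredSpectra <- checker@reflectance
  }
  if (is.null(cameraRGB)) stop("camera RGB readings are required")
  if (is.null(measuredSpectra)) stop("measured patch spectra are required")
  if (is.null(referenceXYZ)) referenceXYZ <- spectrumToXYZ(measuredSpectra)

  v <- buildVariableMatrix(cameraRGB, order = order)
  C <- fitCorrectionMatrix(referenceXYZ, v)
  basis <- fitPCABasis(measuredSpectra, nComp = nComp)
  scores <- pcaScores(basis, measuredSpectra)
  M <- fitTransformMatrix(scores, v)

  recon <- reconstructSpectrum(M, basis, v)
  rmse <- patchRMSE(recon, measuredSpectra, window = window)
  reconXYZ <- spectrumToXYZ(spectra(
    recon@wavelength, pmax(recon@values, 0), colnames(recon@values)),
    window = window)
  deRecon <- attr(meanColorDifference(reconXYZ, referenceXYZ), "perPair")
  deCorr <- attr(meanColorDifference(applyCorrection(C, v), referenceXYZ),
                 "perPair")
  report <- data.frame(
    patch = if (!is.null(colnames(cameraRGB))) colnames(cameraRGB)
            else paste0("patch", seq_len(ncol(cameraRGB))),
    rmse = rmse, deltaE00 = deRecon, deltaE00corrected = deCorr,
    row.names = NULL)

  new("CalibrationBundle", order = as.integer(order),
      termLabels = variableTermLabels(order),
      correction = unclass(C)[, , drop = FALSE],
      transform = unclass(M)[, , drop = FALSE],
      basis = basis, window = as.numeric(window), fitReport = report)
}

#' Reconstruct a spectral cube from a linear RGB image
#'
#' Vectorised per-pixel reconstruction: the variable matrix is built for
#' every pixel and mapped through the calibrated transform; the result is
#' identical to looping \code{\link{reconstructSpectrum}} over pixels.
#' Pixels with any channel at or above 0.999 are flagged saturated (they are
#' still converted).
#'
#' @param img height x width x 3 array of linear RGB.
#' @param bundle a \linkS4class{CalibrationBundle}.
#' @return a \linkS4class{SpectralCube} with a logical
#'   \code{"saturated"} mask attribute on its values.
#' @export
rgbImageToSpectralCube <- function(img, bundle) {
  d <- dim(img)
  if (length(d) != 3L || d[3L] != 3L)
    stop("img must be a height x width x 3 array")
  rgb <- t(matrix(img, d[1L] * d[2L], 3L))          # 3 x npix
  sat <- matrix(apply(rgb >= 0.999, 2L, any), d[1L], d[2L])
  v <- buildVariableMatrix(rgb, order = bundle@order)
  recon <- reconstructSpectrum(bundle@transform, bundle@basis, v)
  vals <- array(t(recon@values), dim = c(d[1L], d[2L], length(bundle@basis@wavelength)))
  vals <- pmin(pmax(vals, -0.1), 1.3)
  cube <- spectralCube(bundle@basis@wavelength, vals)
  attr(cube@values, "saturated") <- sat
  cube
}
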