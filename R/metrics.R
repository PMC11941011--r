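## Image quality metrics used to validate SAVE output: SSIM, PSNR, Shannon
## entropy and relative entropy difference.

## separable 'valid' convolution of a matrix with a 1-d kernel, realised as
## banded matrix products (rows then columns)
.convValid <- function(m, kern) {
  k <- length(kern)
  bandMat <- function(nIn) {
    nOut <- nIn - k + 1L
    K <- matrix(0, nOut, nIn)
    for (i in seq_len(nOut)) K[i, i:(i + k - 1L)] <- kern
    K
  }
  Kr <- bandMat(nrow(m))
  Kc <- bandMat(ncol(m))
  Kr %*% m %*% t(Kc)
}

.gaussKernel <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-0.5 * (x / sigma)^2)
  g / sum(g)
}

.ssimChannel <- function(a, b, window, sigma, C1, C2) {
  if (min(dim(a)) < window) {
    ## image smaller than the window: single global window, uniform weights
    mua <- mean(a); mub <- mean(b)
    va <- mean((a - mua)^2); vb <- mean((b - mub)^2)
    cab <- mean((a - mua) * (b - mub))
    return(((2 * mua * mub + C1) * (2 * cab + C2)) /
           ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  g <- .gaussKernel(window, sigma)
  mua <- .convValid(a, g); mub <- .convValid(b, g)
  saa <- .convValid(a * a, g) - mua^2
  sbb <- .convValid(b * b, g) - mub^2
  sab <- .convValid(a * b, g) - mua * mub
  mean(((2 * mua * mub + C1) * (2 * sab + C2)) /
       ((mua^2 + mub^2 + C1) * (saa + sbb + C2)))
}

.toChannels <- function(img) {
  if (is.matrix(img)) list(img)
  else lapply(seq_len(dim(img)[3L]), function(c.) img[, , c.])
}

.luminance <- function(img) {
  if (is.matrix(img)) return(img)
  ## Y row of the linear sRGB -> XYZ matrix
  0.2126729 * img[, , 1L] + 0.7151522 * img[, , 2L] + 0.0721750 * img[, , 3L]
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with a Gaussian 11 x 11 window (sigma 1.5) and stabilisers
#' C1 = (k1 L)^2, C2 = (k2 L)^2. For colour images the headline value is
#' computed on linear luminance; per-channel values are attached as an
#' attribute. Images smaller than the window fall back to a single global
#' window.
#'
#' @param imgA,imgB matrices or height x width x 3 arrays of equal shape,
#'   intensities on the \code{dynamicRange} scale.
#' @param window window size in pixels.
#' @param sigma Gaussian window standard deviation.
#' @param k1,k2 stabiliser constants.
#' @param dynamicRange intensity range L (1 for [0,1] images).
#' @return SSIM in [-1, 1] with attribute \code{"perChannel"}.
#' @export
ssim <- function(imgA, imgB, window = 11, sigma = 1.5, k1 = 0.01, k2 = 0.03,
                 dynamicRange = 1) {
  if (!identical(dim(imgA), dim(imgB))) stop("images must have the same shape")
  C1 <- (k1 * dynamicRange)^2
  C2 <- (k2 * dynamicRange)^2
  chA <- .toChannels(imgA); chB <- .toChannels(imgB)
  perCh <- vapply(seq_along(chA), function(i)
    .ssimChannel(chA[[i]], chB[[i]], window, sigma, C1, C2), numeric(1))
  out <- .ssimChannel(.luminance(imgA), .luminance(imgB), window, sigma, C1, C2)
  attr(out, "perChannel") <- perCh
  out
}

#' Peak signal-to-noise ratio
#'
#' 10 log10(peak^2 / MSE) in decibels; identical images give Inf (callers
#' exporting reports cap at 100 dB).
#'
#' @param imgA,imgB equal-shape images.
#' @param peak peak signal value (1 for [0,1] images).
#' @return PSNR in dB.
#' @export
psnr <- function(imgA, imgB, peak = 1) {
  if (!identical(dim(imgA), dim(imgB))) stop("images must have the same shape")
  mse <- mean((imgA - imgB)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Shannon entropy of an image histogram
#'
#' Entropy in bits of the intensity histogram over [0, 1] with
#' \code{nBins} equal bins.
#'
#' @param img numeric image with intensities in [0, 1].
#' @param nBins number of histogram bins.
#' @return entropy in bits (0 for a constant image).
#' @export
entropyBits <- function(img, nBins = 256) {
  if (length(img) == 0L) stop("empty image")
  v <- pmin(pmax(as.numeric(img), 0), 1)
  counts <- tabulate(pmin(floor(v * nBins) + 1L, nBins), nbins = nBins)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Relative entropy difference in percent
#'
#' |H(A) - H(B)| / H(A) x 100, the summary used to compare the information
#' content of enhanced images against their reference.
#'
#' @param imgA reference image (intensities in [0, 1]).
#' @param imgB test image.
#' @param nBins histogram bins.
#' @return percentage difference (NA if the reference entropy is zero).
#' @export
entropyDiffPct <- function(imgA, imgB, nBins = 256) {
  hA <- entropyBits(imgA, nBins)
  hB <- entropyBits(imgB, nBins)
  if (hA == 0) return(NA_real_)
  abs(hA - hB) / hA * 100
}

#' Full metric report for an image pair
#'
#' @param refImg reference image (matrix or 3-channel array, [0, 1]).
#' @param testImg test image of the same shape.
#' @return list with \code{rmse}, \code{ssim}, \code{ssimPerChannel},
#'   \code{psnrDb} (capped at 100), \code{entropyRefBits},
#'   \code{entropyTestBits} and \code{entropyDiffPct}.
#' @export
metricReport <- function(refImg, testImg) {
  s <- ssim(refImg, testImg)
  list(rmse = sqrt(mean((refImg - testImg)^2)),
       ssim = as.numeric(s),
       ssimPerChannel = attr(s, "perChannel"),
       psnrDb = min(psnr(refImg, testImg), 100),
       entropyRefBits = entropyBits(refImg),
       entropyTestBits = entropyBits(testImg),
       entropyDiffPct = entropyDiffPct(refImg, testImg))
}
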