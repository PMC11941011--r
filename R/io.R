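## File I/O: PNG/TIFF images (sRGB decoded to linear light exactly once at
## ingest), ENVI BSQ spectral cubes, spectra CSV tables and JSON calibration
## bundles.

#' Read an RGB image
#'
#' Reads PNG or TIFF (8/16-bit) and, by default, decodes sRGB to linear
#' light. The returned array carries a \code{"linear"} attribute so
#' downstream code can detect double decoding.
#'
#' @param path file path (.png, .tif or .tiff).
#' @param linearize decode sRGB to linear light?
#' @return height x width x 3 numeric array in [0, 1].
#' @export
readImage <- function(path, linearize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (linearize) {
    img[] <- srgbToLinear(img * 255)
    attr(img, "linear") <- TRUE
  } else attr(img, "linear") <- FALSE
  img
}

#' Write an RGB image
#'
#' Encodes linear light back to sRGB by default and writes PNG (8-bit) or
#' TIFF (8- or 16-bit).
#'
#' @param img height x width x 3 array in [0, 1].
#' @param path output path (.png, .tif or .tiff).
#' @param encode apply the sRGB transfer function before writing?
#' @param bits bits per sample for TIFF (8 or 16).
#' @return the path, invisibly.
#' @export
writeImage <- function(img, path, encode = TRUE, bits = 8) {
  out <- if (encode) linearToSrgb(img) / 255 else pmin(pmax(img, 0), 1)
  out <- array(out, dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(out, path),
    tif = , tiff = tiff::writeTIFF(out, path, bits.per.sample = bits),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Write a spectral cube as ENVI BSQ
#'
#' Writes \code{<path>} (band-sequential float32, little endian) plus
#' \code{<path>.hdr} with the band wavelengths.
#'
#' @param cube a \linkS4class{SpectralCube}.
#' @param path output path for the binary file.
#' @return the path, invisibly.
#' @export
writeCube <- function(cube, path) {
  d <- dim(cube@values)
  hdr <- c("ENVI",
           "description = {saveHSI reflectance cube}",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0", "file type = ENVI Standard",
           "data type = 4", "interleave = bsq", "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = {",
                  paste(format(cube@wavelength, trim = TRUE), collapse = ", "),
                  "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  ## BSQ: band-major, row-major within a band
  for (b in seq_len(d[3L]))
    writeBin(as.numeric(t(cube@values[, , b])), con, size = 4L,
             endian = "little")
  invisible(path)
}

.enviHeaderValue <- function(lines, key) {
  hit <- grep(paste0("^", key, "\\s*="), lines, value = TRUE)
  if (!length(hit)) stop("ENVI header: missing field '", key, "'")
  trimws(sub("^[^=]*=", "", hit[1L]))
}

#' Read an ENVI BSQ spectral cube
#'
#' @param path path to the binary file written by \code{\link{writeCube}}
#'   (expects \code{<path>.hdr} alongside).
#' @return a \linkS4class{SpectralCube}.
#' @export
readCube <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) stop("ENVI header not found: ", hdrPath)
  lines <- readLines(hdrPath)
  samples <- as.integer(.enviHeaderValue(lines, "samples"))
  nlines <- as.integer(.enviHeaderValue(lines, "lines"))
  bands <- as.integer(.enviHeaderValue(lines, "bands"))
  dtype <- as.integer(.enviHeaderValue(lines, "data type"))
  interleave <- tolower(.enviHeaderValue(lines, "interleave"))
  if (dtype != 4L) stop("ENVI reader supports data type 4 (float32) only")
  if (interleave != "bsq") stop("ENVI reader supports BSQ interleave only")
  wlTxt <- .enviHeaderValue(lines, "wavelength")
  wl <- as.numeric(strsplit(gsub("[{}]", "", wlTxt), ",")[[1L]])
  if (length(wl) != bands) stop("ENVI header: wavelength count != bands")
  n <- samples * nlines * bands
  raw <- readBin(path, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(raw) != n)
    stop("ENVI file truncated: expected ", n, " values, got ", length(raw))
  vals <- array(0, dim = c(nlines, samples, bands))
  for (b in seq_len(bands)) {
    off <- (b - 1L) * samples * nlines
    vals[, , b] <- matrix(raw[off + seq_len(samples * nlines)],
                          nlines, samples, byrow = TRUE)
  }
  spectralCube(wl, vals)
}

#' Read and write spectra CSV tables
#'
#' Dialect: a header row, a \code{wavelength_nm} column, then one column per
#' spectrum.
#'
#' @param sp a \linkS4class{Spectra}.
#' @param path CSV file path.
#' @return \code{readSpectraCSV} returns a \linkS4class{Spectra};
#'   \code{writeSpectraCSV} returns the path invisibly.
#' @export
writeSpectraCSV <- function(sp, path) {
  df <- data.frame(wavelength_nm = sp@wavelength, sp@values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("spectra CSV must have a 'wavelength_nm' column: ", path)
  bad <- which(!stats::complete.cases(df))
  if (length(bad))
    stop("spectra CSV ", path, ": missing values in row ", bad[1L])
  m <- as.matrix(df[setdiff(names(df), "wavelength_nm")])
  spectra(df$wavelength_nm, m, names = colnames(m))
}

#' Serialize and restore a calibration bundle as JSON
#'
#' Matrices are stored row-major with their dimensions; the spectral grid,
#' term labels, PCA basis and fit report travel with the bundle.
#'
#' @param bundle a \linkS4class{CalibrationBundle}.
#' @param path JSON file path.
#' @return \code{readBundle} returns a \linkS4class{CalibrationBundle};
#'   \code{writeBundle} returns the path invisibly.
#' @export
writeBundle <- function(bundle, path) {
  b <- bundle@basis
  payload <- list(
    format = "saveHSI-calibration",
    version = 1L,
    order = bundle@order,
    termLabels = bundle@termLabels,
    window = bundle@window,
    wavelength = list(start = b@wavelength[1L],
                      stop = b@wavelength[length(b@wavelength)],
                      step = gridStep(b@wavelength)),
    correction = .matToList(bundle@correction),
    transform = .matToList(bundle@transform),
    basis = list(meanSpectrum = b@meanSpectrum,
                 loadings = .matToList(b@loadings),
                 eigenvalues = b@eigenvalues,
                 explainedFraction = b@explainedFraction),
    fitReport = bundle@fitReport)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.matToList <- function(m)
  list(nrow = nrow(m), ncol = ncol(m), data = as.numeric(t(m)))

.listToMat <- function(l)
  matrix(unlist(l$data), l$nrow, l$ncol, byrow = TRUE)

#' @rdname writeBundle
#' @export
readBundle <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "saveHSI-calibration"))
    stop("not a saveHSI calibration bundle: ", path)
  wl <- seq(p$wavelength$start, p$wavelength$stop, by = p$wavelength$step)
  basis <- new("PCABasis", wavelength = wl,
               meanSpectrum = as.numeric(p$basis$meanSpectrum),
               loadings = .listToMat(p$basis$loadings),
               eigenvalues = as.numeric(p$basis$eigenvalues),
               explainedFraction = as.numeric(p$basis$explainedFraction))
  new("CalibrationBundle", order = as.integer(p$order),
      termLabels = as.character(p$termLabels),
      correction = .listToMat(p$correction),
      transform = .listToMat(p$transform),
      basis = basis, window = as.numeric(p$window),
      fitReport = as.data.frame(p$fitReport))
}
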