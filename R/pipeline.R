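## End-to-end pipeline driver: simulate -> calibrate -> convert -> render ->
## evaluate, with cached stage artifacts and a JSON run manifest.

#' Build a pipeline configuration
#'
#' All stage parameters and seeds in one validated list. Reruns with an
#' identical configuration produce identical metric values; every source of
#' randomness is derived from \code{seed}.
#'
#' @param outDir output directory for stage artifacts and the manifest.
#' @param seed master RNG seed.
#' @param gridStart,gridStop,gridStep spectral grid in nm.
#' @param order variable-matrix polynomial order (1--3).
#' @param nComp PCA components.
#' @param cameraNoiseSigma,spectrometerNoiseSigma instrument noise levels.
#' @param sceneSize,lesionRadius,melaninOD,hemoglobinOD lesion-scene
#'   parameters (see \code{\link{makeLesionScene}}).
#' @param annealing \code{\link{fsaParams}} for the band calibration.
#' @param window evaluation window in nm.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outDir, seed = 20240714,
                           gridStart = 380, gridStop = 780, gridStep = 1,
                           order = 3, nComp = 6,
                           cameraNoiseSigma = 0.002,
                           spectrometerNoiseSigma = 0.002,
                           sceneSize = 48, lesionRadius = 12,
                           melaninOD = 1.0, hemoglobinOD = 0.4,
                           annealing = fsaParams(maxIter = 600),
                           window = c(400, 700)) {
  stopifnot(is.character(outDir), length(outDir) == 1L,
            order %in% 1:3, nComp >= 1,
            cameraNoiseSigma >= 0, spectrometerNoiseSigma >= 0,
            gridStep > 0, gridStop > gridStart,
            inherits(annealing, "fsaParams"))
  structure(list(outDir = outDir, seed = as.integer(seed),
                 gridStart = gridStart, gridStop = gridStop,
                 gridStep = gridStep, order = order, nComp = nComp,
                 cameraNoiseSigma = cameraNoiseSigma,
                 spectrometerNoiseSigma = spectrometerNoiseSigma,
                 sceneSize = sceneSize, lesionRadius = lesionRadius,
                 melaninOD = melaninOD, hemoglobinOD = hemoglobinOD,
                 annealing = annealing, window = window),
            class = "pipelineConfig")
}

## write JSON atomically: temp file in the same directory, then rename
.writeJSONAtomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json.tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full synthetic SAVE pipeline
#'
#' Executes, in order: synthetic-data generation (checker spectra, camera
#' readings, lesion scene), calibration fitting, RGB-to-cube conversion of
#' the scene capture, SAVE rendering (with a reference narrow-band render of
#' the ground-truth cube standing in for hardware NBI), and quality
#' evaluation. Stage artifacts are written under \code{config$outDir} and
#' reused when present (\code{force = TRUE} recomputes everything); the run
#' manifest with all quality numbers is written atomically at the end.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param force ignore cached artifacts and recompute all stages?
#' @return the run manifest (list), invisibly also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outDir, ...)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] done in %.2fs", name, timings[[name]]))
    res
  }
  wl <- spectralGrid(config$gridStart, config$gridStop, config$gridStep)

  ## -- simulate ------------------------------------------------------
  checker <- stage("simulate", {
    checker <- makeReferenceChecker(wl)
    cam <- virtualCamera(wl, noiseSigma = config$cameraNoiseSigma)
    checker <- simulateCameraCapture(checker, cam, seed = config$seed)
    if (force || !file.exists(p("checker_spectra.csv")))
      writeSpectraCSV(checker@reflectance, p("checker_spectra.csv"))
    utils::write.csv(t(checker@cameraRGB), p("checker_rgb.csv"))
    checker
  })
  cam <- virtualCamera(wl, noiseSigma = config$cameraNoiseSigma)

  ## -- calibrate -----------------------------------------------------
  bundle <- stage("calibrate", {
    if (!force && file.exists(p("bundle.json"))) readBundle(p("bundle.json"))
    else {
      measured <- simulateSpectrometer(checker@reflectance,
                                       config$spectrometerNoiseSigma,
                                       seed = config$seed + 1L)
      b <- fitCalibration(checker, measuredSpectra = measured,
                          order = config$order, nComp = config$nComp,
                          window = config$window)
      writeBundle(b, p("bundle.json"))
      ## use the serialized form so cached and fresh runs are identical
      readBundle(p("bundle.json"))
    }
  })

  ## -- convert -------------------------------------------------------
  scene <- makeLesionScene(size = config$sceneSize,
                           lesionRadius = config$lesionRadius,
                           melaninOD = config$melaninOD,
                           hemoglobinOD = config$hemoglobinOD,
                           wavelength = wl, seed = config$seed + 2L)
  cube <- stage("convert", {
    if (!force && file.exists(p("scene_recon.bsq"))) readCube(p("scene_recon.bsq"))
    else {
      img <- simulateCameraCapture(scene$cube, cam, seed = config$seed + 3L)
      writeImage(pmin(pmax(img, 0), 1), p("scene_rgb.png"))
      cb <- rgbImageToSpectralCube(img, bundle)
      writeCube(cb, p("scene_recon.bsq"))
      ## read back so cached and fresh runs see the same float32 values
      readCube(p("scene_recon.bsq"))
    }
  })

  ## -- render --------------------------------------------------------
  rendered <- stage("render", {
    bands <- defaultBandSet()
    saveImg <- synthesizeSaveImage(cube, bands)
    refImg <- synthesizeSaveImage(scene$cube, bands)  # ground-truth NBI-style
    writeImage(saveImg, p("scene_save.png"), encode = TRUE)
    writeImage(refImg, p("scene_nbi_ref.png"), encode = TRUE)
    list(saveImg = saveImg, refImg = refImg)
  })

  ## -- evaluate ------------------------------------------------------
  metrics <- stage("evaluate", {
    rep <- metricReport(rendered$refImg, rendered$saveImg)
    fit <- bundle@fitReport
    c(list(meanPatchRMSE = mean(fit$rmse),
           maxPatchRMSE = max(fit$rmse),
           meanDeltaE00recon = mean(fit$deltaE00),
           meanDeltaE00corrected = mean(fit$deltaE00corrected)),
      rep)
  })

  manifest <- list(
    tool = "saveHSI", version = as.character(utils::packageVersion("saveHSI")),
    configHash = rlang::hash(unclass(config)),
    config = unclass(config),
    timings = timings,
    metrics = metrics)
  .writeJSONAtomic(manifest, p("manifest.json"))
  invisible(manifest)
}
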