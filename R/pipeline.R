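# End-to-end orchestration: simulate (or load) -> QC -> detect -> metric ->
# grid -> biovolume -> statistics -> validation, returning a StationReport.
# The run is pure with respect to (config, seed).

#' Build a pipeline run configuration
#'
#' Every quality-control and calibration default equals the survey protocol
#' value: green threshold 0--100 of 255, depth cut 5 m, tilt cut 10 degrees,
#' 10-pixel shape minimum, 3 x 3 m grid cells, carbon density 390 mg C L^-1,
#' camera constant 4.5 mm px^-1 m^-1.
#'
#' @param station station label.
#' @param seed integer seed; the whole run is deterministic given it.
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @param thresholdLo,thresholdHi inclusive green-channel bounds.
#' @param maxDepth,maxTilt frame QC cuts (m, degrees; strict inequalities).
#' @param minShapePixels strict pixel-area bound for shape analysis.
#' @param connectivity component connectivity (8 or 4).
#' @param solidityMin,sizeOutlierK clump-flag parameters
#'   (\code{\link{flagClumps}}).
#' @param blocklist frame ids to discard manually.
#' @param cellSize grid cell size, m.
#' @param carbonDensity mg C per ml.
#' @param restrictedDMin lower bound of the restricted size fit, cm.
#' @param nBins size-distribution bins.
#' @param typeConvention "anchored" or "literal" type-fraction convention.
#' @param epsAnchors numeric(2) eccentricity extremes for type fractions, or
#'   NULL to skip them.
#' @param simulate generate a synthetic survey (TRUE) or analyze supplied
#'   frames.
#' @param scene,field,survey,rendering parameter lists forwarded to
#'   \code{\link{genIceScene}}, \code{\link{genAggregateField}},
#'   \code{\link{surveyParams}} and \code{\link{renderingParams}}.
#' @return a named list of class \code{aggConfig}.
#' @export
aggConfig <- function(station = "SYN-1", seed = 1L,
                      calib = cameraCalib(),
                      thresholdLo = 0, thresholdHi = 100,
                      maxDepth = 5, maxTilt = 10, minShapePixels = 10,
                      connectivity = 8, solidityMin = 0.9,
                      sizeOutlierK = Inf, blocklist = character(0),
                      cellSize = 3, carbonDensity = 0.39,
                      restrictedDMin = 2, nBins = 12,
                      typeConvention = "anchored", epsAnchors = NULL,
                      simulate = TRUE, scene = list(), field = list(),
                      survey = list(), rendering = list()) {
  structure(as.list(environment()), class = "aggConfig")
}

#' Reference synthetic scenario
#'
#' The scenario used for ground-truth validation: a 60 x 60 m floe with one
#' ridge, aggregates with slope -3 diameters of 2--25 cm, Thomas-clustered
#' and drawn toward draft minima (realized abundance about 3 m^-2, the
#' study-wide mean), surveyed on a 5 m lawnmower grid at 1 m standoff with
#' mild sensor noise and clean rendering contrast.
#'
#' @param seed integer seed.
#' @param ... overrides for any \code{\link{aggConfig}} argument; list-valued
#'   arguments (scene, field, survey, rendering) are merged element-wise
#'   into the scenario defaults.
#' @return an \code{aggConfig}.
#' @export
referenceScenario <- function(seed = 1L, ...) {
  defaults <- list(
    station = "SYN-REF", seed = seed,
    scene = list(extent = c(60, 60), cellSize = 0.5, meanDraft = 1.2,
                 draftSd = 0.25, corrLength = 8, nRidges = 1,
                 ridgeAmp = 2.5, ridgeWidth = 4),
    field = list(intensity = 5,
                 sizeLaw = list(b = -3, dMin = 2, dMax = 25),
                 clustering = list(meanPerCluster = 8, clusterSd = 2),
                 pFilamentous = 0.3, draftAffinity = 1, tau = 2),
    survey = list(trackType = "lawnmower", speed = 0.5, frameInterval = 5,
                  nominalStandoff = 1, depthNoiseSd = 0.02,
                  altimeterNoiseSd = 0.02, tiltNoiseSd = 3,
                  positionNoiseSd = 0.5, lineSpacing = 5, margin = 2),
    rendering = list(backgroundGreenMean = 200, gradientAmp = 20,
                     noiseSd = 5, aggregateGreen = 40))
  do.call(aggConfig, utils::modifyList(defaults, list(...)))
}

#' Detect and measure aggregates in a set of QC-passed frames
#'
#' Crops each frame, applies the green-channel threshold, labels connected
#' regions, partitions them into measurable and detect-only, flags probable
#' clumps (station-wide), converts to metric units at the frame's altimeter
#' scale, and summarizes each frame.
#'
#' @param frames list of \code{\linkS4class{IceFrame}} objects (valid
#'   frames).
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @param thresholdLo,thresholdHi green bounds.
#' @param connectivity component connectivity.
#' @param minShapePixels shape-analysis pixel bound.
#' @param solidityMin,sizeOutlierK clump-flag parameters.
#' @param cropOffset crop window offset, NULL for centred.
#' @return list with \code{detections} (metric table with measurable and
#'   clump_flag columns) and \code{frameSummaries}.
#' @export
detectAggregates <- function(frames, calib = cameraCalib(),
                             thresholdLo = 0, thresholdHi = 100,
                             connectivity = 8, minShapePixels = 10,
                             solidityMin = 0.9, sizeOutlierK = Inf,
                             cropOffset = NULL) {
  detList <- vector("list", length(frames))
  sumList <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    cropped <- cropFrame(f, calib@cropSize[1], calib@cropSize[2], cropOffset)
    mask <- thresholdGreen(cropped, thresholdLo, thresholdHi)
    regions <- labelRegions(mask, connectivity, frameId = f@frameId)
    scale <- pixelScale(f@altimeter, calib)
    det <- toMetric(regions, scale)
    det$measurable <- regions$pixel_area > minShapePixels
    det$clump_flag <- rep(FALSE, nrow(det))
    detList[[k]] <- det
  }
  detections <- do.call(rbind, detList)
  # clump flagging is station-wide (the size rule needs the population)
  meas <- detections$measurable
  if (any(meas)) {
    px <- data.frame(pixel_area = detections$pixel_area[meas],
                     solidity = detections$solidity[meas])
    detections$clump_flag[meas] <- flagClumps(px, solidityMin, sizeOutlierK)
  }
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    det <- detections[detections$frame_id == f@frameId, , drop = FALSE]
    sumList[[k]] <- summarizeFrame(det, f, calib)
  }
  list(detections = detections, frameSummaries = do.call(rbind, sumList))
}

#' Validate detections against rendered ground truth
#'
#' Matches detections to rendered aggregate instances frame by frame
#' (greedy nearest-centroid within one truth radius plus a small pixel
#' margin). Recall is the matched fraction of rendered instances visible in
#' the analysis crop; precision the matched fraction of detections; the size
#' bias compares measured ECD to true diameter over matches rendered fully
#' inside the crop.
#'
#' @param detections metric detection table (crop pixel coordinates).
#' @param truth rendered-instance table from \code{\link{simulateSurvey}}.
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @param cropOffset crop offset used in detection (NULL = centred).
#' @return list: recall, precision, n_truth, n_detections, n_matched,
#'   mean_size_error (mean |ECD - d|/d over full-crop matches),
#'   median_size_error.
#' @export
validateDetections <- function(detections, truth, calib = cameraCalib(),
                               cropOffset = NULL) {
  W <- calib@nativeSize[1]; H <- calib@nativeSize[2]
  if (is.null(cropOffset))
    cropOffset <- c((W - calib@cropSize[1]) %/% 2L,
                    (H - calib@cropSize[2]) %/% 2L)
  tr <- truth[truth$pixels_in_crop > 0, , drop = FALSE]
  nMatched <- 0L
  sizeErr <- numeric(0)
  for (fid in unique(tr$frame_id)) {
    t1 <- tr[tr$frame_id == fid, , drop = FALSE]
    d1 <- detections[detections$frame_id == fid, , drop = FALSE]
    if (nrow(d1) == 0) next
    dx <- d1$centroid_x_px + cropOffset[1]
    dy <- d1$centroid_y_px + cropOffset[2]
    usedDet <- rep(FALSE, nrow(d1))
    for (r in seq_len(nrow(t1))) {
      tol <- sqrt(t1$analytic_px_area[r] / pi) + 4
      dist <- sqrt((dx - t1$cx_px[r])^2 + (dy - t1$cy_px[r])^2)
      dist[usedDet] <- Inf
      if (any(dist <= tol)) {
        jm <- which.min(dist)
        usedDet[jm] <- TRUE
        nMatched <- nMatched + 1L
        full <- t1$pixels_in_crop[r] == t1$pixels_rendered[r]
        if (full && d1$measurable[jm] && !d1$clump_flag[jm])
          sizeErr <- c(sizeErr,
                       abs(d1$ecd_cm[jm] - t1$diameter_cm[r]) /
                         t1$diameter_cm[r])
      }
    }
  }
  list(recall = if (nrow(tr)) nMatched / nrow(tr) else NA_real_,
       precision = if (nrow(detections)) nMatched / nrow(detections)
                   else NA_real_,
       n_truth = nrow(tr), n_detections = nrow(detections),
       n_matched = nMatched,
       mean_size_error = if (length(sizeErr)) mean(sizeErr) else NA_real_,
       median_size_error = if (length(sizeErr)) median(sizeErr)
                           else NA_real_)
}

#' Run the full analysis pipeline for one station
#'
#' Either simulates a synthetic survey from the configuration (scene,
#' aggregate field, ROV track, rendered frames) or analyzes supplied frames;
#' then applies frame QC, detection, metric registration, 3 x 3 m gridding,
#' the six biovolume estimators, Lloyd's patchiness on per-cell counts, the
#' full and restricted power-law size fits, optional type fractions, and --
#' when ground truth is available -- the validation harness.
#'
#' @param config an \code{\link{aggConfig}}.
#' @param frames optional list of \code{\linkS4class{IceFrame}} objects
#'   (required when \code{config$simulate} is FALSE).
#' @param truth optional ground-truth table for validation.
#' @param outDir optional artifact directory (tables, QC report, maps).
#' @return a \code{\linkS4class{StationReport}}.
#' @examples
#' \donttest{
#' rep <- runPipeline(referenceScenario(seed = 7))
#' biovolumeTable(rep)
#' }
#' @export
runPipeline <- function(config = referenceScenario(), frames = NULL,
                        truth = NULL, outDir = NULL) {
  calib <- config$calib
  if (isTRUE(config$simulate)) {
    set.seed(config$seed)
    scene <- do.call(genIceScene, config$scene)
    field <- do.call(genAggregateField, c(list(scene), config$field))
    sim <- simulateSurvey(scene, field,
                          survey = do.call(surveyParams, config$survey),
                          calib = calib,
                          rendering = do.call(renderingParams,
                                              config$rendering))
    frames <- sim$frames
    truth <- sim$truth
  } else if (is.null(frames)) {
    stop("pipeline stage 'input': no frames supplied and simulate = FALSE")
  } else {
    scene <- NULL
  }

  qc <- qcFrames(frames, config$maxDepth, config$maxTilt, config$blocklist)
  if (qc$report$n_valid == 0)
    stop("pipeline stage 'qc': no frames passed quality control")

  dres <- detectAggregates(qc$frames, calib,
                           config$thresholdLo, config$thresholdHi,
                           config$connectivity, config$minShapePixels,
                           config$solidityMin, config$sizeOutlierK)
  detections <- dres$detections
  fsum <- dres$frameSummaries

  cellMap <- assignFrames(fsum, config$cellSize)
  grid <- gridAverage(fsum, cellMap, detections)
  grid <- roughnessFromDraft(grid)

  biov <- estimateBiovolume("all", detections, fsum, grid,
                            config$carbonDensity)

  cellCounts <- round(grid$abundance * config$cellSize^2)
  patch <- if (nrow(grid) >= 2 && mean(cellCounts) > 0)
    lloydPatchiness(cellCounts) else list()

  sdet <- detections[detections$measurable & !detections$clump_flag, ,
                     drop = FALSE]
  medStandoff <- median(fsum$altimeter_m)
  dMinFull <- 3 * pixelScale(medStandoff, calib) * 100   # cm
  fitFull <- tryCatch(
    fitSizeDistribution(sdet$ecd_cm, dMin = dMinFull, nBins = config$nBins),
    error = function(e) NULL)
  fitRestr <- tryCatch(
    fitSizeDistribution(sdet$ecd_cm, dMin = config$restrictedDMin,
                        nBins = config$nBins),
    error = function(e) NULL)
  sizeFits <- Filter(Negate(is.null),
                     list(full = fitFull, restricted = fitRestr))

  tfrac <- NULL
  if (!is.null(config$epsAnchors) && nrow(sdet)) {
    epsStation <- mean(sdet$eccentricity, na.rm = TRUE)
    tfrac <- tryCatch(
      as.list(typeFractions(epsStation, config$epsAnchors[1],
                            config$epsAnchors[2], config$typeConvention)),
      error = function(e) NULL)
  }

  valid <- if (!is.null(truth) && nrow(truth))
    validateDetections(detections, truth, calib) else NULL
  if (isTRUE(config$simulate) && !is.null(valid)) {
    # ground truth for end-to-end parameter-recovery checks
    valid$true_field <- field
    valid$truth_table <- truth
    valid$true_intensity_per_m2 <- nrow(field) / prod(scene@extent)
    valid$scene_extent <- scene@extent
  }

  report <- new("StationReport", station = config$station,
                frameSummaries = fsum, detections = detections, grid = grid,
                biovolume = biov, patchiness = patch, sizeFits = sizeFits,
                typeFractions = tfrac, qc = qc$report, validation = valid,
                config = unclass(config)[setdiff(names(config), "calib")])
  if (!is.null(outDir)) {
    writeStationReport(report, outDir)
    if (nrow(grid) > 1) {
      plotGridMap(grid, "abundance",
                  file.path(outDir, "map_abundance.png"))
      plotGridMap(grid, "mean_draft_m", file.path(outDir, "map_draft.png"))
      if (any(is.finite(grid$roughness_m)))
        plotGridMap(grid, "roughness_m",
                    file.path(outDir, "map_roughness.png"))
    }
  }
  report
}

#' Compare two station reports of the same floe
#'
#' Per-method percent biovolume loss between an early and a late sampling,
#' plus the station-level abundance and median-diameter changes.
#'
#' @param early,late \code{\linkS4class{StationReport}} objects produced
#'   with the same method set.
#' @return list with \code{byMethod} (method, V_early, V_late, loss_pct,
#'   carbon_early, carbon_late), \code{abundance} (early, late) and
#'   \code{median_ecd_cm} (early, late).
#' @export
compareStations <- function(early, late) {
  be <- early@biovolume; bl <- late@biovolume
  if (!identical(be$method, bl$method))
    stop("method sets differ between the two reports")
  byMethod <- data.frame(
    method = be$method, V_early = be$V_ml_m2, V_late = bl$V_ml_m2,
    loss_pct = biomassChange(be$V_ml_m2, bl$V_ml_m2),
    carbon_early = be$carbon_mg_m2, carbon_late = bl$carbon_mg_m2,
    stringsAsFactors = FALSE)
  medE <- function(r) {
    s <- r@detections[r@detections$measurable & !r@detections$clump_flag, ]
    if (nrow(s)) median(s$ecd_cm) else NA_real_
  }
  list(byMethod = byMethod,
       abundance = c(early = mean(early@frameSummaries$abundance),
                     late = mean(late@frameSummaries$abundance)),
       median_ecd_cm = c(early = medE(early), late = medE(late)))
}
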