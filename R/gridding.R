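# Floe-fixed gridding: frame-level results are averaged onto a regular
# 3 x 3 m raster (the maximal uncertainty of the ROV position) so that areas
# sampled repeatedly by overlapping dive tracks do not dominate station
# statistics. Cells never visited are absent, not zero: absence of
# observation is not absence of aggregates.

#' Assign frames to grid cells
#'
#' Cells are half-open squares \code{[lo, hi)} of side \code{cellSize};
#' a frame belongs to the cell containing its centre (nadir) point.
#'
#' @param frameSummaries data.frame with floe-fixed \code{x_m}, \code{y_m}
#'   columns (as from \code{\link{summarizeFrame}}).
#' @param cellSize grid cell size, m (default 3).
#' @param origin numeric(2) grid origin; NULL uses the minimum observed x/y.
#' @return data.frame frame_id, i, j (integer cell indices) with the origin
#'   stored in attribute \code{origin} for reproducibility.
#' @export
assignFrames <- function(frameSummaries, cellSize = 3, origin = NULL) {
  if (is.null(origin))
    origin <- c(min(frameSummaries$x_m), min(frameSummaries$y_m))
  structure(
    data.frame(frame_id = frameSummaries$frame_id,
               i = as.integer(floor((frameSummaries$x_m - origin[1]) / cellSize)),
               j = as.integer(floor((frameSummaries$y_m - origin[2]) / cellSize)),
               stringsAsFactors = FALSE),
    origin = origin, cellSize = cellSize)
}

#' Average frame summaries within grid cells
#'
#' Per occupied cell, frame-level quantities (abundance, coverage, draft,
#' eccentricity, ...) are arithmetic means over the frames in the cell --
#' duplicating a frame inside its cell therefore changes nothing, which is
#' the multiple-sampling robustness the grid exists for. Diameter statistics
#' instead pool the individual measurable, unflagged aggregates of all
#' frames in the cell.
#'
#' @param frameSummaries data.frame from \code{\link{summarizeFrame}} rows.
#' @param cellMap data.frame from \code{\link{assignFrames}}.
#' @param detections optional metric detection data.frame (with
#'   \code{measurable} and \code{clump_flag}); needed for cell diameter
#'   statistics.
#' @return data.frame with one row per occupied cell: i, j, x_center_m,
#'   y_center_m, n_frames, abundance, coverage, mean_draft_m, mean_ecd_cm,
#'   median_ecd_cm, mean_eccentricity, n_aggregates, n_measurable.
#' @export
gridAverage <- function(frameSummaries, cellMap, detections = NULL) {
  origin <- attr(cellMap, "origin")
  cellSize <- attr(cellMap, "cellSize")
  if (is.null(cellSize)) cellSize <- 3
  if (is.null(origin)) origin <- c(0, 0)
  fs <- merge(frameSummaries, cellMap, by = "frame_id")
  key <- paste(fs$i, fs$j, sep = ":")
  cells <- split(fs, key)
  det <- NULL
  if (!is.null(detections) && nrow(detections)) {
    det <- merge(detections, cellMap, by = "frame_id")
    det <- det[det$measurable & !det$clump_flag, , drop = FALSE]
    detKey <- paste(det$i, det$j, sep = ":")
    detByCell <- split(det$ecd_cm, detKey)
  } else detByCell <- list()
  out <- lapply(cells, function(cf) {
    k <- paste(cf$i[1], cf$j[1], sep = ":")
    ecds <- detByCell[[k]]
    data.frame(
      i = cf$i[1], j = cf$j[1],
      x_center_m = origin[1] + (cf$i[1] + 0.5) * cellSize,
      y_center_m = origin[2] + (cf$j[1] + 0.5) * cellSize,
      n_frames = nrow(cf),
      abundance = mean(cf$abundance),
      coverage = mean(cf$coverage),
      mean_draft_m = mean(cf$draft_m, na.rm = TRUE),
      mean_ecd_cm = if (length(ecds)) mean(ecds) else NA_real_,
      median_ecd_cm = if (length(ecds)) median(ecds) else NA_real_,
      mean_eccentricity = if (any(!is.na(cf$mean_eccentricity)))
        mean(cf$mean_eccentricity, na.rm = TRUE) else NA_real_,
      n_aggregates = sum(cf$n_aggregates),
      n_measurable = length(ecds),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "origin") <- origin
  attr(res, "cellSize") <- cellSize
  res
}

#' Windowed roughness from cell drafts
#'
#' Sample standard deviation of the draft values within a window (by default
#' a cell and its 8 neighbours). Requires at least two draft samples.
#'
#' @param grid data.frame from \code{\link{gridAverage}} (uses i, j,
#'   mean_draft_m).
#' @param window odd window size in cells (default 3: the 3 x 3
#'   neighbourhood).
#' @return the grid with a \code{roughness_m} column added (NA where fewer
#'   than two draft samples fall in the window).
#' @export
roughnessFromDraft <- function(grid, window = 3) {
  half <- (window - 1) %/% 2
  rough <- vapply(seq_len(nrow(grid)), function(r) {
    sel <- abs(grid$i - grid$i[r]) <= half & abs(grid$j - grid$j[r]) <= half
    v <- grid$mean_draft_m[sel]
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v)
  }, numeric(1))
  grid$roughness_m <- rough
  grid
}
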