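# Frame, navigation and reference-table input/output. Frames travel as 8-bit
# RGB PNGs with a navigation CSV (frame_id, t_s, depth_m, tilt_deg,
# altimeter_m, x_m, y_m); reports as CSV/JSON.

#' Write frames as PNG files plus a navigation CSV
#'
#' @param frames list of \code{\linkS4class{IceFrame}} objects with pixels.
#' @param dir output directory (created if absent).
#' @return invisibly, the navigation table written to \code{dir/nav.csv}.
#' @export
writeFrames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (f in frames) {
    if (!length(f@pixels)) next
    png::writePNG(f@pixels / 255, file.path(dir, paste0(f@frameId, ".png")))
  }
  nav <- navTable(frames)
  write.csv(nav, file.path(dir, "nav.csv"), row.names = FALSE)
  invisible(nav)
}

#' Read frames from a directory of PNGs and a navigation CSV
#'
#' @param dir directory holding \code{<frame_id>.png} files and
#'   \code{nav.csv}.
#' @param navFile navigation CSV path (default \code{dir/nav.csv}).
#' @return list of \code{\linkS4class{IceFrame}} objects.
#' @export
readFrames <- function(dir, navFile = file.path(dir, "nav.csv")) {
  nav <- read.csv(navFile, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(nav)), function(i) {
    p <- file.path(dir, paste0(nav$frame_id[i], ".png"))
    pix <- if (file.exists(p)) {
      a <- png::readPNG(p)
      if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
      round(a[, , 1:3, drop = FALSE] * 255)
    } else array(numeric(0), c(0, 0, 3))
    iceFrame(pixels = pix, frameId = nav$frame_id[i], t = nav$t_s[i],
             depth = nav$depth_m[i], tilt = nav$tilt_deg[i],
             altimeter = nav$altimeter_m[i], x = nav$x_m[i], y = nav$y_m[i])
  })
}

#' Published station summaries of the 2012 central-Arctic ROV survey
#'
#' Station-level aggregate properties from the published August--September
#' 2012 icebreaker survey of under-ice algal aggregates at eight Arctic ice
#' stations (ICE-1 ... ICE-9; ICE-1 and ICE-9 are the same floe sampled
#' seven weeks apart): position, percent aggregate coverage, abundance,
#' median and mean ECD, circularity, eccentricity, Lloyd's index of
#' patchiness, and the full and restricted (diameter > 2 cm) power-law
#' slopes with their low-R^2 flag.
#'
#' @return data.frame, one row per station.
#' @export
referenceStations <- function() {
  read.csv(system.file("extdata", "icearc2012_stations.csv",
                       package = "icefloc"), stringsAsFactors = FALSE,
           check.names = FALSE)
}

#' Published biovolume and carbon estimates of the 2012 survey
#'
#' The published method-comparison table: aggregate biovolume (ml m^-2) and
#' carbon content (mg C m^-2) per station for the six estimation approaches,
#' plus the printed row means. Cells the published table reports only as
#' "<0.01" are encoded as 0.005 (no row graded against that bound uses
#' them).
#'
#' @return data.frame in long-ish form: block (volume_ml_m2 or
#'   carbon_mg_m2), method, one column per station, and the printed Mean.
#' @export
referenceBiovolume <- function() {
  read.csv(system.file("extdata", "icearc2012_biovolume.csv",
                       package = "icefloc"), stringsAsFactors = FALSE,
           check.names = FALSE)
}

#' Write a station report's tables and QC block to disk
#'
#' @param report a \code{\linkS4class{StationReport}}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeStationReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(report@frameSummaries, file.path(dir, "frame_summaries.csv"),
            row.names = FALSE)
  write.csv(report@detections, file.path(dir, "detections.csv"),
            row.names = FALSE)
  write.csv(report@grid, file.path(dir, "grid_cells.csv"), row.names = FALSE)
  write.csv(report@biovolume, file.path(dir, "biovolume.csv"),
            row.names = FALSE)
  valid <- report@validation
  if (!is.null(valid))
    valid <- valid[setdiff(names(valid), c("true_field", "truth_table"))]
  stats <- list(patchiness = report@patchiness,
                sizeFits = lapply(report@sizeFits, function(f)
                  f[c("b", "c", "r2", "dMin", "n", "flagged", "method")]),
                typeFractions = report@typeFractions,
                validation = valid)
  jsonlite::write_json(stats, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(report@qc[setdiff(names(report@qc), "reasons")],
                       file.path(dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot floe-scale maps of a gridded quantity
#'
#' Draws the occupied grid cells coloured by one variable, mirroring the
#' habitat-map layout of floe-scale survey figures.
#'
#' @param grid data.frame from \code{\link{gridAverage}}.
#' @param variable column to plot (default "abundance").
#' @param file optional PNG path; NULL plots to the active device.
#' @param main plot title.
#' @return invisibly NULL.
#' @export
plotGridMap <- function(grid, variable = "abundance", file = NULL,
                        main = variable) {
  if (!is.null(file)) grDevices::png(file, 800, 700)
  v <- grid[[variable]]
  pal <- grDevices::hcl.colors(32, "viridis")
  col <- pal[cut(v, breaks = 32, labels = FALSE, include.lowest = TRUE)]
  cs <- attr(grid, "cellSize"); if (is.null(cs)) cs <- 3
  plot(NA, xlim = range(grid$x_center_m) + c(-cs, cs),
       ylim = range(grid$y_center_m) + c(-cs, cs),
       xlab = "x (m)", ylab = "y (m)", main = main, asp = 1)
  graphics::rect(grid$x_center_m - cs / 2, grid$y_center_m - cs / 2,
                 grid$x_center_m + cs / 2, grid$y_center_m + cs / 2,
                 col = col, border = NA)
  if (!is.null(file)) grDevices::dev.off()
  invisible(NULL)
}
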