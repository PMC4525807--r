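# Shared fixtures: pixel-geometry builders and one cached reference-scenario
# pipeline run (expensive, reused across test files).

# logical mask with one filled ellipse (image coordinates, y down)
ellipseMask <- function(ny, nx, cy, cx, a, b, theta = 0) {
  cc <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  rr <- matrix(seq_len(ny), ny, nx)
  dx <- cc - cx; dy <- rr - cy
  ((dx * cos(theta) + dy * sin(theta)) / a)^2 +
    ((-dx * sin(theta) + dy * cos(theta)) / b)^2 <= 1
}

diskMask <- function(ny, nx, cy, cx, r) ellipseMask(ny, nx, cy, cx, r, r)

# an RGB frame whose green channel is `bg` except `fg` inside the mask
maskFrame <- function(mask, fg = 40, bg = 200) {
  g <- matrix(bg, nrow(mask), ncol(mask))
  g[mask] <- fg
  pix <- array(0, c(nrow(mask), ncol(mask), 3))
  pix[, , 1] <- g; pix[, , 2] <- g; pix[, , 3] <- g
  pix
}

navFrame <- function(id = "f1", depth = 2, tilt = 0, altimeter = 1,
                     x = 0, y = 0, pixels = array(numeric(0), c(0, 0, 3))) {
  iceFrame(pixels = pixels, frameId = id, t = 0, depth = depth, tilt = tilt,
           altimeter = altimeter, x = x, y = y)
}

# a hand-built frame-summary row (the summarizeFrame output dialect)
fsRow <- function(id, x, y, abundance = 1, coverage = 0.01, draft = 1,
                  n = 1, footprint = 1, meanEcd = NA_real_,
                  medianEcd = NA_real_) {
  data.frame(frame_id = id, t_s = 0, depth_m = 2, tilt_deg = 0,
             altimeter_m = 1, x_m = x, y_m = y, draft_m = draft,
             footprint_m2 = footprint, n_aggregates = n,
             abundance = abundance, coverage = coverage,
             mean_ecd_cm = meanEcd, median_ecd_cm = medianEcd,
             mean_eccentricity = NA_real_, mean_circularity = NA_real_,
             stringsAsFactors = FALSE)
}

# a hand-built metric detection row
detRow <- function(id, frame, ecd, measurable = TRUE, flag = FALSE) {
  data.frame(frame_id = frame, region_id = id, area_m2 = pi * (ecd / 200)^2,
             perimeter_m = pi * ecd / 100, ecd_cm = ecd, major_cm = ecd,
             minor_cm = ecd, eccentricity = 0, circularity = 1,
             orientation_rad = 0, centroid_x_px = 0, centroid_y_px = 0,
             pixel_area = 100, solidity = 1, measurable = measurable,
             clump_flag = flag, stringsAsFactors = FALSE)
}

# aggregate counts on a full grid (zero cells included) for patchiness tests
countsOnGrid <- function(x, y, extent, cell) {
  nx <- ceiling(extent[1] / cell); ny <- ceiling(extent[2] / cell)
  i <- pmin(floor(x / cell), nx - 1); j <- pmin(floor(y / cell), ny - 1)
  tab <- table(factor(i + nx * j, levels = 0:(nx * ny - 1)))
  as.numeric(tab)
}

# gridded_median / raster_cells recomputed from the rendered-instance ground
# truth over the same frames and cells: what a perfect detector and
# measurer would have reported for the surveyed footprints
truthGridEstimates <- function(rep) {
  fsum <- frameSummaries(rep)
  tr <- rep@validation$truth_table
  tr <- tr[tr$pixels_in_crop > 0, , drop = FALSE]
  map <- assignFrames(fsum, 3)
  nByFrame <- table(factor(tr$frame_id, levels = fsum$frame_id))
  abund <- as.numeric(nByFrame) / fsum$footprint_m2
  fsm <- merge(data.frame(frame_id = fsum$frame_id, abundance = abund),
               map, by = "frame_id")
  keyA <- paste(fsm$i, fsm$j, sep = ":")
  cellA <- tapply(fsm$abundance, keyA, mean)
  mrg <- merge(tr, map, by = "frame_id")
  cellD <- split(mrg$diameter_cm, paste(mrg$i, mrg$j, sep = ":"))
  ks <- names(cellA)
  medD <- vapply(ks, function(k)
    if (!is.null(cellD[[k]])) median(cellD[[k]]) else NA_real_, numeric(1))
  meanD <- vapply(ks, function(k)
    if (!is.null(cellD[[k]])) mean(cellD[[k]]) else NA_real_, numeric(1))
  list(gridded_median = mean(cellA) *
         sphereVolume(mean(medD, na.rm = TRUE)),
       raster_cells = mean(ifelse(is.na(meanD), 0,
                                  cellA * sphereVolume(meanD))))
}

# cached reference-scenario run (fixed test seed)
refRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- referenceScenario(seed = 101)
      cache <<- runPipeline(cfg)
    }
    cache
  }
})
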