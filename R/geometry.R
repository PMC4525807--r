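# Metric registration: pixel measurements are converted to real units using
# the altimeter distance to the ice and the laboratory camera calibration,
# then summarized per frame. Units follow the survey convention: areas m^2,
# aggregate lengths cm, volumes ml (cm^3) per m^2.

#' Metric scale of a frame from the altimeter distance
#'
#' Pinhole model with a single calibration constant: the pixel pitch grows
#' linearly with the distance to the ice, \code{k} mm per pixel per metre of
#' standoff (about 4.5 mm per pixel at 1 m).
#'
#' @param distance altimeter distance to the ice underside, m (vectorized).
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @return metres per pixel.
#' @examples
#' pixelScale(1, cameraCalib())    # 0.0045 m/px
#' @export
pixelScale <- function(distance, calib = cameraCalib()) {
  if (any(distance <= 0)) stop("altimeter distance must be positive")
  calib@k * distance / 1000
}

#' Ice draft from ROV depth and altimeter distance
#'
#' Draft (depth of the ice underside below the water surface) is the ROV
#' depth minus its measured distance to the ice. Sensor noise can invert the
#' difference; negative drafts are clipped to zero and counted.
#'
#' @param depth ROV depth, m (vectorized).
#' @param distance altimeter distance to the ice, m.
#' @return numeric vector of drafts (m) with attribute \code{n_clipped}, the
#'   number of negative differences clipped to 0.
#' @examples
#' iceDraft(2.5, 1.0)   # 1.5 m
#' @export
iceDraft <- function(depth, distance) {
  if (any(depth < 0, na.rm = TRUE) || any(distance < 0, na.rm = TRUE))
    stop("depth and distance must be non-negative")
  d <- depth - distance
  nClip <- sum(d < 0, na.rm = TRUE)
  if (nClip > 0)
    warning(nClip, " negative draft value(s) clipped to 0")
  structure(pmax(d, 0), n_clipped = nClip)
}

#' Convert pixel-space region measurements to metric aggregate detections
#'
#' Applies the per-frame metric scale: areas scale with the square of the
#' pixel pitch, lengths linearly. Dimensionless descriptors follow the
#' standard definitions: equivalent circular diameter d = 2 sqrt(A / pi),
#' eccentricity = sqrt(1 - (minor / major)^2), circularity =
#' 4 pi A / P^2. Regions without an ellipse fit keep area, ECD and
#' circularity but no axis-derived fields.
#'
#' @param regions data.frame from \code{\link{labelRegions}} (optionally with
#'   columns \code{measurable} and \code{clump_flag} already attached).
#' @param scale metric scale of the frame, m per pixel.
#' @return data.frame with columns frame_id, region_id, area_m2,
#'   perimeter_m, ecd_cm, major_cm, minor_cm, eccentricity, circularity,
#'   orientation_rad, centroid_x_px, centroid_y_px, pixel_area, solidity.
#' @export
toMetric <- function(regions, scale) {
  if (length(scale) != 1 || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive scalar (m per pixel)")
  area <- regions$pixel_area * scale^2
  per <- regions$pixel_perimeter * scale
  ecd <- 2 * sqrt(area / pi) * 100
  major <- regions$major_axis_px * scale * 100
  minor <- regions$minor_axis_px * scale * 100
  ecc <- sqrt(pmax(1 - (minor / major)^2, 0))
  circ <- ifelse(per > 0, 4 * pi * area / per^2, NA_real_)
  data.frame(frame_id = regions$frame_id, region_id = regions$region_id,
             area_m2 = area, perimeter_m = per, ecd_cm = ecd,
             major_cm = major, minor_cm = minor, eccentricity = ecc,
             circularity = circ,
             orientation_rad = regions$orientation_rad,
             centroid_x_px = regions$centroid_x_px,
             centroid_y_px = regions$centroid_y_px,
             pixel_area = regions$pixel_area,
             solidity = regions$solidity,
             stringsAsFactors = FALSE)
}

#' Summarize detections of one frame
#'
#' The image footprint is the metric area of the analysis crop at the
#' frame's altimeter distance; abundance is the number of detected
#' aggregates divided by that footprint, and coverage the summed aggregate
#' area as a fraction of it. All detections (including clump-flagged and
#' detect-only regions) count toward abundance and coverage; size and shape
#' statistics use measurable, unflagged detections only.
#'
#' @param detections metric detection data.frame for this frame, with
#'   logical columns \code{measurable} and \code{clump_flag}.
#' @param frame the \code{\linkS4class{IceFrame}} (for altimeter and id).
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @return one-row data.frame: frame_id, t_s, depth_m, tilt_deg,
#'   altimeter_m, x_m, y_m, draft_m, footprint_m2, n_aggregates, abundance
#'   (aggregates per m^2), coverage (fraction), mean_ecd_cm, median_ecd_cm,
#'   mean_eccentricity, mean_circularity.
#' @export
summarizeFrame <- function(detections, frame, calib = cameraCalib()) {
  scale <- pixelScale(frame@altimeter, calib)
  footprint <- (calib@cropSize[1] * scale) * (calib@cropSize[2] * scale)
  if (footprint <= 0) stop("zero frame footprint")
  n <- nrow(detections)
  coverage <- if (n) sum(detections$area_m2) / footprint else 0
  sizeSel <- if (n) detections$measurable & !detections$clump_flag
             else logical(0)
  sdet <- detections[sizeSel, , drop = FALSE]
  draft <- suppressWarnings(as.numeric(iceDraft(frame@depth, frame@altimeter)))
  data.frame(
    frame_id = frame@frameId, t_s = frame@t, depth_m = frame@depth,
    tilt_deg = frame@tilt, altimeter_m = frame@altimeter,
    x_m = frame@x, y_m = frame@y, draft_m = draft,
    footprint_m2 = footprint, n_aggregates = n,
    abundance = n / footprint, coverage = coverage,
    mean_ecd_cm = if (nrow(sdet)) mean(sdet$ecd_cm) else NA_real_,
    median_ecd_cm = if (nrow(sdet)) median(sdet$ecd_cm) else NA_real_,
    mean_eccentricity = if (nrow(sdet))
      mean(sdet$eccentricity, na.rm = TRUE) else NA_real_,
    mean_circularity = if (nrow(sdet))
      mean(sdet$circularity, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
}
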