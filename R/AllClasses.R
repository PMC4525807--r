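#' @import methods
#' @importFrom stats rnorm runif rpois median sd var lm coef cor.test mad optimize residuals
#' @importFrom utils read.csv write.csv modifyList
#' @importFrom graphics plot rect
NULL

#' Ice scene: gridded physical habitat fields of an ice floe underside
#'
#' An \code{IceScene} holds co-registered raster fields of ice draft (m,
#' positive down), small-scale ice roughness (m, the windowed standard
#' deviation of draft) and light transmittance (dimensionless, 0--1) over a
#' rectangular floe-fixed extent. Matrices are indexed \code{[iy, ix]} with
#' cell centers at \code{origin + (i - 0.5) * cellSize}.
#'
#' @slot extent numeric(2), floe-fixed x/y extent in metres (the scene spans
#'   \code{[0, extent[1]] x [0, extent[2]]}).
#' @slot cellSize numeric(1), raster cell size in metres.
#' @slot draft matrix of ice draft (m, >= 0).
#' @slot roughness matrix of windowed draft standard deviation (m, >= 0).
#' @slot transmittance matrix of light transmittance in [0, 1].
#'
#' @seealso \code{\link{genIceScene}}
#' @export
setClass("IceScene",
  representation(
    extent = "numeric",
    cellSize = "numeric",
    draft = "matrix",
    roughness = "matrix",
    transmittance = "matrix"
  )
)

setValidity("IceScene", function(object) {
  msg <- character()
  if (length(object@extent) != 2 || any(object@extent <= 0))
    msg <- c(msg, "extent must be two positive lengths (m)")
  if (length(object@cellSize) != 1 || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a positive scalar (m)")
  dims <- dim(object@draft)
  if (!identical(dims, dim(object@roughness)) ||
      !identical(dims, dim(object@transmittance)))
    msg <- c(msg, "draft, roughness and transmittance must share one shape")
  if (any(object@draft < 0)) msg <- c(msg, "draft must be >= 0 everywhere")
  if (any(object@roughness < 0)) msg <- c(msg, "roughness must be >= 0")
  if (any(object@transmittance < 0 | object@transmittance > 1))
    msg <- c(msg, "transmittance must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn IceScene-class dimensions of the raster fields (ny, nx).
#' @param x,object an \code{IceScene}.
#' @export
setMethod("dim", "IceScene", function(x) dim(x@draft))

setMethod("show", "IceScene", function(object) {
  d <- dim(object)
  cat("IceScene:", object@extent[1], "x", object@extent[2], "m at",
      object@cellSize, "m resolution (", d[2], "x", d[1], "cells )\n")
  cat("  draft: mean", signif(mean(object@draft), 3), "m, max",
      signif(max(object@draft), 3), "m\n")
  cat("  transmittance: mean", signif(mean(object@transmittance), 3), "\n")
})

#' @describeIn IceScene-class ice-draft field accessor.
#' @export
sceneDraft <- function(x) x@draft

#' @describeIn IceScene-class roughness field accessor.
#' @export
sceneRoughness <- function(x) x@roughness

#' @describeIn IceScene-class transmittance field accessor.
#' @export
sceneTransmittance <- function(x) x@transmittance

#' @describeIn IceScene-class scene extent accessor (m).
#' @export
sceneExtent <- function(x) x@extent

#' Camera calibration for upward-looking under-ice imagery
#'
#' A pinhole camera reduced to a single laboratory calibration constant
#' \code{k}: the pixel pitch in millimetres per pixel per metre of standoff
#' distance to the ice. The default \code{k = 4.5} gives the nominal 4--5 mm
#' resolution of a standard-definition under-ice camera at 1 m distance.
#'
#' @slot k mm per pixel per metre of standoff (> 0).
#' @slot nativeSize integer(2), native frame width x height in pixels.
#' @slot cropSize integer(2), analysis crop width x height in pixels.
#' @export
setClass("CameraCalib",
  representation(k = "numeric", nativeSize = "integer", cropSize = "integer")
)

setValidity("CameraCalib", function(object) {
  msg <- character()
  if (length(object@k) != 1 || object@k <= 0) msg <- c(msg, "k must be > 0")
  if (length(object@nativeSize) != 2 || any(object@nativeSize <= 0))
    msg <- c(msg, "nativeSize must be two positive integers")
  if (length(object@cropSize) != 2 || any(object@cropSize <= 0))
    msg <- c(msg, "cropSize must be two positive integers")
  if (any(object@cropSize > object@nativeSize))
    msg <- c(msg, "cropSize cannot exceed nativeSize")
  if (length(msg)) msg else TRUE
})

#' Construct a camera calibration
#'
#' @param k pixel pitch, mm per pixel per metre of standoff.
#' @param nativeSize native frame size, c(width, height) in pixels.
#' @param cropSize analysis crop size, c(width, height) in pixels.
#' @return a \code{\linkS4class{CameraCalib}}.
#' @examples
#' cameraCalib()           # 4.5 mm px^-1 at 1 m, 384x288 frames, 250x200 crop
#' @export
cameraCalib <- function(k = 4.5, nativeSize = c(384L, 288L),
                        cropSize = c(250L, 200L)) {
  new("CameraCalib", k = as.numeric(k),
      nativeSize = as.integer(nativeSize), cropSize = as.integer(cropSize))
}

setMethod("show", "CameraCalib", function(object) {
  cat("CameraCalib: k =", object@k, "mm px^-1 m^-1; native",
      paste(object@nativeSize, collapse = "x"), "px; crop",
      paste(object@cropSize, collapse = "x"), "px\n")
})

#' A single upward-looking camera frame with navigation metadata
#'
#' Pixels are stored as a numeric array \code{[row, col, channel]} with 8-bit
#' values in 0--255 (channels R, G, B); the array may be empty (0 x 0 x 3)
#' for frames whose geometry is known but whose pixels have not been rendered
#' or loaded. Rows run top to bottom, columns left to right; (x, y) is the
#' floe-fixed position of the frame centre (nadir point) in metres.
#'
#' @slot pixels numeric array H x W x 3 in [0, 255].
#' @slot frameId character frame identifier.
#' @slot t capture time, s.
#' @slot depth ROV depth, m (NA when navigation dropped out).
#' @slot tilt ROV tilt, degrees.
#' @slot altimeter distance to the ice underside, m.
#' @slot x,y floe-fixed position, m.
#' @export
setClass("IceFrame",
  representation(
    pixels = "array", frameId = "character", t = "numeric",
    depth = "numeric", tilt = "numeric", altimeter = "numeric",
    x = "numeric", y = "numeric"
  )
)

setValidity("IceFrame", function(object) {
  msg <- character()
  p <- object@pixels
  if (length(dim(p)) != 3 || dim(p)[3] != 3)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  if (length(p) && (min(p) < 0 || max(p) > 255))
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(msg)) msg else TRUE
})

#' Construct an IceFrame
#'
#' @param pixels H x W x 3 numeric array in [0, 255] (may be empty).
#' @param frameId frame identifier.
#' @param t capture time (s).
#' @param depth ROV depth (m).
#' @param tilt ROV tilt (deg).
#' @param altimeter distance to the ice (m).
#' @param x,y floe-fixed frame-centre position (m).
#' @return an \code{\linkS4class{IceFrame}}.
#' @export
iceFrame <- function(pixels = array(numeric(0), c(0, 0, 3)),
                     frameId = "f1", t = 0, depth = NA_real_,
                     tilt = NA_real_, altimeter = NA_real_,
                     x = NA_real_, y = NA_real_) {
  new("IceFrame", pixels = pixels, frameId = as.character(frameId),
      t = as.numeric(t), depth = as.numeric(depth), tilt = as.numeric(tilt),
      altimeter = as.numeric(altimeter), x = as.numeric(x), y = as.numeric(y))
}

setMethod("show", "IceFrame", function(object) {
  d <- dim(object@pixels)
  cat("IceFrame", object@frameId, ":", d[2], "x", d[1], "px; depth",
      object@depth, "m; tilt", object@tilt, "deg; altimeter",
      object@altimeter, "m; (x, y) = (", object@x, ",", object@y, ") m\n")
})

#' Navigation table of a list of frames
#'
#' @param frames list of \code{\linkS4class{IceFrame}} objects.
#' @return data.frame with columns frame_id, t_s, depth_m, tilt_deg,
#'   altimeter_m, x_m, y_m (the navigation CSV dialect).
#' @export
navTable <- function(frames) {
  data.frame(
    frame_id = vapply(frames, function(f) f@frameId, character(1)),
    t_s = vapply(frames, function(f) f@t, numeric(1)),
    depth_m = vapply(frames, function(f) f@depth, numeric(1)),
    tilt_deg = vapply(frames, function(f) f@tilt, numeric(1)),
    altimeter_m = vapply(frames, function(f) f@altimeter, numeric(1)),
    x_m = vapply(frames, function(f) f@x, numeric(1)),
    y_m = vapply(frames, function(f) f@y, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Station-level analysis report
#'
#' The end product of \code{\link{runPipeline}}: per-frame summaries, the
#' floe-fixed grid, the six biovolume/carbon estimates, patchiness and
#' size-distribution statistics, quality-control counts, and (for synthetic
#' surveys) a validation block against ground truth.
#'
#' @slot station character station label.
#' @slot frameSummaries data.frame of per-frame summaries.
#' @slot detections data.frame of metric per-aggregate detections.
#' @slot grid data.frame of 3 x 3 m grid-cell averages.
#' @slot biovolume data.frame of method-tagged biovolume/carbon estimates.
#' @slot patchiness list: m, mStar, P (Lloyd's index).
#' @slot sizeFits list of size-distribution fits (full, restricted).
#' @slot typeFractions list or NULL.
#' @slot qc list of quality-control counts and reasons.
#' @slot validation list or NULL (recall, precision, size bias).
#' @slot config list, the resolved run configuration.
#' @export
setClass("StationReport",
  representation(
    station = "character", frameSummaries = "data.frame",
    detections = "data.frame", grid = "data.frame",
    biovolume = "data.frame", patchiness = "list", sizeFits = "list",
    typeFractions = "ANY", qc = "list", validation = "ANY", config = "list"
  )
)

setMethod("show", "StationReport", function(object) {
  cat("StationReport:", object@station, "\n")
  cat("  frames:", nrow(object@frameSummaries), "valid /",
      object@qc$n_input, "input;", nrow(object@detections), "detections;",
      nrow(object@grid), "occupied 3x3 m cells\n")
  if (nrow(object@biovolume)) {
    cat("  biovolume (ml m^-2):",
        paste(sprintf("%s=%.2f", object@biovolume$method,
                      object@biovolume$V_ml_m2), collapse = ", "), "\n")
  }
  if (length(object@patchiness))
    cat("  Lloyd's P =", signif(object@patchiness$P, 3), "\n")
  if (!is.null(object@validation))
    cat("  validation: recall", signif(object@validation$recall, 3),
        "precision", signif(object@validation$precision, 3), "\n")
})

#' @describeIn StationReport-class biovolume estimate table accessor.
#' @param x a \code{StationReport}.
#' @export
biovolumeTable <- function(x) x@biovolume

#' @describeIn StationReport-class per-frame summary table accessor.
#' @export
frameSummaries <- function(x) x@frameSummaries

#' @describeIn StationReport-class metric detection table accessor.
#' @export
detectionTable <- function(x) x@detections

#' @describeIn StationReport-class grid-cell table accessor.
#' @export
gridTable <- function(x) x@grid
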