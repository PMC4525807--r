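# Biovolume and carbon estimation. Each aggregate is represented by a
# compact sphere of its equivalent circular diameter; station biovolume per
# unit ice area follows V = a * (4/3) pi (d/2)^3 with abundance a
# (aggregates m^-2) and diameter d (cm), evaluated under six different
# averaging schemes whose spread measures the estimation uncertainty.
# Carbon derives from the measured aggregate carbon density of
# 390 mg C per litre.

#' Volume of a spherical aggregate
#'
#' @param d equivalent circular diameter, cm (vectorized).
#' @return volume in ml (cm^3): (4/3) pi (d/2)^3.
#' @examples
#' sphereVolume(2)    # 4.18879 ml
#' @export
sphereVolume <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("diameter must be non-negative")
  (4 / 3) * pi * (d / 2)^3
}

#' Convert biovolume to carbon content
#'
#' @param V biovolume, ml per m^2.
#' @param carbonDensity aggregate carbon density, mg C per ml (default 0.39,
#'   i.e. 390 mg C per litre, measured on aggregates of known volume).
#' @return carbon content, mg C per m^2.
#' @examples
#' carbonFromVolume(21.9)   # 8.541 mg C m^-2
#' @export
carbonFromVolume <- function(V, carbonDensity = 0.39) {
  if (carbonDensity < 0) stop("carbon density must be non-negative")
  if (any(V < 0)) stop("biovolume must be non-negative")
  V * carbonDensity
}

#' Percent biomass loss between two samplings
#'
#' @param vEarly biovolume (or carbon) at the first sampling; must be > 0.
#' @param vLate biovolume at the later sampling.
#' @return percent loss, 100 (vEarly - vLate) / vEarly (negative for gains);
#'   NA when \code{vEarly} is 0.
#' @examples
#' biomassChange(0.9, 0.3)   # 66.7 %
#' @export
biomassChange <- function(vEarly, vLate) {
  ifelse(vEarly > 0, 100 * (vEarly - vLate) / vEarly, NA_real_)
}

.methodNames <- c("aggregate_list", "global_mean", "global_median",
                  "gridded_mean", "gridded_median", "raster_cells")

#' Estimate station biovolume and carbon by one of six methods
#'
#' All methods treat aggregates as spheres of their ECD but differ in how
#' abundance and diameter are averaged:
#' \describe{
#'   \item{aggregate_list}{sums the individual sphere volumes of every
#'     measurable, unflagged detection and divides by the survey area (the
#'     summed footprints of all valid frames, overlap not deduplicated --
#'     deliberately reproducing the overestimate of multiply sampled areas).}
#'   \item{global_mean}{V = a (4/3) pi (d/2)^3 with a the mean per-frame
#'     abundance and d the mean ECD over all pooled detections.}
#'   \item{global_median}{as global_mean with the pooled median ECD, damping
#'     the cubic influence of large, likely non-spherical aggregates.}
#'   \item{gridded_mean, gridded_median}{the same formula with abundance and
#'     diameter averaged over the occupied 3 x 3 m grid cells (cell mean,
#'     respectively cell median, ECD averaged across cells), neutralizing
#'     multiple sampling.}
#'   \item{raster_cells}{evaluates the formula in each grid cell separately
#'     (cell abundance, cell mean ECD) and averages the per-cell volumes,
#'     retaining local hotspots that global averaging dilutes.}
#' }
#'
#' @param method one of the six method names (or "all" for every method).
#' @param detections metric detection data.frame with columns ecd_cm,
#'   measurable, clump_flag.
#' @param frameSummaries data.frame of per-frame summaries (valid frames).
#' @param grid data.frame from \code{\link{gridAverage}}; required for the
#'   gridded and raster methods.
#' @param carbonDensity mg C per ml (default 0.39).
#' @return data.frame with one row per method: method, V_ml_m2, a_per_m2,
#'   d_cm (NA for aggregate_list and raster_cells, which use no single
#'   station-level diameter), carbon_mg_m2.
#' @export
estimateBiovolume <- function(method = "all", detections, frameSummaries,
                              grid = NULL, carbonDensity = 0.39) {
  methods <- if (identical(method, "all")) .methodNames
             else match.arg(method, .methodNames, several.ok = TRUE)
  needGrid <- c("gridded_mean", "gridded_median", "raster_cells")
  if (any(methods %in% needGrid) && is.null(grid))
    stop("grid required for gridded and raster methods")
  sdet <- if (nrow(detections))
    detections[detections$measurable & !detections$clump_flag, , drop = FALSE]
  else detections
  ecds <- sdet$ecd_cm
  aGlobal <- if (nrow(frameSummaries)) mean(frameSummaries$abundance) else 0

  one <- function(m) {
    a <- NA_real_; d <- NA_real_
    V <- switch(m,
      aggregate_list = {
        surveyArea <- sum(frameSummaries$footprint_m2)
        a <- aGlobal
        if (length(ecds) && surveyArea > 0)
          sum(sphereVolume(ecds)) / surveyArea else 0
      },
      global_mean = {
        a <- aGlobal; d <- if (length(ecds)) mean(ecds) else NA_real_
        if (is.na(d)) 0 else a * sphereVolume(d)
      },
      global_median = {
        a <- aGlobal; d <- if (length(ecds)) median(ecds) else NA_real_
        if (is.na(d)) 0 else a * sphereVolume(d)
      },
      gridded_mean = {
        a <- mean(grid$abundance)
        d <- if (any(!is.na(grid$mean_ecd_cm)))
          mean(grid$mean_ecd_cm, na.rm = TRUE) else NA_real_
        if (is.na(d)) 0 else a * sphereVolume(d)
      },
      gridded_median = {
        a <- mean(grid$abundance)
        d <- if (any(!is.na(grid$median_ecd_cm)))
          mean(grid$median_ecd_cm, na.rm = TRUE) else NA_real_
        if (is.na(d)) 0 else a * sphereVolume(d)
      },
      raster_cells = {
        a <- mean(grid$abundance)
        dCell <- grid$mean_ecd_cm
        dCell[is.na(dCell)] <- 0            # cells with no measurable sizes
        if (nrow(grid)) mean(grid$abundance * sphereVolume(dCell)) else 0
      })
    data.frame(method = m, V_ml_m2 = V, a_per_m2 = a, d_cm = d,
               carbon_mg_m2 = carbonFromVolume(V, carbonDensity),
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(methods, one))
  rownames(res) <- NULL
  res
}

#' Round values for report tables
#'
#' One decimal, half away from zero (the presentation convention of the
#' station report tables; base \code{round} rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
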