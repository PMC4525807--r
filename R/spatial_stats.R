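# Patchiness, size-distribution and station-level statistics. Lloyd's index
# of patchiness P = m*/m (with mean crowding m* = m + s^2/m - 1) is 1 for
# Poisson-dispersed counts and grows with clustering; the aggregate number
# size distribution follows a power law f(d) = c d^b whose characteristic
# slope b sits near -3 for typical marine particle fields.

#' Lloyd's index of patchiness from per-cell counts
#'
#' Mean crowding m* = m + (s^2/m - 1) and Lloyd's index P = m*/m, where m is
#' the mean count per cell and s^2 the count variance. With
#' \code{variance = "sample"} (default) s^2 carries Bessel's correction; the
#' \code{"population"} form divides by N and is exactly the per-individual
#' definition of mean crowding, sum x(x-1) / sum x.
#'
#' @param counts integer-like vector of aggregate counts per grid cell
#'   (at least two cells with positive mean).
#' @param variance "sample" or "population".
#' @return list with m (mean count), mStar (mean crowding), P (Lloyd's
#'   index), nCells.
#' @examples
#' lloydPatchiness(c(0, 0, 0, 4))   # P = 4 (strongly aggregated)
#' @export
lloydPatchiness <- function(counts, variance = c("sample", "population")) {
  variance <- match.arg(variance)
  counts <- counts[!is.na(counts)]
  if (length(counts) < 2) stop("need at least two cells")
  m <- mean(counts)
  if (m <= 0)
    return(list(m = m, mStar = NA_real_, P = NA_real_,
                nCells = length(counts)))
  s2 <- if (variance == "sample") var(counts)
        else sum((counts - m)^2) / length(counts)
  mStar <- m + (s2 / m - 1)
  list(m = m, mStar = mStar, P = mStar / m, nCells = length(counts))
}

#' Fit a power-law aggregate size distribution
#'
#' Bins diameters into logarithmically spaced bins, normalizes counts by bin
#' width to a number-density spectrum, and fits log10(density) against
#' log10(diameter) by least squares over the non-empty bins -- the classic
#' transparent estimate of the characteristic slope b in f(d) = c d^b. A
#' maximum-likelihood mode for the truncated power law is available for
#' sensitivity analysis. Fits with R^2 below 0.8 are flagged.
#'
#' @param diameters aggregate ECDs, cm.
#' @param dMin lower fit bound, cm (default: smallest diameter). The
#'   restricted station fit uses dMin = 2 cm.
#' @param dMax upper bin edge (default: largest diameter).
#' @param nBins number of logarithmic bins.
#' @param method "ls" (binned log-log least squares, default) or "mle".
#' @param minSamples minimum diameters above dMin required.
#' @return list: b (slope), c (normalization), r2 (log-log goodness of fit,
#'   NA for mle), dMin, n, flagged (TRUE when r2 < 0.8), method, and the
#'   bin table (mid, count, density).
#' @examples
#' set.seed(1)
#' d <- sampleTruncPowerLaw(5000, -3, 1, 30)
#' fitSizeDistribution(d)$b
#' @export
fitSizeDistribution <- function(diameters, dMin = NULL, dMax = NULL,
                                nBins = 12, method = c("ls", "mle"),
                                minSamples = 20) {
  method <- match.arg(method)
  diameters <- diameters[!is.na(diameters)]
  if (is.null(dMin)) dMin <- min(diameters)
  d <- diameters[diameters >= dMin]
  if (length(d) < minSamples)
    stop("need at least ", minSamples, " diameters above dMin")
  if (is.null(dMax)) dMax <- max(d) * (1 + 1e-9)
  if (diff(range(d)) == 0) stop("degenerate sample: all diameters identical")
  edges <- exp(seq(log(dMin), log(dMax), length.out = nBins + 1))
  counts <- as.numeric(table(cut(d, edges, include.lowest = TRUE)))
  width <- diff(edges)
  mid <- sqrt(edges[-1] * edges[-length(edges)])
  dens <- counts / width
  keep <- counts > 0
  if (sum(keep) < 3)
    stop("degenerate sample: fewer than three non-empty size bins")
  bins <- data.frame(mid = mid, count = counts, density = dens)
  if (method == "ls") {
    yy <- log10(dens[keep]); xx <- log10(mid[keep])
    fit <- lm(yy ~ xx)
    b <- unname(coef(fit)[2])
    cNorm <- 10^unname(coef(fit)[1])
    ssTot <- sum((yy - mean(yy))^2)
    r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  } else {
    dmx <- max(d)
    negll <- function(b) {
      p <- b + 1
      lc <- if (abs(p) < 1e-9) -log(log(dmx / dMin))
            else log(abs(p)) - log(abs(dmx^p - dMin^p))
      -(length(d) * lc + b * sum(log(d)))
    }
    opt <- optimize(negll, c(-8, -0.05))
    b <- opt$minimum
    p <- b + 1
    cNorm <- length(d) * abs(p) / abs(dmx^p - dMin^p)
    r2 <- NA_real_
  }
  list(b = b, c = cNorm, r2 = r2, dMin = dMin, n = length(d),
       flagged = is.finite(r2) && r2 < 0.8, method = method, bins = bins)
}

#' Aggregate-type fractions from station mean eccentricity
#'
#' The observed extremes of station mean eccentricity coincide with stations
#' hosting only rounded (pennate-diatom) or only filamentous aggregates, so
#' the two type fractions follow from a linear mapping of the station mean
#' eccentricity onto [epsMin, epsMax]. Under the default \code{"anchored"}
#' convention the rounded fraction is 1 at the eccentricity minimum (high
#' eccentricity means elongation); \code{"literal"} swaps the two labels,
#' reproducing the printed form of the mapping in the original survey
#' report, whose label assignment contradicts its own anchoring.
#'
#' @param eps station mean eccentricity (vectorized).
#' @param epsMin,epsMax eccentricity extremes across stations.
#' @param convention "anchored" (default) or "literal".
#' @return data.frame with eps, f_spherical, f_elong, convention.
#' @export
typeFractions <- function(eps, epsMin, epsMax,
                          convention = c("anchored", "literal")) {
  convention <- match.arg(convention)
  if (epsMin >= epsMax) stop("epsMin must be below epsMax")
  if (any(eps < epsMin - 1e-9 | eps > epsMax + 1e-9))
    stop("eps must lie within [epsMin, epsMax]")
  u <- pmin(pmax((eps - epsMin) / (epsMax - epsMin), 0), 1)
  if (convention == "anchored") {
    fe <- u; fs <- 1 - u
  } else {
    fs <- u; fe <- 1 - u
  }
  data.frame(eps = eps, f_spherical = fs, f_elong = fe,
             convention = convention, stringsAsFactors = FALSE)
}

#' Pairwise Pearson correlations across stations
#'
#' @param stationTable data.frame with one row per station.
#' @param pairs list of character(2) column-name pairs to correlate.
#' @return data.frame var1, var2, n, r, p (two-sided, no multiplicity
#'   correction); pairs with a constant column or fewer than three complete
#'   stations yield NA.
#' @export
stationCorrelations <- function(stationTable, pairs) {
  out <- lapply(pairs, function(pr) {
    x <- stationTable[[pr[1]]]; y <- stationTable[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0)
      return(data.frame(var1 = pr[1], var2 = pr[2], n = sum(ok),
                        r = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1], var2 = pr[2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
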