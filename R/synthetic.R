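# Synthetic under-ice scenes, aggregate fields and ROV surveys with exact
# ground truth. The generator emulates the study conditions of an Arctic
# late-summer floe survey: ~1 m mean draft with ridge keels, aggregates whose
# diameters follow a truncated power law (slope near -3) and whose positions
# follow a Thomas cluster process, a lawnmower ROV track at ~1 m standoff
# imaging every 5 s.

.smoothField <- function(ny, nx, sigmaCells) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  if (sigmaCells > 0) {
    # circular Gaussian convolution via FFT (kernel may exceed field size)
    dx <- pmin(0:(nx - 1), nx - 0:(nx - 1))
    dy <- pmin(0:(ny - 1), ny - 0:(ny - 1))
    K <- outer(exp(-dy^2 / (2 * sigmaCells^2)),
               exp(-dx^2 / (2 * sigmaCells^2)))
    K <- K / sum(K)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) /
      (ny * nx)
  }
  s <- sd(as.numeric(z))
  if (s > 0) z <- z / s
  z
}

# moving-window statistics with replicated edges; w odd
.movingMean <- function(m, w) {
  half <- (w - 1L) %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  pad <- m[c(rep(1, half), seq_len(ny), rep(ny, half)),
           c(rep(1, half), seq_len(nx), rep(nx, half)), drop = FALSE]
  k <- rep(1 / w, w)
  sm <- stats::filter(pad, k)          # along columns
  sm <- t(stats::filter(t(sm), k))     # along rows
  sm <- matrix(as.numeric(sm), nrow(pad), ncol(pad))
  sm[half + seq_len(ny), half + seq_len(nx), drop = FALSE]
}

.movingSd <- function(m, w) {
  n <- w * w
  mu <- .movingMean(m, w)
  mu2 <- .movingMean(m * m, w)
  v <- (mu2 - mu^2) * n / (n - 1)
  sqrt(pmax(v, 0))
}

#' Generate a synthetic ice scene
#'
#' Builds co-registered draft, roughness and transmittance rasters for a
#' rectangular floe underside: a smooth random draft field (Gaussian noise
#' with correlation length \code{corrLength}) plus Gaussian-profile ridge
#' keels along random lines; roughness as the windowed standard deviation of
#' draft; transmittance decaying exponentially with draft, locally raised
#' under melt-pond patches.
#'
#' @param extent numeric(2), floe extent in metres (x, y).
#' @param cellSize raster cell size, m.
#' @param meanDraft mean level-ice draft, m.
#' @param draftSd standard deviation of the smooth draft variation, m.
#' @param corrLength correlation length of the draft field, m.
#' @param nRidges number of linear ridge keels.
#' @param ridgeAmp keel amplitude added to the draft along the ridge line, m.
#' @param ridgeWidth Gaussian half-width of the keel profile, m.
#' @param roughnessWindow window for the roughness (windowed sd), m.
#' @param transmittance0 open-leads transmittance at zero draft.
#' @param attenuation draft attenuation coefficient, m^-1.
#' @param nPonds number of circular melt-pond patches of raised transmittance.
#' @param pondRadius pond radius, m.
#' @param pondBoost multiplicative transmittance boost under ponds.
#' @param seed optional integer seed; fixed seed gives a bit-identical scene.
#' @return an \code{\linkS4class{IceScene}}.
#' @examples
#' sc <- genIceScene(extent = c(40, 40), nRidges = 1, seed = 1)
#' range(sceneDraft(sc))
#' @export
genIceScene <- function(extent = c(100, 100), cellSize = 0.5,
                        meanDraft = 1.2, draftSd = 0.3, corrLength = 10,
                        nRidges = 2, ridgeAmp = 2.5, ridgeWidth = 4,
                        roughnessWindow = 3,
                        transmittance0 = 0.35, attenuation = 1.5,
                        nPonds = 3, pondRadius = 5, pondBoost = 3,
                        seed = NULL) {
  if (length(extent) == 1) extent <- rep(extent, 2)
  if (any(extent <= 0)) stop("extent must be positive (m)")
  if (cellSize <= 0) stop("cellSize must be positive (m)")
  if (!is.null(seed)) set.seed(seed)
  nx <- max(2L, ceiling(extent[1] / cellSize))
  ny <- max(2L, ceiling(extent[2] / cellSize))
  xc <- (seq_len(nx) - 0.5) * cellSize
  yc <- (seq_len(ny) - 0.5) * cellSize
  draft <- matrix(meanDraft, ny, nx)
  if (draftSd > 0)
    draft <- draft + draftSd * .smoothField(ny, nx, corrLength / cellSize)
  if (nRidges > 0) {
    X <- matrix(xc, ny, nx, byrow = TRUE)
    Y <- matrix(yc, ny, nx)
    for (i in seq_len(nRidges)) {
      x0 <- runif(1, 0, extent[1]); y0 <- runif(1, 0, extent[2])
      th <- runif(1, 0, pi)
      # signed distance to the line through (x0, y0) at angle th
      dist <- abs(-(X - x0) * sin(th) + (Y - y0) * cos(th))
      draft <- draft + ridgeAmp * exp(-dist^2 / (2 * ridgeWidth^2))
    }
  }
  draft <- pmax(draft, 0)
  w <- max(3L, round(roughnessWindow / cellSize))
  if (w %% 2 == 0) w <- w + 1L
  rough <- if (draftSd > 0 || nRidges > 0) .movingSd(draft, w)
           else matrix(0, ny, nx)
  trans <- transmittance0 * exp(-attenuation * draft)
  if (nPonds > 0) {
    X <- matrix(xc, ny, nx, byrow = TRUE)
    Y <- matrix(yc, ny, nx)
    for (i in seq_len(nPonds)) {
      px <- runif(1, 0, extent[1]); py <- runif(1, 0, extent[2])
      inpond <- (X - px)^2 + (Y - py)^2 <= pondRadius^2
      trans[inpond] <- trans[inpond] * pondBoost
    }
  }
  trans <- pmin(pmax(trans, 0), 1)
  new("IceScene", extent = as.numeric(extent), cellSize = cellSize,
      draft = draft, roughness = pmax(rough, 0), transmittance = trans)
}

#' Bilinear lookup of a scene field at floe-fixed positions
#'
#' @param scene an \code{\linkS4class{IceScene}}.
#' @param x,y floe-fixed coordinates, m (vectorized).
#' @param field one of "draft", "roughness", "transmittance".
#' @return numeric vector of field values.
#' @export
sceneValueAt <- function(scene, x, y,
                         field = c("draft", "roughness", "transmittance")) {
  field <- match.arg(field)
  m <- slot(scene, field)
  ny <- nrow(m); nx <- ncol(m); cs <- scene@cellSize
  # fractional cell coordinates relative to cell centers
  fx <- pmin(pmax(x / cs - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y / cs - 0.5, 0), ny - 1)
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  i0 <- i0 + 1; j0 <- j0 + 1   # 1-based
  v00 <- m[cbind(j0, i0)];     v10 <- m[cbind(j0, i0 + 1)]
  v01 <- m[cbind(j0 + 1, i0)]; v11 <- m[cbind(j0 + 1, i0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v10) + ty * ((1 - tx) * v01 + tx * v11)
}

#' Sample diameters from a truncated power law
#'
#' Draws i.i.d. diameters from the number distribution f(d) = c d^b truncated
#' to [dMin, dMax], by inversion of the closed-form CDF.
#'
#' @param n sample size.
#' @param b power-law exponent (b < 0 for aggregate size spectra).
#' @param dMin,dMax truncation bounds (same units as the returned sample).
#' @return numeric vector of length \code{n}.
#' @export
sampleTruncPowerLaw <- function(n, b, dMin, dMax) {
  if (dMin <= 0 || dMin >= dMax) stop("require 0 < dMin < dMax")
  u <- runif(n)
  if (abs(b + 1) < 1e-12) {
    dMin * (dMax / dMin)^u
  } else {
    p <- b + 1
    (dMin^p + u * (dMax^p - dMin^p))^(1 / p)
  }
}

.positionsThomas <- function(extent, nExpected, clustering) {
  area <- extent[1] * extent[2]
  mpc <- clustering$meanPerCluster
  sdc <- clustering$clusterSd
  pad <- 4 * sdc
  areaPad <- (extent[1] + 2 * pad) * (extent[2] + 2 * pad)
  parentInt <- nExpected / (mpc * area)
  nPar <- rpois(1, parentInt * areaPad)
  if (nPar == 0) return(cbind(x = numeric(0), y = numeric(0)))
  px <- runif(nPar, -pad, extent[1] + pad)
  py <- runif(nPar, -pad, extent[2] + pad)
  nOff <- rpois(nPar, mpc)
  x <- rep(px, nOff) + rnorm(sum(nOff), 0, sdc)
  y <- rep(py, nOff) + rnorm(sum(nOff), 0, sdc)
  keep <- x >= 0 & x <= extent[1] & y >= 0 & y <= extent[2]
  cbind(x = x[keep], y = y[keep])
}

#' Generate a field of true aggregates over an ice scene
#'
#' Positions follow a Thomas parent--offspring cluster process (or a
#' homogeneous Poisson process when \code{clustering = NULL}), optionally
#' thinned toward local ice-draft minima, emulating buoyant aggregates
#' trapped in under-ice depressions. Diameters are i.i.d. from a truncated
#' power law; each aggregate carries a type label (rounded diatom mass or
#' filamentous string) with a type-specific eccentricity distribution.
#'
#' @param scene an \code{\linkS4class{IceScene}}.
#' @param n exact number of aggregates to place (mutually exclusive with
#'   \code{intensity}).
#' @param intensity expected aggregates per m^2.
#' @param sizeLaw list(b, dMin, dMax): power-law exponent (b < 0) and
#'   diameter truncation bounds in cm.
#' @param clustering list(meanPerCluster, clusterSd): Thomas-process mean
#'   offspring per parent and isotropic offspring sd (m); \code{NULL}
#'   disables clustering (homogeneous Poisson positions).
#' @param pFilamentous probability that an aggregate is filamentous.
#' @param draftAffinity strength of attraction to draft minima; positions are
#'   kept with acceptance weight exp(-draftAffinity * draft / tau)
#'   (normalized to the scene's draft minimum). 0 disables thinning.
#' @param tau draft e-folding scale of the affinity weight, m.
#' @param seed optional integer seed.
#' @return data.frame with columns id, x_m, y_m, diameter_cm, eccentricity,
#'   orientation_rad, type.
#' @examples
#' sc <- genIceScene(extent = c(50, 50), seed = 1)
#' ag <- genAggregateField(sc, n = 200, seed = 2)
#' table(ag$type)
#' @export
genAggregateField <- function(scene, n = NULL, intensity = NULL,
                              sizeLaw = list(b = -3, dMin = 1, dMax = 30),
                              clustering = list(meanPerCluster = 8,
                                                clusterSd = 2),
                              pFilamentous = 0.5,
                              draftAffinity = 0, tau = 0.5, seed = NULL) {
  if (is.null(n) == is.null(intensity))
    stop("supply exactly one of n or intensity")
  if (sizeLaw$b >= 0) stop("size-law exponent b must be negative")
  if (sizeLaw$dMin <= 0 || sizeLaw$dMin >= sizeLaw$dMax)
    stop("require 0 < dMin < dMax")
  if (!is.null(clustering) &&
      (clustering$meanPerCluster <= 0 || clustering$clusterSd < 0))
    stop("clustering parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  extent <- scene@extent
  area <- extent[1] * extent[2]
  minDraft <- min(scene@draft)

  drawBatch <- function(nExp) {
    if (is.null(clustering) || (clustering$meanPerCluster == 1 &&
                                clustering$clusterSd == 0)) {
      m <- rpois(1, nExp)
      pos <- cbind(x = runif(m, 0, extent[1]), y = runif(m, 0, extent[2]))
    } else {
      pos <- .positionsThomas(extent, nExp, clustering)
    }
    if (draftAffinity > 0 && nrow(pos) > 0) {
      d <- sceneValueAt(scene, pos[, 1], pos[, 2], "draft")
      w <- exp(-draftAffinity * (d - minDraft) / tau)
      pos <- pos[runif(nrow(pos)) < w, , drop = FALSE]
    }
    pos
  }

  if (!is.null(intensity)) {
    pos <- drawBatch(intensity * area)
  } else {
    pos <- drawBatch(max(n * 1.2, n + 10))
    tries <- 0
    while (nrow(pos) < n && tries < 50) {
      pos <- rbind(pos, drawBatch(max(n * 0.5, 10)))
      tries <- tries + 1
    }
    if (nrow(pos) < n) stop("could not place requested number of aggregates")
    pos <- pos[sample.int(nrow(pos), n), , drop = FALSE]
  }
  m <- nrow(pos)
  if (m == 0) {
    return(data.frame(id = integer(0), x_m = numeric(0), y_m = numeric(0),
                      diameter_cm = numeric(0), eccentricity = numeric(0),
                      orientation_rad = numeric(0), type = character(0),
                      stringsAsFactors = FALSE))
  }
  d <- sampleTruncPowerLaw(m, sizeLaw$b, sizeLaw$dMin, sizeLaw$dMax)
  filam <- runif(m) < pFilamentous
  ecc <- ifelse(filam, runif(m, 0.93, 0.995), runif(m, 0.30, 0.85))
  data.frame(id = seq_len(m), x_m = pos[, 1], y_m = pos[, 2],
             diameter_cm = d, eccentricity = ecc,
             orientation_rad = runif(m, 0, pi),
             type = ifelse(filam, "filamentous", "rounded"),
             stringsAsFactors = FALSE)
}

#' Survey parameters for a simulated ROV dive
#'
#' Defaults describe the study conditions: a lawnmower track flown at
#' 0.5 m s^-1 about 1 m below the ice, one frame every 5 s.
#'
#' @param trackType "lawnmower" or "random-walk".
#' @param speed ROV speed, m s^-1.
#' @param frameInterval time between captured frames, s.
#' @param nominalStandoff nominal distance below the ice underside, m.
#' @param depthNoiseSd sd of depth-sensor noise, m.
#' @param altimeterNoiseSd sd of altimeter noise, m.
#' @param tiltNoiseSd sd (half-normal) of ROV tilt, degrees.
#' @param positionNoiseSd sd of recorded floe-fixed position error, m.
#' @param lineSpacing lawnmower line spacing, m.
#' @param margin track margin from the floe edge, m.
#' @param trackLength random-walk track length, m.
#' @param seed optional integer seed used by \code{\link{simulateSurvey}}.
#' @return a list of class \code{surveyParams}.
#' @export
surveyParams <- function(trackType = c("lawnmower", "random-walk"),
                         speed = 0.5, frameInterval = 5,
                         nominalStandoff = 1,
                         depthNoiseSd = 0.02, altimeterNoiseSd = 0.02,
                         tiltNoiseSd = 3, positionNoiseSd = 0.5,
                         lineSpacing = 10, margin = 2, trackLength = 500,
                         seed = NULL) {
  if (frameInterval <= 0) stop("frameInterval must be > 0")
  if (speed <= 0) stop("speed must be > 0")
  structure(list(trackType = match.arg(trackType), speed = speed,
                 frameInterval = frameInterval,
                 nominalStandoff = nominalStandoff,
                 depthNoiseSd = depthNoiseSd,
                 altimeterNoiseSd = altimeterNoiseSd,
                 tiltNoiseSd = tiltNoiseSd,
                 positionNoiseSd = positionNoiseSd,
                 lineSpacing = lineSpacing, margin = margin,
                 trackLength = trackLength, seed = seed),
            class = "surveyParams")
}

#' Rendering parameters for synthetic frames
#'
#' In "clean" rendering the aggregate green level lies below the detection
#' threshold (100 of 255) and the darkest background pixel above it; raising
#' \code{gradientAmp} deliberately violates that separation to probe detector
#' false positives.
#'
#' @param backgroundGreenMean mean background green level (8-bit).
#' @param gradientAmp amplitude of a linear brightness gradient (8-bit).
#' @param gradientAngle gradient direction, rad; NULL draws one at random.
#' @param noiseSd per-pixel Gaussian noise sd (8-bit levels).
#' @param aggregateGreen green level of aggregate pixels (8-bit).
#' @return a list of class \code{renderingParams}.
#' @export
renderingParams <- function(backgroundGreenMean = 200, gradientAmp = 20,
                            gradientAngle = NULL, noiseSd = 5,
                            aggregateGreen = 40) {
  structure(list(backgroundGreenMean = backgroundGreenMean,
                 gradientAmp = gradientAmp, gradientAngle = gradientAngle,
                 noiseSd = noiseSd, aggregateGreen = aggregateGreen),
            class = "renderingParams")
}

#' Render one synthetic upward-looking frame
#'
#' Draws the bright ice background (mean level, linear gradient, Gaussian
#' noise) and every aggregate whose projected ellipse intersects the frame,
#' as a filled dark ellipse projected through the pinhole camera model at the
#' given standoff distance. Filamentous aggregates are rendered as
#' high-eccentricity ellipses.
#'
#' @param aggregates data.frame as from \code{\link{genAggregateField}}.
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @param rendering a \code{\link{renderingParams}} list.
#' @param x,y floe-fixed frame-centre position, m.
#' @param standoff true distance to the ice, m.
#' @param frameId frame identifier carried into the truth table.
#' @return list with \code{pixels} (H x W x 3 array, 0--255) and
#'   \code{truth}, a data.frame with one row per rendered aggregate instance
#'   (id, frame_id, cx_px, cy_px, pixels_rendered, pixels_in_crop,
#'   analytic_px_area, diameter_cm, eccentricity, type).
#' @export
renderFrame <- function(aggregates, calib = cameraCalib(),
                        rendering = renderingParams(), x = 0, y = 0,
                        standoff = 1, frameId = "f1") {
  if (rendering$backgroundGreenMean - rendering$gradientAmp <=
      rendering$aggregateGreen)
    stop("empty dynamic range: background minus gradient must exceed the ",
         "aggregate green level")
  W <- calib@nativeSize[1]; H <- calib@nativeSize[2]
  cw <- calib@cropSize[1]; ch <- calib@cropSize[2]
  offC <- (W - cw) %/% 2L; offR <- (H - ch) %/% 2L
  scale <- pixelScale(standoff, calib)          # m per px
  ang <- rendering$gradientAngle
  if (is.null(ang)) ang <- runif(1, 0, 2 * pi)
  u <- matrix(seq(-1, 1, length.out = W), H, W, byrow = TRUE)
  v <- matrix(seq(-1, 1, length.out = H), H, W)
  green <- rendering$backgroundGreenMean +
    rendering$gradientAmp * (u * cos(ang) + v * sin(ang)) +
    rnorm(H * W, 0, rendering$noiseSd)

  halfW <- W * scale / 2; halfH <- H * scale / 2
  truth <- list()
  if (nrow(aggregates)) {
    dx <- aggregates$x_m - x
    dy <- aggregates$y_m - y
    rmaj_m <- (aggregates$diameter_cm / 200) /
      (1 - aggregates$eccentricity^2)^0.25
    vis <- abs(dx) <= halfW + rmaj_m & abs(dy) <= halfH + rmaj_m
    for (i in which(vis)) {
      cx <- (W + 1) / 2 + dx[i] / scale
      cy <- (H + 1) / 2 - dy[i] / scale
      q <- (1 - aggregates$eccentricity[i]^2)^0.25
      a <- (aggregates$diameter_cm[i] / 200) / q / scale    # semi-major, px
      b <- (aggregates$diameter_cm[i] / 200) * q / scale    # semi-minor, px
      th <- aggregates$orientation_rad[i]
      c0 <- max(1L, floor(cx - a)); c1 <- min(W, ceiling(cx + a))
      r0 <- max(1L, floor(cy - a)); r1 <- min(H, ceiling(cy + a))
      if (c0 > c1 || r0 > r1) next
      cc <- matrix(c0:c1, r1 - r0 + 1, c1 - c0 + 1, byrow = TRUE)
      rr <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
      ddx <- cc - cx; ddy <- -(rr - cy)
      inside <- ((ddx * cos(th) + ddy * sin(th)) / a)^2 +
        ((-ddx * sin(th) + ddy * cos(th)) / b)^2 <= 1
      npx <- sum(inside)
      if (npx > 0) {
        idx <- cbind(rr[inside], cc[inside])
        green[idx] <- rendering$aggregateGreen +
          rnorm(npx, 0, rendering$noiseSd)
        inCrop <- idx[, 1] > offR & idx[, 1] <= offR + ch &
          idx[, 2] > offC & idx[, 2] <= offC + cw
        truth[[length(truth) + 1L]] <- data.frame(
          id = aggregates$id[i], frame_id = frameId, cx_px = cx, cy_px = cy,
          pixels_rendered = npx, pixels_in_crop = sum(inCrop),
          analytic_px_area = pi * a * b,
          diameter_cm = aggregates$diameter_cm[i],
          eccentricity = aggregates$eccentricity[i],
          type = aggregates$type[i], stringsAsFactors = FALSE)
      }
    }
  }
  green <- pmin(pmax(green, 0), 255)
  pix <- array(0, c(H, W, 3))
  pix[, , 2] <- round(green)
  pix[, , 1] <- round(pmin(pmax(green * 0.85, 0), 255))
  pix[, , 3] <- round(pmin(pmax(green * 0.95 + 10, 0), 255))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = integer(0), frame_id = character(0), cx_px = numeric(0),
               cy_px = numeric(0), pixels_rendered = integer(0),
               pixels_in_crop = integer(0), analytic_px_area = numeric(0),
               diameter_cm = numeric(0), eccentricity = numeric(0),
               type = character(0), stringsAsFactors = FALSE)
  list(pixels = pix, truth = truth)
}

.lawnmowerWaypoints <- function(extent, spacing, margin) {
  xs <- seq(margin, extent[1] - margin, by = spacing)
  wp <- matrix(NA_real_, 2 * length(xs), 2)
  for (i in seq_along(xs)) {
    ys <- if (i %% 2 == 1) c(margin, extent[2] - margin)
          else c(extent[2] - margin, margin)
    wp[2 * i - 1, ] <- c(xs[i], ys[1])
    wp[2 * i, ] <- c(xs[i], ys[2])
  }
  wp
}

.pathPoints <- function(waypoints, ds) {
  seg <- sqrt(diff(waypoints[, 1])^2 + diff(waypoints[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(cbind(x = numeric(0), y = numeric(0)))
  at <- seq(0, total, by = ds)
  cbind(x = stats::approx(s, waypoints[, 1], xout = at)$y,
        y = stats::approx(s, waypoints[, 2], xout = at)$y)
}

.randomWalkPoints <- function(extent, margin, ds, n) {
  x <- extent[1] / 2; y <- extent[2] / 2
  th <- runif(1, 0, 2 * pi)
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    th <- th + rnorm(1, 0, 0.4)
    x2 <- x + ds * cos(th); y2 <- y + ds * sin(th)
    if (x2 < margin || x2 > extent[1] - margin) { th <- pi - th }
    if (y2 < margin || y2 > extent[2] - margin) { th <- -th }
    x <- pmin(pmax(x + ds * cos(th), margin), extent[1] - margin)
    y <- pmin(pmax(y + ds * sin(th), margin), extent[2] - margin)
  }
  out
}

#' Simulate an ROV survey over a scene with rendered frames and ground truth
#'
#' Flies the configured track across the scene, capturing one frame per
#' \code{frameInterval}. Per frame, the true depth is the local ice draft
#' plus the nominal standoff; the recorded depth, altimeter distance, tilt
#' and floe-fixed position carry the configured sensor noise. Frames are
#' rendered through \code{\link{renderFrame}}; the returned truth table has
#' one row per rendered aggregate instance.
#'
#' @param scene an \code{\linkS4class{IceScene}}.
#' @param aggregates data.frame from \code{\link{genAggregateField}}.
#' @param survey a \code{\link{surveyParams}} list.
#' @param calib a \code{\linkS4class{CameraCalib}}.
#' @param rendering a \code{\link{renderingParams}} list.
#' @param renderPixels if FALSE, frames carry empty pixel arrays (geometry
#'   and truth only), which is faster when only navigation is needed.
#' @param seed optional integer seed (all survey and rendering randomness
#'   funnels through it).
#' @return list with \code{frames} (list of \code{\linkS4class{IceFrame}}),
#'   \code{truth} (rendered-instance table), \code{track} (true positions),
#'   and \code{aggregates} (the input field).
#' @export
simulateSurvey <- function(scene, aggregates, survey = surveyParams(),
                           calib = cameraCalib(),
                           rendering = renderingParams(),
                           renderPixels = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  else if (!is.null(survey$seed)) set.seed(survey$seed)
  extent <- scene@extent
  ds <- survey$speed * survey$frameInterval
  pos <- if (survey$trackType == "lawnmower") {
    .pathPoints(.lawnmowerWaypoints(extent, survey$lineSpacing,
                                    survey$margin), ds)
  } else {
    .randomWalkPoints(extent, survey$margin, ds,
                      max(1L, ceiling(survey$trackLength / ds)))
  }
  n <- nrow(pos)
  frames <- vector("list", n)
  truths <- vector("list", n)
  if (n == 0)
    return(list(frames = list(),
                truth = renderFrame(aggregates[0, , drop = FALSE], calib,
                                    rendering, 0, 0, 1)$truth,
                track = pos, aggregates = aggregates))
  draftHere <- sceneValueAt(scene, pos[, 1], pos[, 2], "draft")
  for (i in seq_len(n)) {
    fid <- sprintf("f%05d", i)
    trueDepth <- draftHere[i] + survey$nominalStandoff
    depth <- trueDepth + rnorm(1, 0, survey$depthNoiseSd)
    altim <- survey$nominalStandoff + rnorm(1, 0, survey$altimeterNoiseSd)
    tilt <- abs(rnorm(1, 0, survey$tiltNoiseSd))
    xr <- pos[i, 1] + rnorm(1, 0, survey$positionNoiseSd)
    yr <- pos[i, 2] + rnorm(1, 0, survey$positionNoiseSd)
    if (renderPixels) {
      rf <- renderFrame(aggregates, calib, rendering,
                        x = pos[i, 1], y = pos[i, 2],
                        standoff = survey$nominalStandoff, frameId = fid)
      pix <- rf$pixels
      truths[[i]] <- rf$truth
    } else {
      pix <- array(numeric(0), c(0, 0, 3))
      truths[[i]] <- NULL
    }
    frames[[i]] <- iceFrame(pixels = pix, frameId = fid,
                            t = (i - 1) * survey$frameInterval,
                            depth = depth, tilt = tilt, altimeter = altim,
                            x = xr, y = yr)
  }
  truth <- do.call(rbind, truths[!vapply(truths, is.null, logical(1))])
  if (is.null(truth))
    truth <- renderFrame(aggregates[0, , drop = FALSE], calib, rendering,
                         0, 0, 1)$truth
  list(frames = frames, truth = truth,
       track = data.frame(x_m = pos[, 1], y_m = pos[, 2]),
       aggregates = aggregates)
}
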