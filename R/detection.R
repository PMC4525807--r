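# Image classification: crop, green-channel threshold, connected-component
# labeling with per-region shape measurements, and frame/region quality
# control. Aggregates appear as dark regions against the bright ice
# background; a pixel is classified as aggregate when its green value lies
# in [0, 100] of 255.

.framePixels <- function(frame) {
  if (is(frame, "IceFrame")) frame@pixels else frame
}

#' Crop a frame to the undisturbed analysis window
#'
#' Removes the inconsistently lit frame edges (and any overlay display),
#' keeping a \code{width x height} window; by default the window is centred
#' in the native frame. Navigation metadata is unchanged.
#'
#' @param frame an \code{\linkS4class{IceFrame}} or H x W x 3 array.
#' @param width,height crop size in pixels (defaults 250 x 200).
#' @param offset integer(2) \code{c(x, y)} offset of the window's top-left
#'   corner from the frame's top-left, in pixels; NULL centres the window.
#' @return same type as \code{frame}, cropped.
#' @examples
#' f <- iceFrame(array(255, c(288, 384, 3)))
#' dim(cropFrame(f)@pixels)   # 200 250 3
#' @export
cropFrame <- function(frame, width = 250L, height = 200L, offset = NULL) {
  pix <- .framePixels(frame)
  H <- dim(pix)[1]; W <- dim(pix)[2]
  if (is.null(offset)) offset <- c((W - width) %/% 2L, (H - height) %/% 2L)
  ox <- as.integer(offset[1]); oy <- as.integer(offset[2])
  if (ox < 0 || oy < 0 || ox + width > W || oy + height > H)
    stop("crop window exceeds frame bounds")
  sub <- pix[oy + seq_len(height), ox + seq_len(width), , drop = FALSE]
  if (is(frame, "IceFrame")) {
    frame@pixels <- sub
    frame
  } else sub
}

#' Green-channel threshold segmentation
#'
#' Classifies every pixel whose green value lies in \code{[lo, hi]}
#' (inclusive bounds, 8-bit scale) as aggregate. The default band 0--100 of
#' 255 separates dark algal aggregates from the bright ice background.
#'
#' @param frame an \code{\linkS4class{IceFrame}} or H x W x 3 array (0--255).
#' @param lo,hi inclusive green-channel bounds.
#' @return logical matrix, TRUE at aggregate pixels.
#' @export
thresholdGreen <- function(frame, lo = 0, hi = 100) {
  if (lo > hi) stop("lo must not exceed hi")
  pix <- .framePixels(frame)
  if (length(dim(pix)) != 3 || dim(pix)[3] != 3)
    stop("expected an 8-bit RGB frame")
  g <- pix[, , 2]
  g >= lo & g <= hi
}

# 8-connectivity on top of EBImage's 4-connected labeling: labels touching
# diagonally are merged with a union-find over label ids.
.label8 <- function(mask) {
  L <- EBImage::bwlabel(mask)
  L <- matrix(as.integer(L), nrow(mask), ncol(mask))
  nl <- max(L)
  if (nl < 2) return(L)
  ny <- nrow(L); nx <- ncol(L)
  a <- L[-ny, -nx]; d <- L[-1, -1]       # NW-SE diagonal contacts
  b <- L[-ny, -1];  c2 <- L[-1, -nx]     # NE-SW diagonal contacts
  p1 <- cbind(a[a > 0 & d > 0 & a != d], d[a > 0 & d > 0 & a != d])
  p2 <- cbind(b[b > 0 & c2 > 0 & b != c2], c2[b > 0 & c2 > 0 & b != c2])
  pairs <- unique(rbind(p1, p2))
  if (nrow(pairs)) {
    parent <- seq_len(nl)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nl), find, integer(1))
    L[L > 0] <- root[L[L > 0]]
  }
  # renumber to consecutive ids
  ids <- sort(unique(L[L > 0]))
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  L[L > 0] <- remap[L[L > 0]]
  L
}

# Boundary-step perimeter via Moore contour tracing. The 8-connected chain
# through the outer boundary pixel centres is length-corrected with the
# Vossepoel-Smeulders weights (0.980 per axial step, 1.406 per diagonal
# step, -0.091 per corner), then pi is added for the half-pixel dilation
# separating the centre polygon from the digitized outline. Digitized disks
# and squares then measure within a few percent of their continuum
# perimeter and circularity stays <= 1 up to discretization.
.tracePerimeter <- function(mask) {
  n <- sum(mask)
  if (n == 1) return(2 * sqrt(pi))   # circularity 1 for a single pixel
  p <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  p[1 + seq_len(nrow(mask)), 1 + seq_len(ncol(mask))] <- mask
  idx <- which(p, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])        # topmost row, then leftmost col
  s <- as.integer(idx[ord[1], ])
  # neighbour offsets clockwise (rows grow downward): N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  bpos0 <- s + c(0L, -1L)                  # backtrack starts west of s
  cur <- s; bpos <- bpos0
  nAxial <- 0L; nDiag <- 0L; nCorner <- 0L; lastd <- NA_integer_
  maxIter <- 8L * n + 16L
  for (it in seq_len(maxIter)) {
    db <- which(dr == bpos[1] - cur[1] & dc == bpos[2] - cur[2])
    found <- FALSE
    for (k in 1:8) {
      d <- ((db - 1L + k) %% 8L) + 1L      # scan clockwise after backtrack
      rr <- cur[1] + dr[d]; cc <- cur[2] + dc[d]
      if (p[rr, cc]) {
        if (d %% 2L == 1L) nAxial <- nAxial + 1L else nDiag <- nDiag + 1L
        if (!is.na(lastd) && lastd != d) nCorner <- nCorner + 1L
        lastd <- d
        if (k > 1) {
          dprev <- ((d - 2L) %% 8L) + 1L   # last background cell scanned
          bpos <- cur + c(dr[dprev], dc[dprev])
        }                                   # k == 1: backtrack unchanged
        cur <- c(rr, cc)
        found <- TRUE
        break
      }
    }
    if (!found) break                       # no neighbours: lone pixel
    if (cur[1] == s[1] && cur[2] == s[2] &&
        bpos[1] == bpos0[1] && bpos[2] == bpos0[2]) break
  }
  max(0.980 * nAxial + 1.406 * nDiag - 0.091 * nCorner, 0) + pi
}

# Solidity as in standard region-properties analysis: region area divided by
# the number of lattice points inside (or on) the convex hull of the pixel
# centres, so a digitized convex shape scores ~1.
.hullSolidity <- function(cols, rows) {
  n <- length(cols)
  h <- grDevices::chull(cols, rows)
  if (length(h) < 3) return(1)              # collinear region
  hx <- cols[h]; hy <- rows[h]               # chull returns clockwise order
  gx <- seq(min(cols), max(cols)); gy <- seq(min(rows), max(rows))
  px <- rep(gx, times = length(gy)); py <- rep(gy, each = length(gx))
  inside <- rep(TRUE, length(px))
  m <- length(h)
  for (e in seq_len(m)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[if (e == m) 1 else e + 1]; y2 <- hy[if (e == m) 1 else e + 1]
    # clockwise polygon: interior has non-positive cross product
    inside <- inside &
      ((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)) <= 1e-9
    if (!any(inside)) break
  }
  hullCount <- sum(inside)
  if (hullCount < n) hullCount <- n
  n / hullCount
}

#' Label connected aggregate regions and measure their pixel-space shape
#'
#' Connected components of the binary mask (8-connectivity by default, so
#' diagonally touching pixels join) become one detection each. Per region
#' the pixel area, marching-squares contour perimeter, centroid, fitted
#' ellipse (from second central moments, with the 1/12 unit-pixel variance
#' added), orientation and convex-hull solidity are computed. Regions of a
#' single pixel get no ellipse fit.
#'
#' @param mask logical matrix from \code{\link{thresholdGreen}}.
#' @param connectivity 8 (default) or 4.
#' @param frameId frame identifier carried into the output.
#' @return data.frame with one row per region: region_id, frame_id,
#'   pixel_area, pixel_perimeter, centroid_x_px, centroid_y_px,
#'   major_axis_px, minor_axis_px, orientation_rad, solidity.
#' @export
labelRegions <- function(mask, connectivity = 8, frameId = "f1") {
  stopifnot(connectivity %in% c(4, 8))
  empty <- data.frame(region_id = integer(0), frame_id = character(0),
                      pixel_area = numeric(0), pixel_perimeter = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      major_axis_px = numeric(0), minor_axis_px = numeric(0),
                      orientation_rad = numeric(0), solidity = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)
  L <- if (connectivity == 8) .label8(mask) else {
    l4 <- EBImage::bwlabel(mask)
    matrix(as.integer(l4), nrow(mask), ncol(mask))
  }
  idx <- which(L > 0)
  lab <- L[idx]
  rows <- ((idx - 1L) %% nrow(L)) + 1L
  cols <- ((idx - 1L) %/% nrow(L)) + 1L
  byLab <- split(seq_along(idx), lab)
  out <- lapply(seq_along(byLab), function(k) {
    sel <- byLab[[k]]
    rr <- rows[sel]; cc <- cols[sel]
    n <- length(sel)
    sub <- matrix(FALSE, max(rr) - min(rr) + 1L, max(cc) - min(cc) + 1L)
    sub[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
    per <- .tracePerimeter(sub)
    if (n >= 2) {
      mx <- mean(cc); my <- mean(rr)
      cxx <- sum((cc - mx)^2) / n + 1 / 12
      cyy <- sum((rr - my)^2) / n + 1 / 12
      cxy <- sum((cc - mx) * (rr - my)) / n
      tr2 <- (cxx + cyy) / 2
      det <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
      l1 <- tr2 + det; l2 <- max(tr2 - det, 0)
      major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
      orient <- 0.5 * atan2(2 * cxy, cxx - cyy)
      sol <- .hullSolidity(cc, rr)
    } else {
      major <- NA_real_; minor <- NA_real_; orient <- NA_real_
      sol <- 1
    }
    data.frame(region_id = k, frame_id = frameId, pixel_area = n,
               pixel_perimeter = per,
               centroid_x_px = mean(cc), centroid_y_px = mean(rr),
               major_axis_px = major, minor_axis_px = minor,
               orientation_rad = orient, solidity = sol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Frame-level quality control
#'
#' Discards frames taken deeper than \code{maxDepth} or at tilts above
#' \code{maxTilt} (strict inequalities: a frame at exactly 5 m depth and 10
#' degrees tilt is retained), frames without navigation metadata, and frames
#' on an optional manual blocklist.
#'
#' @param frames list of \code{\linkS4class{IceFrame}} objects.
#' @param maxDepth maximum ROV depth, m.
#' @param maxTilt maximum ROV tilt, degrees.
#' @param blocklist character vector of frame ids to discard manually.
#' @return list with \code{frames} (the retained frames) and \code{report}:
#'   n_input, n_discarded_depth, n_discarded_tilt, n_discarded_manual,
#'   n_discarded_missing, n_valid, and a per-frame \code{reasons} data.frame.
#' @export
qcFrames <- function(frames, maxDepth = 5, maxTilt = 10,
                     blocklist = character(0)) {
  n <- length(frames)
  reason <- character(n)
  for (i in seq_len(n)) {
    f <- frames[[i]]
    reason[i] <-
      if (is.na(f@depth) || is.na(f@tilt) || is.na(f@altimeter)) "missing-nav"
      else if (f@depth > maxDepth) "depth"
      else if (f@tilt > maxTilt) "tilt"
      else if (f@frameId %in% blocklist) "manual"
      else "valid"
  }
  report <- list(
    n_input = n,
    n_discarded_depth = sum(reason == "depth"),
    n_discarded_tilt = sum(reason == "tilt"),
    n_discarded_manual = sum(reason == "manual"),
    n_discarded_missing = sum(reason == "missing-nav"),
    n_valid = sum(reason == "valid"),
    reasons = data.frame(
      frame_id = vapply(frames, function(f) f@frameId, character(1)),
      reason = reason, stringsAsFactors = FALSE)
  )
  list(frames = frames[reason == "valid"], report = report)
}

#' Partition regions into measurable and detect-only
#'
#' Regions covering more than \code{minShapePixels} pixels carry reliable
#' shape parameters; smaller regions still count toward abundance and
#' coverage but enter no size or shape statistics.
#'
#' @param regions data.frame from \code{\link{labelRegions}}.
#' @param minShapePixels strict lower pixel-area bound for shape analysis
#'   (default 10: an 11-pixel region is measurable, a 10-pixel one is not).
#' @return list with data.frames \code{measurable} and \code{detectOnly}.
#' @export
qcRegions <- function(regions, minShapePixels = 10) {
  meas <- regions$pixel_area > minShapePixels
  list(measurable = regions[meas, , drop = FALSE],
       detectOnly = regions[!meas, , drop = FALSE])
}

#' Flag probable clumps of close-lying aggregates
#'
#' Several aggregates merged into one thresholded region masquerade as a
#' single large one. Such regions are flagged automatically when their
#' convex-hull solidity falls below \code{solidityMin} (merged blobs are
#' concave: two tangent equal disks score about 0.88, while isolated convex
#' aggregates stay above ~0.99 even under pixel noise, hence the 0.9
#' default) or, optionally, when their log pixel area exceeds the station
#' median by more than \code{sizeOutlierK} robust (MAD) deviations. The size
#' rule is off by default (\code{Inf}): aggregate areas follow a heavy-tailed
#' power law, so an untempered outlier rule would cull the genuine large-size
#' tail. Flagged regions are excluded from shape and size statistics but
#' retained for abundance and coverage.
#'
#' @param regions data.frame of measurable regions.
#' @param solidityMin minimum solidity of an unflagged region.
#' @param sizeOutlierK robust-deviation multiplier for the log-area size
#'   rule; \code{Inf} disables it.
#' @return logical vector, TRUE where the region is flagged as a clump.
#' @export
flagClumps <- function(regions, solidityMin = 0.9, sizeOutlierK = Inf) {
  if (nrow(regions) == 0) return(logical(0))
  flag <- regions$solidity < solidityMin
  if (is.finite(sizeOutlierK)) {
    la <- log(regions$pixel_area)
    madA <- mad(la)
    if (madA > 0)
      flag <- flag | la > median(la) + sizeOutlierK * madA
  }
  flag
}
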