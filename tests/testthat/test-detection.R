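test_that("crop window: centred offsets, identity, bounds", {
  pix <- array(200, c(288, 384, 3))
  # mark the native-frame pixel that a centred 250 x 200 crop should map to
  # its own (1, 1): offsets ((384-250)/2, (288-200)/2) = (67, 44)
  pix[45, 68, 2] <- 7
  f <- navFrame(pixels = pix)
  cr <- cropFrame(f)
  expect_identical(dim(cr@pixels), c(200L, 250L, 3L))
  expect_equal(cr@pixels[1, 1, 2], 7)
  expect_equal(cr@frameId, f@frameId)   # metadata unchanged

  small <- array(100, c(200, 250, 3))
  expect_identical(cropFrame(small, 250, 200, offset = c(0, 0)), small)
  expect_error(cropFrame(small, 250, 200, offset = c(10, 0)), "bounds")
})

test_that("green threshold has inclusive bounds and rejects inverted bands", {
  pix <- array(0, c(1, 4, 3))
  pix[1, , 2] <- c(0, 100, 101, 255)
  m <- thresholdGreen(pix)
  expect_identical(as.vector(m), c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(thresholdGreen(array(255, c(5, 5, 3)))))
  expect_error(thresholdGreen(pix, lo = 50, hi = 10), "lo")
  # deterministic: identical input, identical mask
  expect_identical(thresholdGreen(pix), m)
})

test_that("region labelling: separation, connectivity, degenerate regions", {
  m <- diskMask(60, 120, 30, 30, 8) | diskMask(60, 120, 30, 90, 8)
  regs <- labelRegions(m)
  expect_equal(nrow(regs), 2)

  # single pixel: area 1, no ellipse fit
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  r1 <- labelRegions(one)
  expect_equal(r1$pixel_area, 1)
  expect_true(is.na(r1$major_axis_px))

  # diagonal contact joins under 8-connectivity, not 4
  dg <- matrix(FALSE, 5, 5); dg[2, 2] <- TRUE; dg[3, 3] <- TRUE
  expect_equal(nrow(labelRegions(dg, 8)), 1)
  expect_equal(nrow(labelRegions(dg, 4)), 2)

  # region count invariant under geometric relabelings of the same mask
  expect_equal(nrow(labelRegions(t(m))), 2)
  expect_equal(nrow(labelRegions(m[, rev(seq_len(ncol(m)))])), 2)

  expect_equal(nrow(labelRegions(matrix(FALSE, 4, 4))), 0)
})

test_that("region shape descriptors match continuum geometry", {
  disk <- labelRegions(diskMask(60, 60, 30, 30, 10))
  circ <- 4 * pi * disk$pixel_area / disk$pixel_perimeter^2
  expect_lt(abs(circ - 1), 0.1)
  expect_lte(circ, 1.02)
  ecc <- sqrt(1 - (disk$minor_axis_px / disk$major_axis_px)^2)
  expect_lt(ecc, 0.15)
  expect_gt(disk$solidity, 0.97)
  expect_lt(abs(disk$major_axis_px - 20), 1)

  sq <- matrix(FALSE, 40, 40); sq[11:30, 11:30] <- TRUE
  rs <- labelRegions(sq)
  circS <- 4 * pi * rs$pixel_area / rs$pixel_perimeter^2
  expect_lt(abs(circS - pi / 4), 0.08)

  # 2:1 ellipse: eccentricity sqrt(1 - 1/4) ~ 0.866
  el <- labelRegions(ellipseMask(60, 60, 30, 30, 20, 10))
  eccE <- sqrt(1 - (el$minor_axis_px / el$major_axis_px)^2)
  expect_lt(abs(eccE - sqrt(0.75)), 0.02)
})

test_that("frame QC applies strict depth/tilt cuts and enumerates reasons", {
  frames <- list(
    navFrame("a", depth = 6, tilt = 0),          # too deep
    navFrame("b", depth = 5.0, tilt = 10.0),     # boundary: retained
    navFrame("c", depth = 2, tilt = 12),         # too tilted
    navFrame("d", depth = 2, tilt = NA),         # missing navigation
    navFrame("e", depth = 2, tilt = 0),
    navFrame("f", depth = 2, tilt = 0)
  )
  qc <- qcFrames(frames, blocklist = "f")
  rep <- qc$report
  expect_equal(rep$n_input, 6)
  expect_equal(rep$n_discarded_depth, 1)
  expect_equal(rep$n_discarded_tilt, 1)
  expect_equal(rep$n_discarded_missing, 1)
  expect_equal(rep$n_discarded_manual, 1)
  expect_equal(rep$n_valid, 2)
  expect_equal(rep$n_input - rep$n_discarded_depth - rep$n_discarded_tilt -
                 rep$n_discarded_missing - rep$n_discarded_manual,
               rep$n_valid)
  expect_setequal(vapply(qc$frames, function(f) f@frameId, character(1)),
                  c("b", "e"))
  expect_equal(rep$reasons$reason[rep$reasons$frame_id == "d"],
               "missing-nav")

  # 10 frames, 3 tilt violations -> 7 valid
  f10 <- lapply(1:10, function(i)
    navFrame(paste0("t", i), tilt = if (i <= 3) 15 else 0))
  expect_equal(qcFrames(f10)$report$n_valid, 7)
})

test_that("region QC partitions at the strict 10-pixel bound", {
  regs <- data.frame(region_id = 1:4, pixel_area = c(3, 10, 11, 40))
  parts <- qcRegions(regs)
  expect_equal(parts$measurable$pixel_area, c(11, 40))
  expect_equal(parts$detectOnly$pixel_area, c(3, 10))
  empty <- qcRegions(regs[0, ])
  expect_equal(nrow(empty$measurable), 0)
  expect_equal(nrow(empty$detectOnly), 0)
})

test_that("clump flag catches concave merged regions, spares convex ones", {
  # convex ellipse: unflagged
  el <- labelRegions(ellipseMask(60, 60, 30, 30, 18, 8))
  expect_false(flagClumps(el))

  # pinched dumbbell of two overlapping thin ellipses: flagged by solidity
  db <- ellipseMask(60, 90, 30, 26, 14, 5) | ellipseMask(60, 90, 30, 52, 14, 5)
  rdb <- labelRegions(db)
  expect_equal(nrow(rdb), 1)
  expect_lt(rdb$solidity, 0.9)
  expect_true(flagClumps(rdb))

  # a V-shaped chain of two rotated ellipses is even less solid
  v <- ellipseMask(70, 90, 40, 35, 16, 5, pi / 4) |
    ellipseMask(70, 90, 40, 55, 16, 5, -pi / 4)
  rv <- labelRegions(v)
  expect_equal(nrow(rv), 1)
  expect_true(flagClumps(rv))

  # all-flagged: size statistics empty, abundance untouched
  det <- toMetric(rdb, 0.0045)
  det$measurable <- TRUE
  det$clump_flag <- TRUE
  fs <- summarizeFrame(det, navFrame(altimeter = 1))
  expect_equal(fs$n_aggregates, 1)
  expect_gt(fs$coverage, 0)
  expect_true(is.na(fs$mean_ecd_cm))

  expect_length(flagClumps(el[0, ]), 0)
})
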