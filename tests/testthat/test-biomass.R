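test_that("sphere volume follows the closed form and cubic scaling", {
  expect_equal(sphereVolume(2), 4 / 3 * pi, tolerance = 1e-12)   # 4.18879 ml
  expect_equal(sphereVolume(0), 0)
  expect_equal(sphereVolume(4), 8 * sphereVolume(2))
  expect_error(sphereVolume(-1), "non-negative")
})

test_that("carbon conversion applies the 390 mg C/L density", {
  expect_equal(carbonFromVolume(10.4), 4.056)
  expect_equal(carbonFromVolume(21.9), 8.541)
  expect_equal(carbonFromVolume(0), 0)
  expect_error(carbonFromVolume(1, carbonDensity = -1), "non-negative")
})

test_that("biomass change is the percent loss of the early volume", {
  expect_equal(biomassChange(0.9, 0.3), 200 / 3)   # 66.7 %
  expect_equal(biomassChange(1, 1), 0)
  expect_equal(biomassChange(2, 0), 100)
  expect_true(is.na(biomassChange(0, 1)))
})

test_that("all six estimators collapse on a single uniform observation", {
  fs <- fsRow("f1", 0, 0, abundance = 1, n = 1, footprint = 1,
              meanEcd = 2, medianEcd = 2)
  det <- detRow(1, "f1", 2)
  grid <- gridAverage(fs, assignFrames(fs, origin = c(0, 0)), det)
  est <- estimateBiovolume("all", det, fs, grid)
  expect_setequal(est$method,
                  c("aggregate_list", "global_mean", "global_median",
                    "gridded_mean", "gridded_median", "raster_cells"))
  expect_equal(est$V_ml_m2, rep(sphereVolume(2), 6), tolerance = 1e-9)
  expect_equal(est$a_per_m2, rep(1, 6))
  expect_equal(est$carbon_mg_m2, 0.39 * est$V_ml_m2)
})

test_that("raster cells and gridded mean diverge as specified on two cells", {
  # cell 1: a = 1, d = 2; cell 2: a = 1, d = 4 (cells 3 m apart)
  fs <- rbind(fsRow("f1", 1, 1, abundance = 1, n = 1),
              fsRow("f2", 4, 1, abundance = 1, n = 1))
  det <- rbind(detRow(1, "f1", 2), detRow(2, "f2", 4))
  grid <- gridAverage(fs, assignFrames(fs, origin = c(0, 0)), det)
  est <- estimateBiovolume("all", det, fs, grid)
  raster <- est$V_ml_m2[est$method == "raster_cells"]
  gmean <- est$V_ml_m2[est$method == "gridded_mean"]
  expect_equal(raster, (sphereVolume(2) + sphereVolume(4)) / 2,
               tolerance = 1e-9)                        # 18.85
  expect_equal(gmean, 1 * sphereVolume(3), tolerance = 1e-9)   # 14.14
  expect_gt(raster, gmean)
})

test_that("median-based estimates sit below mean-based on skewed sizes", {
  set.seed(31)
  d <- sampleTruncPowerLaw(400, -3, 1, 30)
  fs <- fsRow("f1", 0, 0, abundance = 400, n = 400, footprint = 1)
  det <- do.call(rbind, lapply(seq_along(d), function(i)
    detRow(i, "f1", d[i])))
  grid <- gridAverage(fs, assignFrames(fs, origin = c(0, 0)), det)
  est <- estimateBiovolume("all", det, fs, grid)
  v <- setNames(est$V_ml_m2, est$method)
  expect_lt(v["global_median"], v["global_mean"])
  # aggregate_list captures the heavy tail the mean-diameter cube misses
  expect_gt(v["aggregate_list"], v["global_mean"])
  # carbon/volume ratio equals the configured density for every method
  expect_equal(est$carbon_mg_m2 / est$V_ml_m2, rep(0.39, 6))
})

test_that("estimators agree within 10 % under spatial and size homogeneity", {
  # 40 frames of 1 m^2 in different cells, one 4 cm aggregate each
  set.seed(7)
  fs <- do.call(rbind, lapply(1:40, function(i)
    fsRow(paste0("f", i), x = 3.5 * (i %% 8), y = 3.5 * (i %/% 8),
          abundance = 1, n = 1, footprint = 1)))
  det <- do.call(rbind, lapply(1:40, function(i)
    detRow(i, paste0("f", i), runif(1, 3.9, 4.1))))
  grid <- gridAverage(fs, assignFrames(fs, origin = c(0, 0)), det)
  est <- estimateBiovolume("all", det, fs, grid)
  expect_lt(max(est$V_ml_m2) / min(est$V_ml_m2), 1.1)
})

test_that("gridded estimators need a grid; unknown methods are rejected", {
  fs <- fsRow("f1", 0, 0)
  det <- detRow(1, "f1", 2)
  expect_error(estimateBiovolume("gridded_mean", det, fs, grid = NULL),
               "grid")
  expect_error(estimateBiovolume("nonsense", det, fs), "arg")
  # empty detections: zero volume, not an error
  est <- estimateBiovolume(c("aggregate_list", "global_mean"), det[0, ],
                           fs, NULL)
  expect_equal(est$V_ml_m2, c(0, 0))
})

test_that("report rounding is one decimal, half away from zero", {
  expect_equal(roundHalfUp(0.25), 0.3)
  expect_equal(roundHalfUp(-0.25), -0.3)
  expect_equal(roundHalfUp(4.056), 4.1)
  expect_equal(roundHalfUp(66.67, 0), 67)
})
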