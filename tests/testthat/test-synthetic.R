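test_that("ice scene fields respect their invariants and are deterministic", {
  sc <- genIceScene(extent = c(30, 30), cellSize = 0.5, seed = 5)
  expect_identical(dim(sceneDraft(sc)), dim(sceneRoughness(sc)))
  expect_identical(dim(sceneDraft(sc)), dim(sceneTransmittance(sc)))
  expect_true(all(sceneDraft(sc) >= 0))
  expect_true(all(sceneRoughness(sc) >= 0))
  expect_true(all(sceneTransmittance(sc) >= 0 & sceneTransmittance(sc) <= 1))

  sc2 <- genIceScene(extent = c(30, 30), cellSize = 0.5, seed = 5)
  expect_identical(sceneDraft(sc), sceneDraft(sc2))

  # constant draft, no ridges: roughness identically zero
  flat <- genIceScene(extent = c(20, 20), meanDraft = 1, draftSd = 0,
                      nRidges = 0, nPonds = 0, seed = 1)
  expect_true(all(sceneDraft(flat) == 1))
  expect_true(all(sceneRoughness(flat) == 0))

  # a 3 m ridge keel raises the maximum draft to at least its amplitude
  ridged <- genIceScene(extent = c(40, 40), meanDraft = 0.5, draftSd = 0,
                        nRidges = 1, ridgeAmp = 3, nPonds = 0, seed = 2)
  expect_gte(max(sceneDraft(ridged)), 3)

  expect_error(genIceScene(extent = c(-5, 10)), "extent")
  expect_error(genIceScene(extent = c(10, 10), cellSize = 0), "cellSize")
})

test_that("truncated power-law sampler follows the specified law", {
  set.seed(42)
  d <- sampleTruncPowerLaw(5000, -3, 1, 30)
  expect_true(all(d >= 1 & d <= 30))
  # analytic CDF of the truncated Pareto for b = -3
  cdf <- function(q) (1 - q^-2) / (1 - 30^-2)
  ks <- suppressWarnings(stats::ks.test(d, cdf))
  expect_gt(ks$p.value, 0.01)
  # the fitting module recovers the generating exponent
  fit <- fitSizeDistribution(d, dMin = 1, dMax = 30)
  expect_lt(abs(fit$b - (-3)), 0.3)
  expect_error(sampleTruncPowerLaw(10, -3, 5, 5), "dMin")
})

test_that("aggregate field: Poisson limit, exact counts, affinity, types", {
  flat <- genIceScene(extent = c(100, 100), meanDraft = 1, draftSd = 0,
                      nRidges = 0, nPonds = 0, seed = 1)
  # clustering off: homogeneous Poisson; count close to lambda * A and
  # Lloyd's P ~ 1 on gridded counts
  ag <- genAggregateField(flat, intensity = 1, clustering = NULL, seed = 7)
  expect_lt(abs(nrow(ag) - 10000), 4 * sqrt(10000))
  cnt <- countsOnGrid(ag$x_m, ag$y_m, c(100, 100), 5)
  P <- lloydPatchiness(cnt)$P
  expect_gt(P, 0.9); expect_lt(P, 1.1)

  # exact-n mode and per-aggregate invariants
  sc <- genIceScene(extent = c(50, 50), seed = 3)
  ag2 <- genAggregateField(sc, n = 300, seed = 8,
                           sizeLaw = list(b = -3, dMin = 1, dMax = 30))
  expect_equal(nrow(ag2), 300)
  expect_true(all(ag2$diameter_cm >= 1 & ag2$diameter_cm <= 30))
  expect_true(all(ag2$eccentricity >= 0 & ag2$eccentricity < 1))
  rEcc <- ag2$eccentricity[ag2$type == "rounded"]
  fEcc <- ag2$eccentricity[ag2$type == "filamentous"]
  expect_true(all(rEcc <= 0.85))
  expect_true(all(fEcc >= 0.93))

  # draft affinity pulls positions toward draft minima
  agA <- genAggregateField(sc, n = 500, draftAffinity = 2, tau = 0.5,
                           seed = 9)
  meanAt <- mean(sceneValueAt(sc, agA$x_m, agA$y_m, "draft"))
  expect_lt(meanAt, mean(sceneDraft(sc)))

  expect_error(genAggregateField(sc, n = 10,
                                 sizeLaw = list(b = -3, dMin = 5, dMax = 2)))
  expect_error(genAggregateField(sc, n = 10,
                                 sizeLaw = list(b = 1, dMin = 1, dMax = 5)))
  expect_error(genAggregateField(sc, n = 10, intensity = 1), "exactly one")
})

test_that("survey: frame count arithmetic, noise-free consistency, determinism", {
  flat <- genIceScene(extent = c(600, 20), meanDraft = 1, draftSd = 0,
                      nRidges = 0, nPonds = 0, seed = 1)
  noAgg <- genAggregateField(flat, n = 0, intensity = NULL, seed = 1)

  # 500 m random-walk track at 0.5 m/s, one frame per 5 s -> 200 frames
  sv <- surveyParams(trackType = "random-walk", trackLength = 500,
                     speed = 0.5, frameInterval = 5, depthNoiseSd = 0,
                     altimeterNoiseSd = 0, tiltNoiseSd = 0,
                     positionNoiseSd = 0)
  sim <- simulateSurvey(flat, noAgg, sv, renderPixels = FALSE, seed = 2)
  expect_length(sim$frames, 200)

  # zero noise over flat ice: every frame records identical depth/altimeter
  depths <- vapply(sim$frames, function(f) f@depth, numeric(1))
  altis <- vapply(sim$frames, function(f) f@altimeter, numeric(1))
  tilts <- vapply(sim$frames, function(f) f@tilt, numeric(1))
  expect_equal(unique(depths), 2)   # 1 m draft + 1 m standoff
  expect_equal(unique(altis), 1)
  expect_equal(unique(tilts), 0)

  # degenerate track -> empty survey
  tiny <- genIceScene(extent = c(4, 4), meanDraft = 1, draftSd = 0,
                      nRidges = 0, nPonds = 0, seed = 1)
  simEmpty <- simulateSurvey(tiny, noAgg,
                             surveyParams(lineSpacing = 10, margin = 2),
                             renderPixels = FALSE, seed = 1)
  expect_length(simEmpty$frames, 0)

  # determinism: identical seed gives identical navigation and pixels
  sc <- genIceScene(extent = c(25, 25), seed = 4)
  ag <- genAggregateField(sc, n = 100, seed = 5)
  sv2 <- surveyParams(lineSpacing = 10)
  a <- simulateSurvey(sc, ag, sv2, seed = 11)
  b <- simulateSurvey(sc, ag, sv2, seed = 11)
  expect_identical(navTable(a$frames), navTable(b$frames))
  expect_identical(a$frames[[1]]@pixels, b$frames[[1]]@pixels)
  expect_identical(a$truth, b$truth)

  # every rendered instance refers to a real aggregate
  expect_true(all(a$truth$id %in% ag$id))
  expect_true(all(a$truth$pixels_rendered >= 1))
})

test_that("rendering: analytic pixel-area oracle, empty scene, adversarial gradient", {
  calib <- cameraCalib()
  one <- data.frame(id = 1L, x_m = 0, y_m = 0, diameter_cm = 4,
                    eccentricity = 0, orientation_rad = 0, type = "rounded")
  clean <- renderingParams(gradientAmp = 0, noiseSd = 0)
  rf <- renderFrame(one, calib, clean, x = 0, y = 0, standoff = 1)
  # 4 cm disk at 1 m standoff: pi * (20 mm / 4.5 mm px^-1)^2 ~ 62 px
  expect_lt(abs(rf$truth$pixels_rendered - 62), 6)
  mask <- thresholdGreen(rf$pixels)
  expect_equal(sum(mask), rf$truth$pixels_rendered)

  # no aggregates -> empty mask
  rf0 <- renderFrame(one[0, ], calib, clean)
  expect_false(any(thresholdGreen(rf0$pixels)))

  # gradient pushing the background below the threshold creates false
  # positives even with no aggregate present
  adv <- renderingParams(backgroundGreenMean = 150, gradientAmp = 60,
                         gradientAngle = pi / 4, noiseSd = 0,
                         aggregateGreen = 40)
  rfAdv <- renderFrame(one[0, ], calib, adv)
  mAdv <- thresholdGreen(rfAdv$pixels)
  expect_gt(sum(mAdv), 0)
  expect_gt(nrow(labelRegions(mAdv)), 0)

  # empty dynamic range rejected
  bad <- renderingParams(backgroundGreenMean = 90, gradientAmp = 0,
                         aggregateGreen = 95)
  expect_error(renderFrame(one, calib, bad), "dynamic range")
})
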