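test_that("Lloyd's index reproduces closed-form cases", {
  even <- lloydPatchiness(c(2, 2, 2, 2))
  expect_equal(even$m, 2)
  expect_equal(even$mStar, 1)    # 2 + (0/2 - 1)
  expect_equal(even$P, 0.5)

  conc <- lloydPatchiness(c(0, 0, 0, 4))
  expect_equal(conc$m, 1)
  expect_equal(conc$mStar, 4)    # sample variance 4
  expect_equal(conc$P, 4)

  expect_true(is.na(lloydPatchiness(c(0, 0, 0))$P))
  expect_error(lloydPatchiness(c(3)), "two cells")
})

test_that("Lloyd's P is ~1 for Poisson counts and scales with concentration", {
  set.seed(99)
  pois <- rpois(1e4, 5)
  P <- lloydPatchiness(pois)$P
  expect_gt(P, 0.95); expect_lt(P, 1.05)

  # permutation invariance
  x <- c(0, 3, 1, 7, 2, 2)
  expect_equal(lloydPatchiness(x)$P, lloydPatchiness(rev(x))$P)

  # concentrating a fixed total raises P
  expect_gt(lloydPatchiness(c(4, 0, 0, 0))$P,
            lloydPatchiness(c(1, 1, 1, 1))$P)
})

test_that("population-variance Lloyd equals the per-individual crowding oracle", {
  # brute force: mean number of same-cell neighbours per individual
  bruteCrowding <- function(x) sum(x * (x - 1)) / sum(x)
  # every composition of 6 individuals over 4 cells
  configs <- expand.grid(a = 0:6, b = 0:6, c = 0:6, d = 0:6)
  configs <- configs[rowSums(configs) == 6, ]
  maxP <- -Inf; maxConc <- NA
  for (r in seq_len(nrow(configs))) {
    x <- as.numeric(configs[r, ])
    res <- lloydPatchiness(x, variance = "population")
    expect_equal(res$mStar, bruteCrowding(x), tolerance = 1e-12)
    if (res$P > maxP) { maxP <- res$P; maxConc <- max(x) }
  }
  # the most patchy configuration is full concentration in one cell
  expect_equal(maxConc, 6)
})

test_that("size-distribution fit recovers a noiseless power law exactly", {
  # diameters placed at the geometric mids of 4 octave bins on [1, 16] with
  # counts 64, 16, 4, 1: the binned density lies exactly on f(d) = c d^-3
  mids <- 2^(0:3 + 0.5)
  d <- rep(mids, times = c(64, 16, 4, 1))
  fit <- fitSizeDistribution(d, dMin = 1, dMax = 16, nBins = 4)
  expect_equal(fit$b, -3, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_false(fit$flagged)
})

test_that("size-distribution fit recovers sampled exponents within 0.3", {
  for (b in c(-2.2, -3)) {
    set.seed(17)
    d <- sampleTruncPowerLaw(5000, b, 1, 30)
    fit <- fitSizeDistribution(d, dMin = 1, dMax = 30)
    expect_lt(abs(fit$b - b), 0.3)
    # slope invariant under diameter rescaling (c absorbs the scale)
    fit2 <- fitSizeDistribution(d * 3.7, dMin = 3.7, dMax = 30 * 3.7)
    expect_equal(fit2$b, fit$b, tolerance = 1e-9)
    # maximum-likelihood mode lands near the same exponent
    mle <- fitSizeDistribution(d, dMin = 1, method = "mle")
    expect_lt(abs(mle$b - b), 0.3)
  }
})

test_that("degenerate and non-power-law inputs are rejected or flagged", {
  expect_error(fitSizeDistribution(rep(2, 100)), "identical")
  expect_error(fitSizeDistribution(c(1, 2, 3)), "at least")
  # strongly non-monotone spectrum: poor log-log fit gets flagged
  d <- rep(c(1.5, 5, 15), times = c(100, 5, 80))
  fit <- fitSizeDistribution(d, dMin = 1, dMax = 16, nBins = 3)
  expect_lt(fit$r2, 0.8)
  expect_true(fit$flagged)
})

test_that("type fractions map eccentricity extremes to pure types", {
  tf <- typeFractions(c(0.76, 0.89), 0.76, 0.89)
  expect_equal(tf$f_spherical, c(1, 0))
  expect_equal(tf$f_elong, c(0, 1))
  # the published-report convention is the exact mirror image
  lit <- typeFractions(c(0.76, 0.89), 0.76, 0.89, convention = "literal")
  expect_equal(lit$f_spherical, tf$f_elong)
  expect_equal(lit$f_elong, tf$f_spherical)
  # a mid-range station: ICE-1's mean eccentricity 0.79 in [0.76, 0.89]
  mid <- typeFractions(0.79, 0.76, 0.89)
  expect_equal(mid$f_elong, 0.03 / 0.13, tolerance = 1e-9)   # 0.231
  expect_equal(mid$f_spherical + mid$f_elong, 1)
  expect_error(typeFractions(0.5, 0.9, 0.8), "epsMin")
})

test_that("station correlations reproduce degenerate and published cases", {
  tab <- data.frame(x = 1:6, y = 2 * (1:6) + 3, z = -(1:6), k = rep(1, 6))
  res <- stationCorrelations(tab, list(c("x", "y"), c("x", "z"),
                                       c("x", "k")))
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_lt(res$p[1], 1e-6)
  expect_equal(res$r[2], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[3]))    # constant column

  # independent pairs: small average |r| over seeds
  rs <- sapply(1:20, function(s) {
    set.seed(s)
    stationCorrelations(data.frame(a = rnorm(8), b = rnorm(8)),
                        list(c("a", "b")))$r
  })
  expect_lt(mean(abs(rs)), 0.5)

  # the published station table: the size-distribution slope steepens with
  # latitude (printed p = 0.014) and coverage is only weakly correlated
  # with abundance (printed p = 0.16)
  st <- referenceStations()
  pub <- stationCorrelations(st, list(c("slope", "latitude_deg"),
                                      c("coverage_pct", "abundance_per_m2")))
  expect_lt(abs(pub$p[1] - 0.014), 0.01)
  expect_lt(abs(pub$p[2] - 0.16), 0.02)
  expect_lt(pub$r[1], 0)
})
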