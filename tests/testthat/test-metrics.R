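test_that("the window rule follows the sampling rate", {
  expect_equal(matchWindowRule(10), 0.05)
  expect_equal(matchWindowRule(20), 0.025)
  expect_equal(matchWindowRule(30), 0.05)
  expect_equal(matchWindowRule(60), 0.05)
})

test_that("matching handles the elementary cases", {
  st <- SpikeTrain(c(1, 2, 3))
  m <- matchSpikes(st, st, 0.05)
  expect_equal(m$hits, 3L)
  expect_equal(m$misses, 0L)
  expect_equal(m$falsePositives, 0L)
  expect_equal(m$pairedErrors, c(0, 0, 0))

  m2 <- matchSpikes(SpikeTrain(1), SpikeTrain(1.2), 0.05)
  expect_equal(c(m2$hits, m2$misses, m2$falsePositives), c(0L, 1L, 1L))

  # equidistant pair resolves to the earlier truth
  m3 <- matchSpikes(SpikeTrain(c(1.00, 1.04)), SpikeTrain(1.02), 0.05)
  expect_equal(m3$hits, 1L)
  expect_equal(m3$matchedTruth, 1.00)
  expect_equal(m3$pairedErrors, 0.02)
})

test_that("matching agrees with the exhaustive optimal oracle", {
  set.seed(11)
  for (trial in 1:1000) {
    nT <- sample(0:6, 1); nE <- sample(0:6, 1)
    w <- runif(1, 0.02, 0.3)
    truth <- SpikeTrain(sort(runif(nT, 0, 2)))
    est <- SpikeTrain(sort(runif(nE, 0, 2)))
    m <- matchSpikes(truth, est, w)
    o <- oracleMatch(truth, est, w)
    expect_identical(m$hits, o$hits)
    if (m$hits > 0)
      expect_equal(sum(abs(m$pairedErrors)), o$cost, tolerance = 1e-9)
  }
})

test_that("removing estimates never increases the hit count", {
  set.seed(12)
  for (trial in 1:200) {
    truth <- SpikeTrain(sort(runif(6, 0, 2)))
    est <- sort(runif(6, 0, 2))
    w <- runif(1, 0.05, 0.3)
    full <- matchSpikes(truth, SpikeTrain(est), w)$hits
    sub <- matchSpikes(truth, SpikeTrain(est[-sample(6, 1)]), w)$hits
    expect_lte(sub, full)
  }
})

test_that("ROC scores follow the printed formulas and conventions", {
  expect_equal(unname(rocScores(1, 0, 0)), c(1, 1, 1))
  expect_equal(unname(rocScores(8, 2, 2)), c(0.8, 0.8, 0.8))
  expect_equal(unname(rocScores(0, 5, 0)), c(0, 0, 0))
  expect_equal(unname(rocScores(0, 0, 0)), c(0, 0, 0))
})

test_that("spike distance reproduces closed-form cases", {
  st <- SpikeTrain(c(1, 2, 3))
  d0 <- spikeDistance(st, st, 0.05)
  expect_equal(d0$distance, 0)
  expect_equal(d0$inverse, 100)

  d1 <- spikeDistance(SpikeTrain(1), SpikeTrain(1.02), 0.05)
  expect_equal(d1$distance, 0.4, tolerance = 1e-12)   # 20 * 0.02
  expect_equal(d1$inverse, 2.5, tolerance = 1e-12)

  d2 <- spikeDistance(SpikeTrain(c(1, 2)), SpikeTrain(), 0.05)
  expect_equal(d2$distance, 1)                        # 2 deletions / 2

  d3 <- spikeDistance(SpikeTrain(), SpikeTrain(c(1, 2, 3)), 0.05)
  expect_equal(d3$distance, 3)                        # raw insertions
  expect_false(d3$normalized)
})

test_that("the spike-distance DP agrees with brute-force edit enumeration", {
  set.seed(13)
  for (trial in 1:1000) {
    nT <- sample(0:4, 1); nE <- sample(0:4, 1)
    w <- runif(1, 0.02, 0.3)
    truth <- SpikeTrain(sort(runif(nT, 0, 1.5)))
    est <- SpikeTrain(sort(runif(nE, 0, 1.5)))
    d <- spikeDistance(truth, est, w)
    raw <- if (nT) d$distance * nT else d$distance
    expect_equal(raw, oracleSpikeDistance(truth, est, w),
                 tolerance = 1e-9)
  }
})

test_that("CosMIC matches its closed-form values", {
  e <- 0.05
  st <- SpikeTrain(c(0.5, 1))
  expect_equal(as.numeric(cosmic(st, st, e)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(cosmic(SpikeTrain(0.5),
                                 SpikeTrain(0.5 + 2 * e), e)), 0)
  # offset e/2: closed-form triangle overlap 9/16
  got <- as.numeric(cosmic(SpikeTrain(0.5), SpikeTrain(0.5 + e / 2), e))
  expect_equal(got, 0.5625, tolerance = 2e-3)
  # cross-check by independent numeric integration on a fine grid
  grid <- seq(0.5 - e, 0.5 + 1.5 * e, length.out = 10000)
  tri <- function(t, T) pmax(0, (e - abs(t - T)) / e)
  num <- 2 * sum(pmin(tri(grid, 0.5), tri(grid, 0.5 + e / 2))) /
    (sum(tri(grid, 0.5)) + sum(tri(grid, 0.5 + e / 2)))
  expect_equal(got, num, tolerance = 2e-3)
})

test_that("CosMIC is bounded, symmetric, and flags the empty-empty case", {
  set.seed(14)
  for (trial in 1:50) {
    a <- SpikeTrain(sort(runif(sample(1:5, 1), 0, 1)))
    b <- SpikeTrain(sort(runif(sample(1:5, 1), 0, 1)))
    x <- as.numeric(cosmic(a, b, 0.05))
    expect_gte(x, 0); expect_lte(x, 1)
    expect_equal(x, as.numeric(cosmic(b, a, 0.05)), tolerance = 1e-12)
  }
  both <- cosmic(SpikeTrain(), SpikeTrain(), 0.05)
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "trivial"))
  expect_equal(as.numeric(cosmic(SpikeTrain(1), SpikeTrain(), 0.05)), 0)
})

test_that("the hyperacuity index is the interval over the mean error", {
  expect_equal(hyperacuityIndex(c(0.025, -0.025), 10), 4)
  expect_error(hyperacuityIndex(numeric(), 10), "no paired errors")
  # all-zero errors hit the epsilon floor instead of dividing by zero
  expect_equal(hyperacuityIndex(c(0, 0), 10), 0.1 / 1e-6)
  # frame-onset estimates of uniform spike times approach the Nyquist
  # limit of 2 (Monte-Carlo oracle)
  set.seed(15)
  u <- runif(20000, 0, 0.1)               # quantization errors at 10 Hz
  expect_equal(hyperacuityIndex(u, 10), 2, tolerance = 0.03)
})

test_that("evaluateSpikes composes the metrics coherently", {
  truth <- SpikeTrain(c(1, 2, 3, 4))
  est <- SpikeTrain(c(1.01, 2.02, 3.3))
  r <- evaluateSpikes(truth, est, samplingRate = 10)
  expect_equal(r@window, 0.05)
  expect_equal(r@hits + r@misses, 4L)
  expect_equal(r@hits, 2L)
  expect_equal(r@falsePositives, 1L)
  expect_equal(r@f1, 2 * (0.5 * 2 / 3) / (0.5 + 2 / 3), tolerance = 1e-12)
  expect_equal(r@hyperacuityIndex, 0.1 / mean(c(0.01, 0.02)),
               tolerance = 1e-6)
  expect_equal(sort(abs(r@pairedErrors)), c(0.01, 0.02), tolerance = 1e-9)
})

test_that("report summaries have zero spread for constant metrics", {
  r <- evaluateSpikes(SpikeTrain(c(1, 2)), SpikeTrain(c(1, 2)), 10)
  s <- summarizeReports(list(r, r, r))
  expect_true(all(s$twoSEM == 0))
  expect_equal(s$mean[s$metric == "f1"], 1)
})
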