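test_that("spike counts follow the Poisson law", {
  counts <- vapply(1:1000, function(s)
    length(simulateSpikeTrain(1, 500, seed = s)), numeric(1))
  # per-seed counts lie in the +/- 3 sigma band around 500 almost surely
  expect_gt(mean(counts >= 433 & counts <= 567), 0.99)
  expect_lt(abs(mean(counts) - 500), 3)
  expect_error(simulateSpikeTrain(1, 0), "duration")
  expect_error(simulateSpikeTrain(0, 10), "firingRate")
})

test_that("inter-spike intervals are exponential", {
  st <- simulateSpikeTrain(5, 2100, seed = 99)
  isi <- diff(spikeTimes(st))[1:10000]
  # a handful of floating-point-identical intervals only triggers the
  # ks.test ties caveat; the distributional check is unaffected
  expect_gt(suppressWarnings(stats::ks.test(isi, "pexp", 5))$p.value, 0.01)
})

test_that("the power-law nonlinearity acts only above the one-spike level", {
  expect_equal(applyAlphaNonlinearity(1, 2.7), 1)
  expect_equal(applyAlphaNonlinearity(2, 1), 2)
  expect_equal(applyAlphaNonlinearity(4, 0.5), 2)
  expect_equal(applyAlphaNonlinearity(c(-1, 0.5, 1, 2), 2),
               c(-1, 0.5, 1, 4))
  # continuity at v = 1
  eps <- 1e-9
  expect_lt(abs(applyAlphaNonlinearity(1 + eps, 3) -
                applyAlphaNonlinearity(1 - eps, 3)), 1e-7)
  expect_error(applyAlphaNonlinearity(c(1, NA), 2), "finite")
})

test_that("an empty train with no noise synthesizes the flat baseline", {
  model <- CaSpikeModel(0.01, 0.5, 1, baseline = 0.7)
  tr <- synthesizeTrace(SpikeTrain(), model, snr = Inf, samplingRate = 20,
                        duration = 5)
  expect_true(all(traceValues(tr) == 0.7))
})

test_that("the noiseless transient peaks at the closed-form argmax", {
  model <- CaSpikeModel(0.05, 0.4, 1)
  tr <- synthesizeTrace(SpikeTrain(0), model, snr = Inf,
                        samplingRate = 1000, duration = 3)
  peakT <- frameTimes(tr)[which.max(traceValues(tr))]
  expect_equal(peakT, 0.05 * log((0.05 + 0.4) / 0.05), tolerance = 2e-3)
})

test_that("noise SD matches the SNR calibration", {
  model <- CaSpikeModel(0.01, 0.5, 1)
  clean <- synthesizeTrace(SpikeTrain(1), model, snr = Inf,
                           samplingRate = 100, duration = 1000)
  noisy <- synthesizeTrace(SpikeTrain(1), model, snr = 5,
                           samplingRate = 100, duration = 1000, seed = 3)
  target <- singleSpikePeak(model) / 5
  expect_equal(sd(traceValues(noisy) - traceValues(clean)), target,
               tolerance = 0.02)
})

test_that("synthesis equals the linear prediction when alpha = 1, sigma = 0", {
  model <- CaSpikeModel(0.01, 0.5, 1.3, baseline = 0.2)
  st <- simulateSpikeTrain(2, 20, seed = 5)
  tr <- synthesizeTrace(st, model, alpha = 1, snr = Inf,
                        samplingRate = 30, duration = 20)
  expect_equal(traceValues(tr), linearPrediction(st, model, frameTimes(tr)),
               tolerance = 1e-12)
})

test_that("near-zero noise reproduces the linear prediction", {
  cfgHi <- SimulationConfig(nCells = 2, spikesPerCell = 10, alpha = 1,
                            snr = 1e6, samplingRate = 30, seed = 8)
  ds <- generateDataset(cfgHi)
  for (cell in ds) {
    pred <- linearPrediction(cell$spikes,
                             CaSpikeModel(cfgHi@tau1, cfgHi@tau2),
                             frameTimes(cell$trace))
    relErr <- max(abs(traceValues(cell$trace) - pred)) /
      max(abs(pred))
    expect_lt(relErr, 1e-4)
  }
})

test_that("datasets are deterministic and carry the stated structure", {
  cfg <- SimulationConfig(nCells = 10, spikesPerCell = 50, seed = 21,
                          samplingRate = 20)
  ds1 <- generateDataset(cfg)
  ds2 <- generateDataset(cfg)
  expect_identical(lapply(ds1, function(c) traceValues(c$trace)),
                   lapply(ds2, function(c) traceValues(c$trace)))
  expect_identical(attr(ds1, "train"), 1:5)
  expect_identical(attr(ds1, "test"), 6:10)
  total <- sum(vapply(ds1, function(c) length(c$spikes), numeric(1)))
  expect_gt(total, 500 - 3 * sqrt(500))   # expected 500 spikes in 10 cells
  expect_lt(total, 500 + 3 * sqrt(500))
  # per-cell duration = spikesPerCell / firingRate
  expect_equal(length(ds1[[1]]$trace) / samplingRate(ds1[[1]]$trace), 50)
})

test_that("raising the SNR never increases deviation from the clean trace", {
  model <- CaSpikeModel(0.01, 0.5, 1)
  st <- simulateSpikeTrain(1, 30, seed = 2)
  clean <- traceValues(synthesizeTrace(st, model, snr = Inf,
                                       samplingRate = 30, duration = 30))
  mses <- vapply(c(3, 5, 10, 100), function(snr) {
    tr <- synthesizeTrace(st, model, snr = snr, samplingRate = 30,
                          duration = 30, seed = 7)
    mean((traceValues(tr) - clean)^2)
  }, numeric(1))
  expect_true(all(diff(mses) <= 0))
})
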