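test_that("the kernel is zero before and at onset and validates taus", {
  expect_equal(kernelValue(c(-1, -0.01, 0), 0, 0.05, 0.4), c(0, 0, 0))
  expect_gt(kernelValue(0.01, 0, 0.05, 0.4), 0)
  expect_error(kernelValue(1, 0, 0.4, 0.05), "tau1 < tau2")
})

test_that("kernel peak matches the closed form and a brute-force grid", {
  s <- seq(0, 2, by = 1e-4)                # 10 kHz grid oracle
  g <- kernelValue(s, 0, 0.05, 0.4)
  expect_equal(s[which.max(g)], 0.05 * log((0.05 + 0.4) / 0.05),
               tolerance = 1e-3)
  m <- CaSpikeModel(0.05, 0.4, 1)
  expect_equal(singleSpikePeak(m), max(g), tolerance = 1e-6)
})

test_that("linear prediction superposes transients additively", {
  model <- CaSpikeModel(0.01, 0.5, 1.5, baseline = 0.3)
  tt <- seq(0, 20, by = 1 / 30)
  expect_equal(linearPrediction(SpikeTrain(), model, tt),
               rep(0.3, length(tt)))
  one <- linearPrediction(SpikeTrain(5), model, tt) - 0.3
  two <- linearPrediction(SpikeTrain(c(5, 5)), model, tt) - 0.3
  expect_equal(two, 2 * one, tolerance = 1e-12)
  st <- sort(runif(5, 0, 18))
  full <- linearPrediction(SpikeTrain(st), model, tt)
  parts <- Reduce(`+`, lapply(st, function(T)
    linearPrediction(SpikeTrain(T), model, tt) - 0.3)) + 0.3
  expect_equal(full, parts, tolerance = 1e-12)
})

test_that("a noiseless in-model trace is recovered near-exactly", {
  # true taus placed on the search grid so the exact model is reachable
  tau1g <- exp(seq(log(0.005), log(0.2), length.out = 20))
  tau2g <- exp(seq(log(0.1), log(2.0), length.out = 25))
  model <- CaSpikeModel(tau1g[8], tau2g[13], 1.4, baseline = 0.25)
  rate <- 30
  st <- SpikeTrain((seq_len(12) * 3) - 1)   # frame-aligned isolated spikes
  tr <- synthesizeTrace(st, model, snr = Inf, samplingRate = rate,
                        duration = 40)
  fit <- fitSpikeModel(tr, st)
  expect_equal(fit@tau2, model@tau2, tolerance = 1e-6)
  expect_equal(fit@amplitude, model@amplitude, tolerance = 1e-6)
  expect_equal(fit@baseline, model@baseline, tolerance = 1e-6)
  expect_lt(fit@noiseSigma, 1e-8)
})

test_that("a flat trace with a claimed spike fails the fit", {
  tr <- CalciumTrace(rep(1, 200), 20)
  expect_error(suppressWarnings(fitSpikeModel(tr, SpikeTrain(5))),
               "degenerate|no transient")
})

test_that("parameters are recovered from noisy simulated data", {
  true <- CaSpikeModel(0.01, 0.5, 1, baseline = 0, noiseSigma = 0.2)
  snr <- singleSpikePeak(true) / 0.2
  st <- simulateSpikeTrain(1, 250, seed = 31)
  tr <- synthesizeTrace(st, true, alpha = 1, snr = snr, samplingRate = 60,
                        duration = 250, seed = 32)
  fit <- suppressWarnings(fitSpikeModel(tr, st))
  expect_lt(abs(fit@tau2 - 0.5) / 0.5, 0.20)
  expect_lt(abs(fit@amplitude - 1), 0.10)
  expect_lt(abs(fit@noiseSigma - 0.2) / 0.2, 0.15)
  # EM-style ascent: inner-loop log-likelihood never decreases
  expect_false(is.unsorted(attr(fit, "llHistory")))
})

test_that("the fit is equivariant under affine rescaling of the trace", {
  true <- CaSpikeModel(0.01, 0.5, 1)
  st <- simulateSpikeTrain(1, 60, seed = 41)
  tr <- synthesizeTrace(st, true, snr = 8, samplingRate = 30,
                        duration = 60, seed = 42)
  f1 <- suppressWarnings(fitSpikeModel(tr, st))
  c_ <- 3.7
  tr2 <- CalciumTrace(traceValues(tr) * c_, samplingRate(tr))
  f2 <- suppressWarnings(fitSpikeModel(tr2, st))
  expect_equal(f2@tau1, f1@tau1, tolerance = 1e-9)
  expect_equal(f2@tau2, f1@tau2, tolerance = 1e-9)
  expect_equal(f2@amplitude, c_ * f1@amplitude, tolerance = 1e-6)
  expect_equal(f2@baseline, c_ * f1@baseline, tolerance = 1e-6)
  expect_equal(f2@noiseSigma, c_ * f1@noiseSigma, tolerance = 1e-6)
})
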