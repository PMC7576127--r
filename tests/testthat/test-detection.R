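test_that("a constant trace scores zero everywhere", {
  tr <- CalciumTrace(rep(2, 300), 30)
  sc <- coincidenceScore(tr, CaSpikeModel(0.01, 0.5, 1))
  expect_true(all(attr(sc, "raw") == 0))
  expect_true(all(sc == 0))
})

test_that("the score peaks at the spike onset frame and ignores offsets", {
  model <- CaSpikeModel(0.01, 0.5, 1)
  rate <- 30
  T <- 5 + 0.4 / rate                       # onset inside frame 150
  tr <- synthesizeTrace(SpikeTrain(T), model, snr = Inf,
                        samplingRate = rate, duration = 12)
  sc <- coincidenceScore(tr, model)
  onsetFrame <- floor(T * rate) + 1L
  expect_equal(which.max(sc), onsetFrame)
  # brute-force matched-filter oracle over all frames
  y <- traceValues(tr)
  dy <- diff(y)
  m <- ceiling(5 * model@tau2 * rate)
  gk <- kernelValue((0:m) / rate, 0, model@tau1, model@tau2)
  dg <- diff(gk)
  oracle <- vapply(seq_len(length(dy) - m + 1L), function(k)
    sum(dy[k:(k + m - 1L)] * dg), numeric(1))
  expect_equal(which.max(oracle), onsetFrame)
  expect_equal(max(attr(sc, "raw")), max(oracle), tolerance = 1e-12)

  tr2 <- CalciumTrace(y + 5, rate)
  expect_equal(coincidenceScore(tr2, model), sc, tolerance = 1e-9)
})

test_that("the score errors out when the kernel support exceeds the trace", {
  tr <- CalciumTrace(rnorm(10), 30)
  expect_error(coincidenceScore(tr, CaSpikeModel(0.01, 1.5)), "support")
})

test_that("candidate extraction finds crossings and pads edges", {
  model <- CaSpikeModel(0.01, 0.5, 1)
  rate <- 30
  st <- SpikeTrain(c(0.02, 5, 10))          # one spike near the trace edge
  tr <- synthesizeTrace(st, model, snr = 1e4, samplingRate = rate,
                        duration = 15, seed = 2)
  sc <- coincidenceScore(tr, model)
  cfg <- DetectionConfig(scoreThreshold = 3, segmentPre = 2,
                         segmentPost = 4)
  cands <- extractCandidates(tr, sc, cfg)
  expect_equal(length(cands), 3L)
  expect_equal(ncol(cands@frames), 2 + 1 + 4)
  # pseudo-spike times land on the onset frames
  expect_equal(sort(pseudoTimes(cands)),
               floor(spikeTimes(st) * rate) / rate, tolerance = 1e-9)
  # threshold above the maximum: nothing
  cfgHi <- DetectionConfig(scoreThreshold = max(sc) + 1)
  expect_length(extractCandidates(tr, sc, cfgHi), 0L)
  # the first candidate starts before frame segmentPre: replicated edge
  first <- cands[which.min(pseudoTimes(cands))]
  expect_equal(first@frames[1, 1], first@frames[1, 2])
})

test_that("candidate labelling marks matched crossings as spikes", {
  model <- CaSpikeModel(0.01, 0.5, 1)
  st <- SpikeTrain(c(3, 8))
  tr <- synthesizeTrace(st, model, snr = 1e4, samplingRate = 30,
                        duration = 12, seed = 3)
  sc <- coincidenceScore(tr, model)
  cands <- extractCandidates(tr, sc, DetectionConfig(scoreThreshold = 3))
  lab <- labelCandidates(cands, st, matchWindowRule(30))
  expect_setequal(unique(candidateLabels(lab)), "spike")
  labNone <- labelCandidates(cands, SpikeTrain(c(1, 6)), 0.05)
  expect_setequal(unique(candidateLabels(labNone)), "non-spike")
})

test_that("detection optimization honours its tie-break contracts", {
  # well-separated spikes on a jittered lattice: every spike produces its
  # own dominant score peak, so every sensible configuration scores F1 = 1
  model <- CaSpikeModel(0.01, 0.5, 1)
  set.seed(9)
  ds <- lapply(1:2, function(i) {
    st <- SpikeTrain(seq(1, 12.5, by = 1) + runif(12, 0, 1 / 30))
    list(trace = synthesizeTrace(st, model, snr = 50, samplingRate = 30,
                                 duration = 16, seed = 90 + i),
         spikes = st)
  })
  # single-configuration grid is returned unchanged
  cfg1 <- optimizeDetection(ds[1:2], model, thresholds = 2.5,
                            segmentPre = 2, segmentPost = 4)
  expect_equal(cfg1@scoreThreshold, 2.5)
  expect_equal(cfg1@segmentPre, 2L)
  expect_equal(cfg1@segmentPost, 4L)
  # on noiseless-grade data every threshold separates perfectly: the
  # tie-break must pick the lowest threshold and shortest segment
  cfg2 <- optimizeDetection(ds[1:2], model, thresholds = c(2, 3),
                            segmentPre = c(1, 2), segmentPost = c(2, 4))
  expect_equal(attr(cfg2, "f1"), 1)
  expect_equal(cfg2@scoreThreshold, 2)
  expect_equal(cfg2@segmentPre, 1L)
  expect_equal(cfg2@segmentPost, 2L)
  # and the chosen threshold admits every true spike as a candidate
  for (cell in ds[1:2]) {
    sc <- coincidenceScore(cell$trace, model)
    cands <- extractCandidates(cell$trace, sc, cfg2)
    m <- matchSpikes(cell$spikes, SpikeTrain(sort(pseudoTimes(cands))),
                     cfg2@matchWindow)
    expect_equal(m$misses, 0L)
  }
})

test_that("the classifier separates a separable toy set exactly", {
  n <- 40
  frames <- rbind(matrix(1, n / 2, 4), matrix(0, n / 2, 4))
  scores <- frames * 2
  cands <- new("CandidateSet", frames = frames, scores = scores,
               pt = seq_len(n) / 10,
               label = rep(c("spike", "non-spike"), each = n / 2))
  clf <- trainClassifier(cands)
  expect_identical(classifyCandidates(clf, cands), candidateLabels(cands))
  # empty candidate list classifies to an empty label vector
  expect_identical(classifyCandidates(clf, new("CandidateSet")),
                   character())
  # single-class training refuses
  expect_error(trainClassifier(cands[1:(n / 2)]), "single class")
  # feature-length mismatch refuses
  bad <- new("CandidateSet", frames = matrix(0, 2, 6),
             scores = matrix(0, 2, 6), pt = c(1, 2),
             label = rep("unknown", 2))
  expect_error(classifyCandidates(clf, bad), "mismatch")
})

test_that("training-set classification accuracy is high on clean data", {
  ds <- generateDataset(SimulationConfig(nCells = 4, spikesPerCell = 25,
                                         snr = 10, samplingRate = 30,
                                         seed = 23))
  model <- suppressWarnings(
    fitSpikeModel(lapply(ds, `[[`, "trace"), lapply(ds, `[[`, "spikes")))
  cfg <- DetectionConfig(scoreThreshold = 1.5, segmentPre = 2,
                         segmentPost = 4,
                         matchWindow = matchWindowRule(30))
  labelled <- lapply(ds, function(cell) {
    sc <- coincidenceScore(cell$trace, model)
    labelCandidates(extractCandidates(cell$trace, sc, cfg), cell$spikes,
                    cfg@matchWindow)
  })
  pool <- hyperspike:::.bindCandidates(labelled)
  clf <- trainClassifier(pool)
  acc <- mean(classifyCandidates(clf, pool) == candidateLabels(pool))
  expect_gte(acc, 0.95)
})
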