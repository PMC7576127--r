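test_that("trace write/read round trip is the identity", {
  tr <- CalciumTrace(c(0.1, 0.5, -0.2, 1.4, 0.0), samplingRate = 12.5,
                     startTime = 0.3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, path)
  back <- readTrace(path)
  expect_equal(length(back), length(tr))
  expect_equal(traceValues(back), traceValues(tr), tolerance = 1e-9)
  expect_equal(samplingRate(back), samplingRate(tr), tolerance = 1e-9)
  expect_equal(startTime(back), startTime(tr), tolerance = 1e-9)
})

test_that("two-column trace files infer the sampling rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(sprintf("%.10g,%.3g", seq(0, 0.9, by = 0.1), rnorm(10)), path)
  tr <- readTrace(path)
  expect_equal(samplingRate(tr), 10, tolerance = 1e-6)
})

test_that("non-uniform time columns are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.0,1", "0.1,2", "0.35,3"), path)
  expect_error(readTrace(path), "non-uniform")
})

test_that("trace reader rejects short files and non-numeric entries", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("0.0,1", path)
  expect_error(readTrace(path), "fewer than 2")
  writeLines(c("0.0,1", "0.1,abc"), path)
  expect_error(readTrace(path), "non-numeric")
})

test_that("spike files round trip, sort with a warning, reject negatives", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeSpikes(SpikeTrain(c(0.5, 1.5, 2.25)), path)
  expect_equal(spikeTimes(readSpikes(path)), c(0.5, 1.5, 2.25),
               tolerance = 1e-9)

  writeLines(character(), path)
  expect_length(spikeTimes(readSpikes(path)), 0)

  writeLines(c("1.5", "0.5"), path)
  expect_warning(st <- readSpikes(path), "unsorted")
  expect_equal(spikeTimes(st), c(0.5, 1.5))

  writeLines("-1.0", path)
  expect_error(readSpikes(path), "negative")
})

test_that("evaluation reports round trip through JSON", {
  rep <- evaluateSpikes(SpikeTrain(c(1, 2, 3)), SpikeTrain(c(1.01, 2, 4)),
                        samplingRate = 10)
  path <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, path)
  back <- readReport(path)
  expect_equal(back@hits, rep@hits)
  expect_equal(back@f1, rep@f1, tolerance = 1e-9)
  expect_equal(back@pairedErrors, rep@pairedErrors, tolerance = 1e-9)
  expect_equal(back@spikeDistance, rep@spikeDistance, tolerance = 1e-9)
})

test_that("datasets round trip through the columnar container", {
  skip_if_not_installed("arrow")
  ds <- generateDataset(SimulationConfig(nCells = 3, spikesPerCell = 5,
                                         samplingRate = 20, seed = 4))
  path <- withr::local_tempfile(fileext = ".feather")
  writeDataset(ds, path)
  back <- readDataset(path)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_equal(traceValues(back[[i]]$trace), traceValues(ds[[i]]$trace),
                 tolerance = 1e-9)
    expect_equal(spikeTimes(back[[i]]$spikes), spikeTimes(ds[[i]]$spikes),
                 tolerance = 1e-9)
  }
})

test_that("class validity catches malformed objects", {
  expect_error(CalciumTrace(c(1, NA), 10), "finite")
  expect_error(CalciumTrace(1, 10), "2 frames")
  expect_error(CalciumTrace(c(1, 2), -1), "positive")
  expect_error(SpikeTrain(c(2, 1)), "non-decreasing")
  expect_error(SpikeTrain(-1), "non-negative")
  expect_error(CaSpikeModel(0.5, 0.2), "tau1 < tau2")
  expect_error(CaSpikeModel(0.01, 0.5, amplitude = -1), "positive")
  expect_error(DetectionConfig(vernierFactor = 1), "vernierFactor")
})
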