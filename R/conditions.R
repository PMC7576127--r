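# The stratified benchmark design and its driver, shared by the test suite
# and the acceptance script.

#' Stratified benchmark conditions for the hyperacuity experiment
#'
#' A fixed 12-condition stratified subset of the simulation study grid
#' (sampling 10/30/60 Hz x nonlinearity 0.5/1/1.5 x decay constant
#' 0.2/0.5/1.0 s x SNR 3/5/10 at 1 Hz firing): four (alpha, tau2, SNR)
#' combinations per sampling rate, balanced so that every level of every
#' factor appears exactly four times across the twelve conditions.
#'
#' @return a data.frame with columns \code{samplingRate}, \code{alpha},
#'   \code{tau2}, \code{snr}.
#' @export
benchmarkConditions <- function() {
  base <- data.frame(
    alpha = c(1.0, 0.5, 1.5),
    tau2 = c(0.5, 0.2, 1.0),
    snr = c(5, 10, 3))
  extra <- data.frame(
    samplingRate = c(10, 30, 60),
    alpha = c(1.0, 0.5, 1.5),
    tau2 = c(0.2, 1.0, 0.5),
    snr = c(3, 5, 10))
  out <- rbind(
    do.call(rbind, lapply(c(10, 30, 60), function(r)
      cbind(samplingRate = r, base))),
    extra)
  out[order(out$samplingRate, out$alpha, out$tau2), ]
}

#' Run one benchmark condition end to end
#'
#' Generates a 10-cell dataset (50 expected spikes per cell at 1 Hz
#' firing) for one condition, runs the supervised pipeline with a 5/5
#' train-test split, and pools hit-case timing errors across test cells
#' for the hyperacuity index, for both the vernier-refined estimates and
#' the grid-quantized (SJ = 0) baseline.
#'
#' @param samplingRate,alpha,tau2,snr the condition.
#' @param seed master seed for the dataset.
#' @param firingRate,nCells,spikesPerCell study-condition defaults.
#' @return list with \code{index} (hyperacuity index over pooled hits),
#'   \code{gridIndex} (same with SJ forced to 0), \code{meanF1} (mean test
#'   F1), \code{reports} and \code{run}.
#' @export
runBenchmarkCondition <- function(samplingRate, alpha, tau2, snr, seed,
                                  firingRate = 1, nCells = 10,
                                  spikesPerCell = 50) {
  cfg <- SimulationConfig(firingRate = firingRate, nCells = nCells,
                          spikesPerCell = spikesPerCell, tau1 = 0.01,
                          tau2 = tau2, alpha = alpha, snr = snr,
                          samplingRate = samplingRate, seed = seed)
  ds <- generateDataset(cfg)
  run <- runSupervised(ds[attr(ds, "train")], ds[attr(ds, "test")])
  test <- ds[attr(ds, "test")]
  pooled <- unlist(lapply(run$reports, function(r)
    if (is.null(r)) numeric() else r@pairedErrors))
  # grid-quantized baseline: same detections and the same hit pairs, with
  # the jitter correction zeroed (spike times back on the frame grid)
  pooledGrid <- unlist(lapply(seq_along(test), function(j) {
    est <- run$estimates[[j]]
    if (!length(est)) return(numeric())
    m <- matchSpikes(test[[j]]$spikes, est, run$config@matchWindow)
    if (!m$hits) return(numeric())
    idx <- match(m$matchedEstimates, spikeTimes(est))
    attr(est, "pt")[idx] - m$matchedTruth
  }))
  f1s <- vapply(run$reports, function(r)
    if (is.null(r)) NA_real_ else r@f1, numeric(1))
  list(
    index = if (length(pooled)) hyperacuityIndex(pooled, samplingRate)
            else NA_real_,
    gridIndex = if (length(pooledGrid))
      hyperacuityIndex(pooledGrid, samplingRate) else NA_real_,
    meanF1 = mean(f1s, na.rm = TRUE),
    reports = run$reports,
    run = run)
}
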