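# Synthetic data with the statistical structure of simultaneous
# imaging/electrophysiology benchmarks: homogeneous Poisson spiking,
# double-exponential transients with continuous-time onsets (so sampling
# jitter arises naturally), a power-law nonlinearity acting above the
# one-spike level, and Gaussian noise calibrated to a target SNR.

# Counter-based per-cell seed derivation: reproducible regardless of the
# order cells are generated in, and kept below 2^31.
.deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + as.double(stream) * 9973) %%
               2147483647)
}

#' Generate a homogeneous Poisson spike train
#'
#' @param firingRate mean rate (Hz), positive.
#' @param duration interval length (s), positive; spikes lie in
#'   \code{[0, duration)}.
#' @param seed integer seed (optional; when missing the current RNG stream
#'   is used).
#' @return a \code{\linkS4class{SpikeTrain}}.
#' @examples
#' st <- simulateSpikeTrain(1, 500, seed = 7)
#' length(st) # Poisson with mean 500
#' @export
simulateSpikeTrain <- function(firingRate, duration, seed = NULL) {
  if (!is.numeric(firingRate) || firingRate <= 0)
    stop("firingRate must be positive")
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- stats::rpois(1, firingRate * duration)
  SpikeTrain(sort(stats::runif(n, 0, duration)))
}

#' Power-law response nonlinearity
#'
#' Applies \eqn{f(v) = v^{\alpha}} for \eqn{v > 1} and \eqn{f(v) = v}
#' otherwise, pointwise. \eqn{v} is in normalized units where 1 is the peak
#' of a single-spike transient, so the nonlinearity only distorts
#' superpositions (bursts). Continuous at \eqn{v = 1}.
#'
#' @param x numeric vector (finite), in single-spike-peak units.
#' @param alpha positive exponent; \eqn{\alpha < 1} saturates,
#'   \eqn{\alpha > 1} grows superlinearly.
#' @return transformed vector.
#' @export
applyAlphaNonlinearity <- function(x, alpha) {
  if (!all(is.finite(x))) stop("x must be finite")
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  ifelse(x > 1, x^alpha, x)
}

#' Synthesize a calcium trace from a spike train
#'
#' The linear response \eqn{x(t) = a \sum_i g(t, T_i)} is evaluated at frame
#' onsets with continuous-time spike onsets; the power-law nonlinearity is
#' applied in single-spike-peak units; i.i.d. Gaussian noise with
#' SD = (single-spike peak) / \code{snr} is added; the baseline is added
#' last.
#'
#' @param spikes a \code{SpikeTrain} within \code{[0, duration)}.
#' @param model a \code{CaSpikeModel} (its \code{noiseSigma} is ignored; the
#'   noise level comes from \code{snr}).
#' @param alpha nonlinearity exponent.
#' @param snr single-spike peak amplitude over noise SD; \code{Inf} for a
#'   noiseless trace.
#' @param samplingRate imaging rate (Hz).
#' @param duration trace length (s).
#' @param seed integer seed for the noise (optional).
#' @return a \code{\linkS4class{CalciumTrace}}.
#' @export
synthesizeTrace <- function(spikes, model, alpha = 1, snr = Inf,
                            samplingRate, duration, seed = NULL) {
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  st <- spikeTimes(spikes)
  if (length(st) && (min(st) < 0 || max(st) >= duration))
    stop("spikes must lie within [0, duration)")
  n <- max(2L, floor(duration * samplingRate))
  tt <- (seq_len(n) - 1L) / samplingRate
  x <- .superpose(tt, st, model@tau1, model@tau2) * model@amplitude
  peak1 <- singleSpikePeak(model)
  y <- peak1 * applyAlphaNonlinearity(x / peak1, alpha)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.finite(snr)) y <- y + stats::rnorm(n, 0, peak1 / snr)
  CalciumTrace(y + model@baseline, samplingRate, 0)
}

# sum of unit kernels over spikes, evaluated at times tt; support-truncated
.superpose <- function(tt, spikeTimes, tau1, tau2, support = NULL) {
  out <- numeric(length(tt))
  if (!length(spikeTimes)) return(out)
  if (is.null(support)) support <- -tau2 * log(1e-8) # kernel below 1e-8
  step <- if (length(tt) > 1L) tt[2] - tt[1] else 1
  for (T in spikeTimes) {
    i0 <- max(1L, ceiling((T - tt[1]) / step))
    i1 <- min(length(tt), floor((T + support - tt[1]) / step) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    out[idx] <- out[idx] + kernelValue(tt[idx], T, tau1, tau2)
  }
  out
}

#' Generate a multi-cell dataset with a train/test split
#'
#' Each cell gets an independent Poisson spike train (duration =
#' \code{spikesPerCell / firingRate}, so spike counts vary around the
#' nominal value) and a synthesized trace, with per-cell seeds derived from
#' the master seed by a counter-based scheme. The first half of the cells is
#' designated the training split and the second half the test split.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @return a list of cells, each \code{list(trace=, spikes=)}, with
#'   attributes \code{train} and \code{test} holding the split indices and
#'   \code{config} the generating configuration.
#' @examples
#' ds <- generateDataset(SimulationConfig(nCells = 4, spikesPerCell = 10,
#'                                        samplingRate = 20, seed = 1))
#' attr(ds, "train"); attr(ds, "test")
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  duration <- config@spikesPerCell / config@firingRate
  model <- CaSpikeModel(config@tau1, config@tau2, config@amplitude,
                        config@baseline)
  cells <- lapply(seq_len(config@nCells), function(i) {
    spikeSeed <- .deriveSeed(config@seed, 2L * i)
    noiseSeed <- .deriveSeed(config@seed, 2L * i + 1L)
    spikes <- simulateSpikeTrain(config@firingRate, duration,
                                 seed = spikeSeed)
    trace <- synthesizeTrace(spikes, model, alpha = config@alpha,
                             snr = config@snr,
                             samplingRate = config@samplingRate,
                             duration = duration, seed = noiseSeed)
    list(trace = trace, spikes = spikes)
  })
  half <- config@nCells %/% 2L
  if (config@nCells >= 2L) {
    attr(cells, "train") <- seq_len(half)
    attr(cells, "test") <- seq.int(half + 1L, config@nCells)
  }
  attr(cells, "config") <- config
  cells
}
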