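#' @import methods
NULL

#' CalciumTrace: a uniformly sampled fluorescence time series
#'
#' Container for a single cell's relative fluorescence (\eqn{\Delta F/F})
#' trace. Frame \eqn{k} (0-based) is stamped at
#' \code{startTime + k / samplingRate} (frame-onset convention); all times in
#' the package are absolute seconds on this clock.
#'
#' @slot values numeric vector of \eqn{\Delta F/F} amplitudes, one per frame.
#' @slot samplingRate frames per second (Hz), positive.
#' @slot startTime onset time of the first frame, seconds.
#'
#' @examples
#' tr <- CalciumTrace(sin(seq(0, 2 * pi, length.out = 100)), samplingRate = 10)
#' samplingRate(tr)
#' head(frameTimes(tr))
#' @export
setClass("CalciumTrace",
  representation(values = "numeric", samplingRate = "numeric",
                 startTime = "numeric"),
  prototype(values = numeric(), samplingRate = 1, startTime = 0))

setValidity("CalciumTrace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive finite number")
  if (length(object@values) < 2L)
    msg <- c(msg, "a trace needs at least 2 frames")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all trace values must be finite")
  if (length(object@startTime) != 1L || !is.finite(object@startTime))
    msg <- c(msg, "startTime must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @rdname CalciumTrace-class
#' @param values numeric vector of amplitudes.
#' @param samplingRate sampling rate in Hz.
#' @param startTime time of the first frame (s).
#' @export
CalciumTrace <- function(values, samplingRate, startTime = 0) {
  new("CalciumTrace", values = as.numeric(values),
      samplingRate = as.numeric(samplingRate),
      startTime = as.numeric(startTime))
}

#' SpikeTrain: sorted spike times in seconds
#'
#' @slot times numeric vector of non-decreasing, non-negative spike times (s).
#'
#' @examples
#' st <- SpikeTrain(c(0.2, 1.5, 3.1))
#' spikeTimes(st)
#' @export
setClass("SpikeTrain", representation(times = "numeric"),
         prototype(times = numeric()))

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (length(object@times) && !all(is.finite(object@times)))
    msg <- c(msg, "spike times must be finite")
  if (length(object@times) && any(object@times < 0))
    msg <- c(msg, "spike times must be non-negative")
  if (is.unsorted(object@times))
    msg <- c(msg, "spike times must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname SpikeTrain-class
#' @param times numeric vector of spike times (s), non-decreasing.
#' @export
SpikeTrain <- function(times = numeric()) {
  new("SpikeTrain", times = as.numeric(times))
}

#' CaSpikeModel: the stereotyped single-spike calcium transient
#'
#' Double-exponential kernel
#' \deqn{g(t, T) = (1 - e^{(T-t)/\tau_1}) e^{(T-t)/\tau_2}, \quad t \ge T}
#' and \eqn{g = 0} for \eqn{t < T}, with trace-level amplitude, baseline and
#' Gaussian noise SD. The generative prediction for a spike train is
#' \eqn{b_0 + a \sum_i g(t, T_i)}.
#'
#' @slot tau1 rise time constant (s), \code{0 < tau1 < tau2}.
#' @slot tau2 decay time constant (s).
#' @slot amplitude kernel multiplier \eqn{a} (\eqn{\Delta F/F} units), positive.
#' @slot baseline baseline \eqn{b_0} (\eqn{\Delta F/F} units).
#' @slot noiseSigma Gaussian noise SD (\eqn{\Delta F/F} units), non-negative.
#'
#' @examples
#' m <- CaSpikeModel(tau1 = 0.01, tau2 = 0.5, amplitude = 1)
#' kernelPeakTime(m)  # tau1 * log((tau1 + tau2) / tau1)
#' @export
setClass("CaSpikeModel",
  representation(tau1 = "numeric", tau2 = "numeric", amplitude = "numeric",
                 baseline = "numeric", noiseSigma = "numeric"),
  prototype(tau1 = 0.01, tau2 = 0.5, amplitude = 1, baseline = 0,
            noiseSigma = 0))

setValidity("CaSpikeModel", function(object) {
  msg <- character()
  if (!(object@tau1 > 0 && object@tau2 > object@tau1))
    msg <- c(msg, "need 0 < tau1 < tau2")
  if (!(object@amplitude > 0))
    msg <- c(msg, "amplitude must be positive")
  if (object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname CaSpikeModel-class
#' @param tau1,tau2 rise and decay time constants (s).
#' @param amplitude kernel multiplier \eqn{a}.
#' @param baseline baseline \eqn{b_0}.
#' @param noiseSigma noise standard deviation.
#' @export
CaSpikeModel <- function(tau1, tau2, amplitude = 1, baseline = 0,
                         noiseSigma = 0) {
  new("CaSpikeModel", tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
      amplitude = as.numeric(amplitude), baseline = as.numeric(baseline),
      noiseSigma = as.numeric(noiseSigma))
}

#' DetectionConfig: hyperparameters of the candidate detector
#'
#' @slot scoreThreshold threshold on the standardized coincidence score,
#'   in robust-SD units.
#' @slot segmentPre,segmentPost frames before/after the threshold-crossing
#'   frame kept in a candidate segment.
#' @slot vernierFactor sub-frame refinement factor (vernier grid is
#'   \code{1/vernierFactor} of the frame interval), integer \eqn{\ge 2}.
#' @slot matchWindow spike-matching window (s) used to label candidates and
#'   score detections.
#' @export
setClass("DetectionConfig",
  representation(scoreThreshold = "numeric", segmentPre = "integer",
                 segmentPost = "integer", vernierFactor = "integer",
                 matchWindow = "numeric"),
  prototype(scoreThreshold = 2, segmentPre = 1L, segmentPost = 2L,
            vernierFactor = 10L, matchWindow = 0.05))

setValidity("DetectionConfig", function(object) {
  msg <- character()
  if (object@vernierFactor < 2L)
    msg <- c(msg, "vernierFactor must be >= 2")
  if (object@segmentPre < 0L || object@segmentPost < 0L)
    msg <- c(msg, "segmentPre and segmentPost must be >= 0")
  if (!(object@matchWindow > 0))
    msg <- c(msg, "matchWindow must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname DetectionConfig-class
#' @param scoreThreshold threshold in robust-SD units.
#' @param segmentPre,segmentPost segment extent in frames.
#' @param vernierFactor sub-frame grid refinement factor.
#' @param matchWindow matching window (s).
#' @export
DetectionConfig <- function(scoreThreshold = 2, segmentPre = 1,
                            segmentPost = 2, vernierFactor = 10,
                            matchWindow = 0.05) {
  new("DetectionConfig", scoreThreshold = as.numeric(scoreThreshold),
      segmentPre = as.integer(segmentPre),
      segmentPost = as.integer(segmentPost),
      vernierFactor = as.integer(vernierFactor),
      matchWindow = as.numeric(matchWindow))
}

#' CandidateSet: windowed trace excerpts around score threshold crossings
#'
#' One row per candidate: a fixed-length excerpt of the trace and of the
#' standardized coincidence score centred on the crossing frame, the
#' pseudo-spike time PT (onset time of the crossing frame), and an optional
#' ground-truth label.
#'
#' @slot frames numeric matrix, candidates x segment length, trace values.
#' @slot scores numeric matrix, same shape, coincidence-score values.
#' @slot pt numeric vector of pseudo-spike times (s), on the frame grid.
#' @slot label character vector, one of \code{"spike"}, \code{"non-spike"},
#'   \code{"unknown"}.
#' @export
setClass("CandidateSet",
  representation(frames = "matrix", scores = "matrix", pt = "numeric",
                 label = "character"),
  prototype(frames = matrix(numeric(), 0, 0),
            scores = matrix(numeric(), 0, 0),
            pt = numeric(), label = character()))

setValidity("CandidateSet", function(object) {
  n <- length(object@pt)
  msg <- character()
  if (nrow(object@frames) != n || nrow(object@scores) != n ||
      length(object@label) != n)
    msg <- c(msg, "frames, scores, pt and label must agree in length")
  if (n > 0 && !identical(dim(object@frames), dim(object@scores)))
    msg <- c(msg, "frames and scores must have identical dimensions")
  if (!all(object@label %in% c("spike", "non-spike", "unknown")))
    msg <- c(msg, "labels must be spike / non-spike / unknown")
  if (length(msg)) msg else TRUE
})

#' NonlinearityModel: fitted amplitude transfer curve
#'
#' Relates observed trace amplitude \eqn{y} to the linear model prediction
#' \eqn{x}. Families: \code{"linear"} (\eqn{y = s x}),
#' \code{"saturating-exponential"} and \code{"growing-exponential"}
#' (\eqn{y = c_1 e^{c_2 x} + c_3} with \eqn{c_2 < 0} resp. \eqn{c_2 > 0}).
#'
#' @slot family character, one of the three families.
#' @slot params numeric; \code{slope} for linear, \code{c(c1, c2, c3)}
#'   otherwise.
#' @slot fitRange numeric length-2, x-range the fit is valid on.
#' @export
setClass("NonlinearityModel",
  representation(family = "character", params = "numeric",
                 fitRange = "numeric"),
  prototype(family = "linear", params = c(slope = 1),
            fitRange = c(0, 1)))

setValidity("NonlinearityModel", function(object) {
  msg <- character()
  if (!object@family %in% c("linear", "saturating-exponential",
                            "growing-exponential"))
    msg <- c(msg, "unknown family")
  if (object@family == "linear" && length(object@params) != 1L)
    msg <- c(msg, "linear family takes a single slope parameter")
  if (object@family != "linear" && length(object@params) != 3L)
    msg <- c(msg, "exponential families take (c1, c2, c3)")
  if (length(object@fitRange) != 2L || diff(object@fitRange) < 0)
    msg <- c(msg, "fitRange must be an increasing length-2 vector")
  if (length(msg)) msg else TRUE
})

#' EvalReport: all evaluation metrics for one (truth, estimate) pair
#'
#' @slot hits,misses,falsePositives integer counts from windowed one-to-one
#'   matching.
#' @slot sensitivity,precision,f1 detection scores in [0, 1].
#' @slot spikeDistance normalized Victor-Purpura-style edit distance.
#' @slot invSpikeDistance its inverse, capped.
#' @slot cosmic CosMIC overlap score in [0, 1].
#' @slot hyperacuityIndex sampling interval / mean absolute timing error over
#'   hits.
#' @slot pairedErrors signed timing errors (estimate - truth, s), one per hit.
#' @slot window matching window used (s).
#' @export
setClass("EvalReport",
  representation(hits = "integer", misses = "integer",
                 falsePositives = "integer", sensitivity = "numeric",
                 precision = "numeric", f1 = "numeric",
                 spikeDistance = "numeric", invSpikeDistance = "numeric",
                 cosmic = "numeric", hyperacuityIndex = "numeric",
                 pairedErrors = "numeric", window = "numeric"),
  prototype(hits = 0L, misses = 0L, falsePositives = 0L, sensitivity = 0,
            precision = 0, f1 = 0, spikeDistance = 0, invSpikeDistance = 0,
            cosmic = 0, hyperacuityIndex = NA_real_,
            pairedErrors = numeric(), window = 0.05))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (object@hits < 0L || object@misses < 0L || object@falsePositives < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (object@hits != length(object@pairedErrors))
    msg <- c(msg, "pairedErrors must have one entry per hit")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: the study conditions of the synthetic-data generator
#'
#' Defaults follow the simulated-data regime the package is benchmarked
#' under: Poisson spiking at 1 Hz, rise constant 0.01 s, decay 0.2-1 s,
#' power-law nonlinearity exponent 0.2-3, SNR (single-spike peak over noise
#' SD) in \{3, 5, 10\}, 10 cells with 50 expected spikes each.
#'
#' @slot firingRate mean Poisson firing rate (Hz).
#' @slot nCells number of cells.
#' @slot spikesPerCell expected spikes per cell (cell duration is
#'   \code{spikesPerCell / firingRate} seconds).
#' @slot tau1,tau2 kernel time constants (s).
#' @slot alpha nonlinearity exponent applied above the one-spike level.
#' @slot snr single-spike peak amplitude over noise SD.
#' @slot samplingRate imaging rate (Hz).
#' @slot amplitude,baseline kernel multiplier and baseline of the generative
#'   model.
#' @slot seed master seed; per-cell streams are derived from it.
#' @export
setClass("SimulationConfig",
  representation(firingRate = "numeric", nCells = "integer",
                 spikesPerCell = "numeric", tau1 = "numeric",
                 tau2 = "numeric", alpha = "numeric", snr = "numeric",
                 samplingRate = "numeric", amplitude = "numeric",
                 baseline = "numeric", seed = "integer"),
  prototype(firingRate = 1, nCells = 10L, spikesPerCell = 50, tau1 = 0.01,
            tau2 = 0.5, alpha = 1, snr = 5, samplingRate = 60,
            amplitude = 1, baseline = 0, seed = 1L))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (!(object@firingRate > 0)) msg <- c(msg, "firingRate must be positive")
  if (!(object@snr > 0)) msg <- c(msg, "snr must be positive")
  if (!(object@alpha > 0)) msg <- c(msg, "alpha must be positive")
  if (!(object@tau1 > 0 && object@tau1 < object@tau2))
    msg <- c(msg, "need 0 < tau1 < tau2")
  if (!(object@samplingRate > 0))
    msg <- c(msg, "samplingRate must be positive")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (!(object@spikesPerCell > 0))
    msg <- c(msg, "spikesPerCell must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param firingRate,nCells,spikesPerCell,tau1,tau2,alpha,snr,samplingRate
#'   see slots.
#' @param amplitude,baseline generative amplitude and baseline.
#' @param seed integer master seed.
#' @export
SimulationConfig <- function(firingRate = 1, nCells = 10, spikesPerCell = 50,
                             tau1 = 0.01, tau2 = 0.5, alpha = 1, snr = 5,
                             samplingRate = 60, amplitude = 1, baseline = 0,
                             seed = 1) {
  new("SimulationConfig", firingRate = as.numeric(firingRate),
      nCells = as.integer(nCells), spikesPerCell = as.numeric(spikesPerCell),
      tau1 = as.numeric(tau1), tau2 = as.numeric(tau2),
      alpha = as.numeric(alpha), snr = as.numeric(snr),
      samplingRate = as.numeric(samplingRate),
      amplitude = as.numeric(amplitude), baseline = as.numeric(baseline),
      seed = as.integer(seed))
}

#' SpikeClassifier: trained spike / non-spike discriminator
#'
#' A radial-basis SVM over the concatenated feature vector
#' \code{[segment frames, segment scores]}, standardized by training-set
#' statistics.
#'
#' @slot svm the fitted \pkg{e1071} model.
#' @slot center,scale per-feature standardization statistics.
#' @slot featureLength expected feature-vector length.
#' @export
setClass("SpikeClassifier",
  representation(svm = "ANY", center = "numeric", scale = "numeric",
                 featureLength = "integer"))
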