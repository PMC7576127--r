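#' @rdname CalciumTrace-class
#' @export
setMethod("samplingRate", "CalciumTrace", function(object) object@samplingRate)

#' @rdname CalciumTrace-class
#' @export
setMethod("traceValues", "CalciumTrace", function(object) object@values)

#' @rdname CalciumTrace-class
#' @export
setMethod("startTime", "CalciumTrace", function(object) object@startTime)

#' @rdname CalciumTrace-class
#' @export
setMethod("frameTimes", "CalciumTrace", function(object) {
  object@startTime +
    (seq_along(object@values) - 1L) / object@samplingRate
})

#' @rdname CalciumTrace-class
#' @export
setMethod("length", "CalciumTrace", function(x) length(x@values))

setMethod("show", "CalciumTrace", function(object) {
  cat(sprintf(
    "CalciumTrace: %d frames at %.4g Hz (%.4g s), start %.4g s\n",
    length(object@values), object@samplingRate,
    length(object@values) / object@samplingRate, object@startTime))
  cat(sprintf("  values: median %.4g, range [%.4g, %.4g]\n",
              stats::median(object@values), min(object@values),
              max(object@values)))
})

#' @rdname SpikeTrain-class
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@times)

#' @rdname SpikeTrain-class
#' @param x a \code{SpikeTrain}.
#' @export
setMethod("length", "SpikeTrain", function(x) length(x@times))

setMethod("show", "SpikeTrain", function(object) {
  n <- length(object@times)
  if (n == 0L) {
    cat("SpikeTrain: empty\n")
  } else {
    cat(sprintf("SpikeTrain: %d spikes in [%.4g, %.4g] s\n",
                n, object@times[1], object@times[n]))
  }
})

setMethod("show", "CaSpikeModel", function(object) {
  cat(sprintf(
    paste0("CaSpikeModel: tau1 = %.4g s, tau2 = %.4g s, a = %.4g, ",
           "b0 = %.4g, sigma = %.4g\n"),
    object@tau1, object@tau2, object@amplitude, object@baseline,
    object@noiseSigma))
  cat(sprintf("  single-spike peak %.4g at %.4g s after onset\n",
              singleSpikePeak(object), kernelPeakTime(object)))
})

setMethod("show", "DetectionConfig", function(object) {
  cat(sprintf(
    paste0("DetectionConfig: threshold %.3g robust SD, segment -%d/+%d ",
           "frames, vernier 1/%d, window %.3g s\n"),
    object@scoreThreshold, object@segmentPre, object@segmentPost,
    object@vernierFactor, object@matchWindow))
})

#' @rdname CandidateSet-class
#' @export
setMethod("pseudoTimes", "CandidateSet", function(object) object@pt)

#' @rdname CandidateSet-class
#' @export
setMethod("candidateLabels", "CandidateSet", function(object) object@label)

#' @rdname CandidateSet-class
#' @param x a \code{CandidateSet}.
#' @export
setMethod("length", "CandidateSet", function(x) length(x@pt))

#' Subset a CandidateSet
#'
#' @param x a \code{CandidateSet}.
#' @param i logical or integer index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "CandidateSet", function(x, i, j, ..., drop = FALSE) {
  new("CandidateSet", frames = x@frames[i, , drop = FALSE],
      scores = x@scores[i, , drop = FALSE], pt = x@pt[i],
      label = x@label[i])
})

setMethod("show", "CandidateSet", function(object) {
  cat(sprintf("CandidateSet: %d candidates, segment length %d\n",
              length(object@pt), ncol(object@frames)))
  if (length(object@pt))
    print(table(label = object@label))
})

setMethod("show", "NonlinearityModel", function(object) {
  if (object@family == "linear") {
    cat(sprintf("NonlinearityModel: linear, y = %.4g x\n", object@params[1]))
  } else {
    cat(sprintf("NonlinearityModel: %s, y = %.4g exp(%.4g x) + %.4g\n",
                object@family, object@params[1], object@params[2],
                object@params[3]))
  }
  cat(sprintf("  fit range x in [%.4g, %.4g]\n", object@fitRange[1],
              object@fitRange[2]))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (window %.3g s)\n", object@window))
  cat(sprintf("  hits %d, misses %d, false positives %d\n", object@hits,
              object@misses, object@falsePositives))
  cat(sprintf("  sensitivity %.3f, precision %.3f, F1 %.3f\n",
              object@sensitivity, object@precision, object@f1))
  cat(sprintf("  spike distance %.3f (inverse %.3f), CosMIC %.3f\n",
              object@spikeDistance, object@invSpikeDistance, object@cosmic))
  cat(sprintf("  hyperacuity index %.3f\n", object@hyperacuityIndex))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %d cells x %.4g expected spikes at %.4g Hz ",
           "firing\n  tau = (%.4g, %.4g) s, alpha = %.4g, SNR = %.4g, ",
           "sampling %.4g Hz, seed %d\n"),
    object@nCells, object@spikesPerCell, object@firingRate, object@tau1,
    object@tau2, object@alpha, object@snr, object@samplingRate,
    object@seed))
})

setMethod("show", "SpikeClassifier", function(object) {
  cat(sprintf("SpikeClassifier: radial-basis SVM on %d features\n",
              object@featureLength))
})

#' Convert an EvalReport to a one-row data.frame
#'
#' @param x an \code{EvalReport}.
#' @param ... ignored.
#' @return a one-row \code{data.frame} of scalar metrics.
#' @export
as.data.frame.EvalReport <- function(x, ...) {
  data.frame(hits = x@hits, misses = x@misses,
             falsePositives = x@falsePositives,
             sensitivity = x@sensitivity, precision = x@precision,
             f1 = x@f1, spikeDistance = x@spikeDistance,
             invSpikeDistance = x@invSpikeDistance, cosmic = x@cosmic,
             hyperacuityIndex = x@hyperacuityIndex, window = x@window)
}
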