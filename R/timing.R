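# Hyperacuity refinement: estimate the sampling jitter SJ of each detected
# spike on a vernier grid 10x finer than the frame interval, by minimizing
# the residual between the local trace and the model prediction; the true
# spike time is TT = PT + SJ.

#' Estimate the sampling jitter of one detected spike
#'
#' The modelled transients of \code{priorSpikes} are first subtracted from
#' the local trace (overlap correction for preceding spikes). SJ is then
#' the offset on the vernier grid
#' \eqn{\{-\Delta + \Delta/v, \ldots, 0, \ldots, \Delta - \Delta/v\}}
#' (frame interval \eqn{\Delta}, factor \eqn{v}) minimizing the sum of
#' squared residuals between the trace and
#' \eqn{b_0 + a\, g(\cdot, PT + SJ)} over a residual window of
#' \code{windowPre} frames before PT to \code{windowPost} seconds after.
#' Ties break toward the smallest \eqn{|SJ|}.
#'
#' @param trace a \code{CalciumTrace} (compensated, if applicable).
#' @param model a fitted \code{CaSpikeModel}.
#' @param pt pseudo-spike time (s), on the frame grid.
#' @param priorSpikes a \code{SpikeTrain} of already-accepted spike times.
#' @param vernierFactor sub-frame grid factor (default 10).
#' @param windowPre frames before PT in the residual window.
#' @param windowPost extent of the residual window after PT (s); covers the
#'   rise and early decay while staying short against typical inter-spike
#'   intervals.
#' @param spanFrames half-width of the SJ search in frames (default 1,
#'   i.e. a full frame either side of PT; wider spans admit noise-driven
#'   spurious minima faster than they recover mis-placed crossings).
#' @return the estimated SJ (s), with attribute \code{"residuals"} (the
#'   residual SS per vernier offset).
#' @export
estimateJitter <- function(trace, model, pt, priorSpikes = SpikeTrain(),
                           vernierFactor = 10, windowPre = 1,
                           windowPost = 0.25, spanFrames = 1) {
  dt <- 1 / samplingRate(trace)
  tt <- frameTimes(trace)
  i0 <- floor((pt - (windowPre + spanFrames - 1) * dt - tt[1]) / dt + 0.5) +
    1L
  i1 <- floor((pt + windowPost - tt[1]) / dt + 0.5) + 1L
  i0 <- max(1L, i0); i1 <- min(length(tt), i1)
  if (i1 < i0) stop("residual window falls outside the trace")
  idx <- i0:i1
  ysub <- traceValues(trace)[idx] - model@amplitude *
    .superposeAny(tt[idx], spikeTimes(priorSpikes), model@tau1, model@tau2)
  v <- as.integer(vernierFactor)
  off <- seq(-spanFrames * dt + dt / v, spanFrames * dt - dt / v,
             by = dt / v)
  rel <- outer(tt[idx] - pt, off, "-")
  g <- matrix(0, nrow(rel), ncol(rel))
  posm <- rel > 0
  g[posm] <- (1 - exp(-rel[posm] / model@tau1)) * exp(-rel[posm] / model@tau2)
  ss <- colSums((ysub - model@baseline - model@amplitude * g)^2)
  best <- which(ss <= min(ss) * (1 + 1e-12))
  sj <- off[best[which.min(abs(off[best]))]]
  attr(sj, "residuals") <- ss
  sj
}

#' Refine detected spike times to hyperacuity resolution
#'
#' Processes accepted candidates in time order; each refined spike is added
#' to the prior-spike set so its modelled transient is subtracted before
#' the next jitter estimate. Returns the sorted train of true spike times
#' TT = PT + SJ. With \code{vernierFactor = 1} every SJ is forced to zero,
#' giving the frame-grid (no-hyperacuity) baseline.
#'
#' @param trace a \code{CalciumTrace}.
#' @param model a fitted \code{CaSpikeModel}.
#' @param candidates a \code{CandidateSet} of accepted detections, or a
#'   numeric vector of pseudo-spike times.
#' @param config a \code{DetectionConfig} (supplies the vernier factor).
#' @param windowPre,windowPost residual-window extent, see
#'   \code{\link{estimateJitter}}.
#' @param refine when \code{FALSE}, skip the vernier search and return the
#'   frame-grid pseudo-spike times (the grid-quantized baseline).
#' @param spanFrames SJ search half-width in frames, see
#'   \code{\link{estimateJitter}}.
#' @return a \code{\linkS4class{SpikeTrain}} of refined times; refined
#'   times closer than one vernier step collapse to a single spike.
#' @export
refineSpikeTimes <- function(trace, model, candidates,
                             config = DetectionConfig(), windowPre = 1,
                             windowPost = 0.25, refine = TRUE,
                             spanFrames = 1) {
  pts <- if (is(candidates, "CandidateSet")) pseudoTimes(candidates)
         else as.numeric(candidates)
  pts <- sort(pts)
  if (!length(pts)) return(SpikeTrain(numeric()))
  v <- config@vernierFactor
  tts <- numeric(0)
  keptPt <- numeric(0)
  for (pt in pts) {
    sj <- if (!refine) 0 else
      estimateJitter(trace, model, pt, SpikeTrain(sort(pmax(tts, 0))),
                     vernierFactor = v, windowPre = windowPre,
                     windowPost = windowPost, spanFrames = spanFrames)
    tt_ <- pt + as.numeric(sj)
    # two crossings refined onto the same onset describe one spike
    if (!length(tts) || min(abs(tts - tt_)) >= (1 / samplingRate(trace)) / v) {
      tts <- c(tts, tt_)
      keptPt <- c(keptPt, pt)
    }
  }
  ord <- order(pmax(tts, 0))
  out <- SpikeTrain(pmax(tts, 0)[ord])
  attr(out, "pt") <- keptPt[ord]   # source pseudo-spike time per spike
  out
}
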