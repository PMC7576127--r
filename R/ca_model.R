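# The generative calcium response model: double-exponential kernel,
# linear prediction for spike trains, and estimation of (a, b0, sigma) by
# EM-style alternating closed-form updates with per-spike sub-frame onsets
# as latent variables, plus an alternating coordinate grid search over the
# kernel time constants.

#' Double-exponential calcium spike kernel
#'
#' \eqn{g(t, T) = (1 - e^{(T-t)/\tau_1}) e^{(T-t)/\tau_2}} for
#' \eqn{t \ge T}, 0 for \eqn{t < T}; continuous at \eqn{t = T}. The peak
#' lies at \eqn{t - T = \tau_1 \log((\tau_1+\tau_2)/\tau_1)}.
#'
#' @param t evaluation time(s), s.
#' @param T spike onset, s.
#' @param tau1,tau2 rise and decay time constants, \code{0 < tau1 < tau2}.
#' @return kernel amplitude(s), dimensionless.
#' @examples
#' kernelValue(0.11, 0, 0.05, 0.4)
#' @export
kernelValue <- function(t, T, tau1, tau2) {
  if (!(tau1 > 0 && tau2 > tau1)) stop("need 0 < tau1 < tau2")
  s <- t - T
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- (1 - exp(-s[pos] / tau1)) * exp(-s[pos] / tau2)
  out
}

#' @rdname CaSpikeModel-class
#' @param model a \code{CaSpikeModel}.
#' @export
kernelPeakTime <- function(model) {
  model@tau1 * log((model@tau1 + model@tau2) / model@tau1)
}

#' @rdname CaSpikeModel-class
#' @export
singleSpikePeak <- function(model) {
  s <- kernelPeakTime(model)
  model@amplitude * (1 - exp(-s / model@tau1)) * exp(-s / model@tau2)
}

#' Linear model prediction for a spike train
#'
#' \eqn{b_0 + a \sum_i g(t, T_i)} at each requested time; transients
#' superpose additively.
#'
#' @param spikes a \code{SpikeTrain}.
#' @param model a \code{CaSpikeModel}.
#' @param frameTimes numeric vector of evaluation times (s).
#' @return numeric vector of predicted amplitudes.
#' @export
linearPrediction <- function(spikes, model, frameTimes) {
  model@baseline + model@amplitude *
    .superposeAny(frameTimes, spikeTimes(spikes), model@tau1, model@tau2)
}

.superposeAny <- function(tt, st, tau1, tau2) {
  uniform <- length(tt) > 1L && {
    d <- diff(tt); all(abs(d - d[1]) < 1e-9 * max(d[1], 1e-12))
  }
  if (uniform) return(.superpose(tt, st, tau1, tau2))
  out <- numeric(length(tt))
  support <- -tau2 * log(1e-8)
  for (T in st) {
    idx <- which(tt > T & tt <= T + support)
    if (length(idx))
      out[idx] <- out[idx] + kernelValue(tt[idx], T, tau1, tau2)
  }
  out
}

# ---- spike-model fitting ---------------------------------------------------

# Keep spikes whose neighbours are >= burstISI away (bursts distort the
# constant-shape assumption); fall back to all spikes when fewer than
# minIsolated survive.
.isolatedMask <- function(times, burstISI = 2) {
  if (length(times) <= 1L) return(rep(TRUE, length(times)))
  prev <- c(Inf, diff(times))
  nxt <- c(diff(times), Inf)
  prev >= burstISI & nxt >= burstISI
}

# Build fitting segments: per kept spike, frames in [T - 2*dt, T + segLen],
# plus the nominal-time background spikes that overlap the window.
.buildSegments <- function(traces, spikeLists, segLen = 2, burstISI = 2,
                           minIsolated = 10) {
  segs <- list()
  nIso <- 0L
  allSegs <- list()
  for (ci in seq_along(traces)) {
    tr <- traces[[ci]]
    st <- spikeTimes(spikeLists[[ci]])
    if (!length(st)) next
    iso <- .isolatedMask(st, burstISI)
    tt <- frameTimes(tr)
    yy <- traceValues(tr)
    dt <- 1 / samplingRate(tr)
    for (si in seq_along(st)) {
      T <- st[si]
      i0 <- max(1L, floor((T - 2 * dt - tt[1]) / dt) + 1L)
      i1 <- min(length(tt), floor((T + segLen - tt[1]) / dt) + 1L)
      if (i1 - i0 < 3L) next
      idx <- i0:i1
      bg <- st[-si]
      bg <- bg[bg > tt[i0] - 20 & bg < tt[i1]]  # possible overlap window
      seg <- list(t = tt[idx], y = yy[idx], T = T, dt = dt, bg = bg,
                  isolated = iso[si])
      allSegs[[length(allSegs) + 1L]] <- seg
    }
  }
  isoFlags <- vapply(allSegs, `[[`, logical(1), "isolated")
  if (sum(isoFlags) >= minIsolated) {
    allSegs[isoFlags]
  } else {
    if (length(allSegs) && sum(isoFlags) < length(allSegs))
      warning("fewer than ", minIsolated,
              " isolated spikes; fitting on all spikes")
    allSegs
  }
}

# Inner fit at fixed (tau1, tau2): alternate closed-form (a, b0) updates
# with per-segment vernier jitter selection. The residual sum of squares is
# non-increasing at every step, so the Gaussian log-likelihood ascends.
.innerFit <- function(segs, tau1, tau2, vernier = 10L, maxIter = 200L,
                      tol = 1e-8) {
  K <- 2L * vernier - 1L
  offGrid <- function(dt) seq(-dt + dt / vernier, dt - dt / vernier,
                              length.out = K)
  # per-segment design matrices: unit-kernel value for each jitter offset,
  # plus the (unjittered) background superposition
  G <- vector("list", length(segs))
  absOff <- vector("list", length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    off <- offGrid(s$dt)
    rel <- outer(s$t - s$T, off, "-")    # frames x offsets
    g <- matrix(0, nrow(rel), ncol(rel))
    pos <- rel > 0
    g[pos] <- (1 - exp(-rel[pos] / tau1)) * exp(-rel[pos] / tau2)
    if (length(s$bg))
      g <- g + .superposeAny(s$t, s$bg, tau1, tau2)
    G[[i]] <- g
    absOff[[i]] <- abs(off)
  }
  y <- lapply(segs, `[[`, "y")
  N <- sum(lengths(y))
  jit <- rep(vernier, length(segs))       # centre offset = 0
  ll <- -Inf
  llHist <- numeric()
  a <- NA_real_
  b0 <- NA_real_
  for (iter in seq_len(maxIter)) {
    gs <- unlist(lapply(seq_along(segs),
                        function(i) G[[i]][, jit[i]]), use.names = FALSE)
    ys <- unlist(y, use.names = FALSE)
    vg <- stats::var(gs)
    if (!is.finite(vg) || vg <= 0) return(NULL)
    a <- stats::cov(gs, ys) / vg
    b0 <- mean(ys) - a * mean(gs)
    # jitter update: per segment, offset minimizing the residual SS,
    # ties broken toward the smallest |offset|
    ss <- 0
    for (i in seq_along(segs)) {
      res2 <- colSums((y[[i]] - b0 - a * G[[i]])^2)
      best <- which(res2 <= min(res2) + 1e-15)
      jit[i] <- best[which.min(absOff[[i]][best])]
      ss <- ss + res2[jit[i]]
    }
    sigma2 <- ss / N
    newLL <- -N / 2 * (log(2 * pi * max(sigma2, 1e-300)) + 1)
    llHist <- c(llHist, newLL)
    if (is.finite(ll) && newLL - ll < tol * N) { ll <- newLL; break }
    ll <- newLL
  }
  list(a = a, b0 = b0, sigma = sqrt(ss / N), ll = ll, llHist = llHist,
       jitters = vapply(seq_along(segs),
                        function(i) offGrid(segs[[i]]$dt)[jit[i]],
                        numeric(1)))
}

#' Fit the calcium spike model from traces with known spike times
#'
#' Estimates \eqn{(\tau_1, \tau_2, a, b_0, \sigma)} by maximum likelihood
#' under the Gaussian generative model. Inner loop: closed-form
#' weighted-least-squares updates of \eqn{(a, b_0)} given the time
#' constants and per-spike sub-frame onsets, which are treated as latent
#' and optimized on the vernier grid; \eqn{\sigma} from the residual SD.
#' Outer loop: alternating one-dimensional grid searches over \eqn{\tau_1}
#' (20 log-spaced points in [0.005, 0.2] s) and \eqn{\tau_2} (25 log-spaced
#' points in [0.1, 2] s) until the best cell is stable, then one refinement
#' pass on a 5x finer local grid. Spikes with a neighbour closer than 2 s
#' (bursts) are excluded when at least 10 isolated spikes remain; fitting
#' segments are 2 s post-spike windows.
#'
#' @param traces a \code{CalciumTrace} or list of them, one per cell.
#' @param spikes a \code{SpikeTrain} or list of them, aligned with
#'   \code{traces}.
#' @param vernierFactor sub-frame grid factor for the latent onsets.
#' @param segmentLength post-spike window (s) used for fitting.
#' @param maxOuter maximum alternating coordinate-search rounds.
#' @return a \code{\linkS4class{CaSpikeModel}} with attributes
#'   \code{logLik} (final log-likelihood), \code{llHistory} (inner-loop
#'   log-likelihood trajectory at the selected time constants) and
#'   \code{nSegments}.
#' @export
fitSpikeModel <- function(traces, spikes, vernierFactor = 10,
                          segmentLength = 2, maxOuter = 20) {
  if (is(traces, "CalciumTrace")) traces <- list(traces)
  if (is(spikes, "SpikeTrain")) spikes <- list(spikes)
  stopifnot(length(traces) == length(spikes))
  segs <- .buildSegments(traces, spikes, segLen = segmentLength)
  if (!length(segs)) stop("no usable spikes to fit the spike model")
  tau1Grid <- exp(seq(log(0.005), log(0.2), length.out = 20))
  tau2Grid <- exp(seq(log(0.1), log(2.0), length.out = 25))
  fitAt <- function(t1, t2) {
    if (t1 >= t2) return(NULL)
    .innerFit(segs, t1, t2, vernier = as.integer(vernierFactor))
  }
  sweep1 <- function(grid, fixed, over = c("tau1", "tau2")) {
    over <- match.arg(over)
    fits <- lapply(grid, function(v)
      if (over == "tau1") fitAt(v, fixed) else fitAt(fixed, v))
    lls <- vapply(fits, function(f)
      if (is.null(f) || !is.finite(f$ll) || f$a <= 0) -Inf else f$ll,
      numeric(1))
    list(i = which.max(lls), fit = fits[[which.max(lls)]], ll = max(lls))
  }
  i1 <- which.min(abs(tau1Grid - 0.02))
  i2 <- which.min(abs(tau2Grid - 0.5))
  best <- NULL
  for (round in seq_len(maxOuter)) {
    s1 <- sweep1(tau1Grid, tau2Grid[i2], "tau1")
    s2 <- sweep1(tau2Grid, tau1Grid[s1$i], "tau2")
    stable <- s1$i == i1 && s2$i == i2
    i1 <- s1$i; i2 <- s2$i; best <- s2$fit
    if (stable) break
  }
  if (is.null(best) || !is.finite(best$ll))
    stop("spike-model fit failed: no transient consistent with the data")
  # one refinement pass on 5x finer local log-grids
  fine <- function(grid, i) {
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    exp(seq(log(lo), log(hi), length.out = 11))
  }
  t1 <- tau1Grid[i1]; t2 <- tau2Grid[i2]
  f1 <- fine(tau1Grid, i1)
  s1 <- sweep1(f1, t2, "tau1")
  t1 <- f1[s1$i]
  f2 <- fine(tau2Grid, i2)
  s2 <- sweep1(f2, t1, "tau2")
  t2 <- f2[s2$i]
  best <- s2$fit
  if (is.null(best) || !is.finite(best$a) || best$a <= 0 ||
      singleSpikePeak(CaSpikeModel(t1, t2, max(best$a, 1e-12))) <
        1e-6 * max(stats::sd(unlist(lapply(segs, `[[`, "y"))), 1e-12))
    stop(sprintf(
      paste0("spike-model fit degenerate (a = %.4g): no transient of ",
             "positive amplitude found"), best$a))
  out <- CaSpikeModel(t1, t2, best$a, best$b0, best$sigma)
  attr(out, "logLik") <- best$ll
  attr(out, "llHistory") <- best$llHist
  attr(out, "nSegments") <- length(segs)
  out
}
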