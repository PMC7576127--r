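# Ground-truth-free operation: penalized greedy maximum-likelihood spike
# insertion at vernier resolution ("hyperacuity Bayes" stage), then a
# classifier bootstrapped from self-simulated data.

# kernel sampled at whole frames minus a sub-frame phase: g(j*dt - phase),
# j = 1..m (frame 0 relative to the onset frame contributes 0)
.phaseKernels <- function(tau1, tau2, dt, vernier) {
  m <- max(3L, ceiling(5 * tau2 / dt))
  phases <- (seq_len(vernier) - 1L) * dt / vernier
  ker <- lapply(phases, function(ph) {
    s <- (1:m) * dt - ph
    k <- numeric(m)
    pos <- s > 0
    k[pos] <- (1 - exp(-s[pos] / tau1)) * exp(-s[pos] / tau2)
    k
  })
  list(kernels = ker, phases = phases, m = m)
}

# correlation of the residual with each phase kernel: C[k, p] =
# sum_j r[k + j] * ker_p[j] (k = onset frame, 1-based)
.gainCorr <- function(r, ker) {
  m <- length(ker)
  n <- length(r)
  rr <- stats::filter(r, rev(ker), method = "convolution", sides = 1)
  out <- rep(-Inf, n)
  k <- seq_len(n - m)
  out[k] <- rr[k + m]
  out
}

#' Model and spike estimation without ground truth
#'
#' Greedy likelihood ascent: starting from trace statistics (baseline from
#' the median, noise from the differenced trace, amplitude from the upper
#' amplitude quantile) and the log-midpoint of the time-constant grids,
#' repeatedly propose the vernier-resolved spike onset giving the largest
#' gain in Gaussian log-likelihood of the residual, accept while the gain
#' exceeds a BIC-style penalty (\code{penalty} x 0.5 log N per spike
#' time), and periodically re-fit \eqn{(a, b_0, \sigma, \tau)} and
#' re-polish accepted onsets given the accepted spikes. The firing rate is
#' the accepted count over the trace duration.
#'
#' @param trace a \code{CalciumTrace} (10 s or more recommended).
#' @param vernierFactor sub-frame proposal grid factor.
#' @param penalty multiplier on the 0.5 log N acceptance penalty.
#' @param refitEvery re-fit cadence (accepted spikes between re-fits).
#' @return list with \code{model} (a \code{CaSpikeModel}), \code{spikes}
#'   (a \code{SpikeTrain}; empty with a warning when nothing is accepted),
#'   \code{firingRate} (Hz) and \code{llHistory} (log-likelihood after
#'   each acceptance, strictly increasing).
#' @export
bayesDetect <- function(trace, vernierFactor = 10, penalty = 1,
                        refitEvery = 25) {
  y <- traceValues(trace)
  tt <- frameTimes(trace)
  n <- length(y)
  dt <- 1 / samplingRate(trace)
  duration <- n * dt
  v <- as.integer(vernierFactor)
  tau1 <- exp(mean(log(c(0.005, 0.2))))
  tau2 <- exp(mean(log(c(0.1, 2))))
  b0 <- stats::median(y)
  # differencing suppresses the slow transients, so this estimates the
  # imaging noise itself and is robust to not-yet-detected spikes; the
  # acceptance penalty is scaled by it throughout
  sigmaNoise <- stats::mad(diff(y)) / sqrt(2)
  if (sigmaNoise == 0)
    sigmaNoise <- max(stats::sd(diff(y)) / sqrt(2), 1e-9)
  sigma <- sigmaNoise
  gpk <- function(t1, t2) {
    s <- t1 * log((t1 + t2) / t1)
    (1 - exp(-s / t1)) * exp(-s / t2)
  }
  a <- max(stats::quantile(y, 0.995) - b0, 3 * sigma) / gpk(tau1, tau2)
  pen <- penalty * 0.5 * log(n)
  spikes <- numeric(0)
  llHist <- numeric(0)
  predict_ <- function(t1, t2) .superposeAny(tt, sort(spikes), t1, t2)
  refit <- function(tau1, tau2) {
    # re-estimate (a, b0, sigma, tau) with the same latent-onset updates
    # the supervised fitter uses: for every candidate tau the per-spike
    # onsets are re-optimized on the vernier grid, so the time constants
    # cannot trade off against a frozen onset error
    sp <- sort(spikes)
    segs <- suppressWarnings(
      .buildSegments(list(CalciumTrace(y, 1 / dt, tt[1])), list(SpikeTrain(sp)),
                     segLen = 2, minIsolated = Inf))  # keep every spike
    if (!length(segs)) return(NULL)
    fitAt <- function(t1, t2) {
      if (t1 >= t2) return(NULL)
      .innerFit(segs, t1, t2, vernier = v, maxIter = 50L)
    }
    sweep1 <- function(grid, fixed, over) {
      fits <- lapply(grid, function(x)
        if (over == "tau1") fitAt(x, fixed) else fitAt(fixed, x))
      lls <- vapply(fits, function(f)
        if (is.null(f) || !is.finite(f$ll) || f$a <= 0) -Inf else f$ll,
        numeric(1))
      list(v = grid[which.max(lls)], fit = fits[[which.max(lls)]])
    }
    t1g <- exp(seq(log(0.005), log(0.2), length.out = 10))
    t2g <- exp(seq(log(0.1), log(2.0), length.out = 12))
    s2 <- sweep1(t2g, tau1, "tau2")
    if (is.null(s2$fit)) return(NULL)
    s1 <- sweep1(t1g, s2$v, "tau1")
    if (is.null(s1$fit)) return(NULL)
    fine <- function(grid, x) {
      i <- which.min(abs(grid - x))
      exp(seq(log(grid[max(1L, i - 1L)]),
              log(grid[min(length(grid), i + 1L)]), length.out = 9))
    }
    s2 <- sweep1(fine(t2g, s2$v), s1$v, "tau2")
    if (is.null(s2$fit)) return(NULL)
    s1 <- sweep1(fine(t1g, s1$v), s2$v, "tau1")
    if (is.null(s1$fit)) return(NULL)
    best <- s1$fit
    t1 <- s1$v; t2 <- s2$v
    # apply the fitted onset jitters to the spikes that own a segment
    segT <- vapply(segs, `[[`, numeric(1), "T")
    idx <- match(segT, sp)
    sp[idx] <- pmax(sp[idx] + best$jitters, 0)
    spikes <<- sp
    g <- .superposeAny(tt, sort(spikes), t1, t2)
    vg <- stats::var(g)
    if (!is.finite(vg) || vg <= 0) return(NULL)
    aa <- stats::cov(g, y) / vg
    bb <- mean(y) - aa * mean(g)
    list(t1 = t1, t2 = t2, a = max(aa, 1e-12), b0 = bb,
         ss = sum((y - bb - aa * g)^2))
  }
  # amplitude/baseline-only refit between acceptance batches; the time
  # constants stay frozen while detection is incomplete, because missed
  # spikes masquerade as slow decay and a lengthened kernel then blocks
  # every remaining true spike (negative insertion gain)
  refitAmp <- function() {
    g <- predict_(tau1, tau2)
    vg <- stats::var(g)
    if (!is.finite(vg) || vg <= 0) return(invisible())
    aa <- stats::cov(g, y) / vg
    if (aa > 0) {
      a <<- aa
      b0 <<- mean(y) - aa * mean(g)
      sigma <<- sqrt(sum((y - b0 - a * g)^2) / n)
    }
    invisible()
  }
  proposalSweep <- function() {
    # accept spikes at the current parameters; amplitude refit after an
    # early first batch (the initial guess is crude), then periodically
    batchSizes <- c(3L, 10L, rep(refitEvery, 1000L))
    batch <- 1L
    total <- 0L
    repeat {
      pk <- .phaseKernels(tau1, tau2, dt, v)
      r <- y - b0 - a * predict_(tau1, tau2)
      E <- vapply(pk$kernels, function(k) sum(k^2), numeric(1))
      C <- vapply(pk$kernels, function(k) .gainCorr(r, k), numeric(n))
      ssNow <- sum(r^2)
      accepted <- 0L
      repeat {
        gains <- 2 * a * C - rep(a^2 * E, each = n)
        bi <- arrayInd(which.max(gains), dim(gains))
        k <- bi[1]; p <- bi[2]
        gain <- gains[k, p]
        dll <- gain / (2 * sigmaNoise^2)
        if (!is.finite(dll) || dll <= pen) break
        T <- tt[k] + pk$phases[p]
        if (length(spikes) && min(abs(spikes - T)) < dt / v / 2) {
          C[k, p] <- -Inf     # duplicate position; mask and continue
          next
        }
        spikes <<- c(spikes, T)
        # update the residual and the correlations locally
        ker <- pk$kernels[[p]]
        idx <- (k + 1L):min(n, k + pk$m)
        r[idx] <- r[idx] - a * ker[seq_along(idx)]
        for (pp in seq_len(v)) {
          klo <- max(1L, k - pk$m)
          khi <- min(n, k + pk$m)
          seg <- klo:khi
          C[seg, pp] <- .gainCorr(r[max(1L, klo - 1L):min(n, khi + pk$m)],
                                  pk$kernels[[pp]])[
            seg - max(1L, klo - 1L) + 1L]
        }
        ssNow <- ssNow - gain
        llHist <<- c(llHist, -n / 2 * (log(2 * pi * ssNow / n) + 1))
        accepted <- accepted + 1L
        if (accepted >= batchSizes[batch] ||
            length(spikes) > 20 * duration) break
      }
      total <- total + accepted
      if (accepted == 0L || length(spikes) > 20 * duration) break
      batch <- batch + 1L
      refitAmp()
    }
    total
  }
  proposalSweep()
  if (!length(spikes)) {
    warning("no spikes accepted; returning an empty spike train")
    model <- CaSpikeModel(tau1, tau2, max(a, 1e-12), b0, sigma)
    return(list(model = model, spikes = SpikeTrain(numeric()),
                firingRate = 0, llHistory = llHist))
  }
  # alternate full (a, b0, sigma, tau) refits with further proposal
  # sweeps until no spike is added and the estimates are stable
  for (round in 1:4) {
    prev <- sort(spikes)
    rf <- refit(tau1, tau2)
    if (is.null(rf)) break
    tau1 <- rf$t1; tau2 <- rf$t2; a <- rf$a; b0 <- rf$b0
    sigma <- sqrt(rf$ss / n)
    added <- proposalSweep()
    if (added == 0L &&
        isTRUE(all.equal(prev, sort(spikes), tolerance = 1e-12))) break
  }
  list(model = CaSpikeModel(tau1, tau2, a, b0, sigma),
       spikes = SpikeTrain(sort(pmax(spikes, 0))),
       firingRate = length(spikes) / duration,
       llHistory = llHist)
}

#' Fully unsupervised spike inference for one trace
#'
#' Runs \code{\link{bayesDetect}} to estimate the response model, firing
#' rate and candidate spikes; simulates labelled training data at the
#' estimated parameters; optimizes the detector and trains the classifier
#' on the simulation; then extracts, classifies and vernier-refines spikes
#' on the real trace. Ground truth is never accepted as an input.
#'
#' @param trace a \code{CalciumTrace}.
#' @param seed master seed for the self-simulation.
#' @param nCells number of self-simulated training cells.
#' @param spikesPerCell expected spikes per self-simulated cell.
#' @param nl optional \code{NonlinearityModel} to compensate the trace
#'   before detection.
#' @return a \code{SpikeTrain} of estimated spike times, with attributes
#'   \code{"model"}, \code{"config"} (the detection configuration) and
#'   \code{"firingRate"}.
#' @export
unsupervisedPipeline <- function(trace, seed = 1, nCells = 10,
                                 spikesPerCell = 50, nl = NULL) {
  if (!is.null(nl)) trace <- compensateTrace(trace, nl)
  bd <- bayesDetect(trace)
  if (!length(bd$spikes)) return(.emptyEstimate(bd))
  model <- bd$model
  rate <- min(max(bd$firingRate, 0.2), 10)
  snr <- min(max(singleSpikePeak(model) / max(model@noiseSigma, 1e-9), 1),
             20)
  simCfg <- SimulationConfig(
    firingRate = rate, nCells = nCells, spikesPerCell = spikesPerCell,
    tau1 = model@tau1, tau2 = model@tau2, alpha = 1, snr = snr,
    samplingRate = samplingRate(trace), amplitude = model@amplitude,
    baseline = model@baseline, seed = .deriveSeed(seed, 77L))
  sim <- generateDataset(simCfg)
  cfg <- optimizeDetection(sim, model)
  labelled <- lapply(sim, function(cell) {
    sc <- coincidenceScore(cell$trace, model)
    labelCandidates(extractCandidates(cell$trace, sc, cfg), cell$spikes,
                    cfg@matchWindow)
  })
  pool <- .bindCandidates(labelled)
  if (length(unique(candidateLabels(pool))) < 2L)
    return(.emptyEstimate(bd, cfg))
  clf <- trainClassifier(pool)
  sc <- coincidenceScore(trace, model)
  cands <- extractCandidates(trace, sc, cfg)
  if (!length(cands)) return(.emptyEstimate(bd, cfg))
  lab <- classifyCandidates(clf, cands)
  accepted <- cands[lab == "spike"]
  out <- refineSpikeTimes(trace, model, accepted, cfg)
  attr(out, "model") <- model
  attr(out, "config") <- cfg
  attr(out, "firingRate") <- bd$firingRate
  out
}

.emptyEstimate <- function(bd, cfg = NULL) {
  out <- SpikeTrain(numeric())
  attr(out, "model") <- bd$model
  attr(out, "config") <- cfg
  attr(out, "firingRate") <- bd$firingRate
  out
}

# row-bind a list of CandidateSets (equal segment lengths)
.bindCandidates <- function(sets) {
  sets <- sets[vapply(sets, length, integer(1)) > 0]
  if (!length(sets))
    return(new("CandidateSet"))
  new("CandidateSet",
      frames = do.call(rbind, lapply(sets, function(s) s@frames)),
      scores = do.call(rbind, lapply(sets, function(s) s@scores)),
      pt = unlist(lapply(sets, function(s) s@pt), use.names = FALSE),
      label = unlist(lapply(sets, function(s) s@label), use.names = FALSE))
}
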