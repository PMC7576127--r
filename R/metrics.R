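# Evaluation metrics: windowed one-to-one spike matching, ROC/F1,
# Victor-Purpura-style weighted spike distance, CosMIC, the hyperacuity
# index, and the leave-one-out cross-validation harness.

#' Matching window rule
#'
#' Half the sampling interval, relaxed to 50 ms for high sampling rates
#' (30 Hz and above).
#'
#' @param samplingRate imaging rate (Hz).
#' @return window (s).
#' @export
matchWindowRule <- function(samplingRate) {
  if (samplingRate >= 30) 0.05 else 0.5 / samplingRate
}

#' One-to-one windowed spike matching
#'
#' Optimal one-to-one matching: among all pairings that use each spike at
#' most once and only pair (truth, estimate) with
#' \eqn{|\Delta t| <} \code{window}, the one maximizing the number of
#' matched pairs and, among those, minimizing the total \eqn{|\Delta t|}
#' (computed by a non-crossing dynamic program over the sorted trains;
#' remaining ties resolve toward the earlier truth). Hits are matched
#' pairs; misses unmatched truths; false positives unmatched estimates.
#'
#' @param truth,estimate \code{SpikeTrain}s.
#' @param window matching window (s), positive.
#' @return list with \code{hits}, \code{misses}, \code{falsePositives},
#'   \code{pairedErrors} (signed, estimate - truth, per hit),
#'   \code{matchedTruth} and \code{matchedEstimates} (times).
#' @export
matchSpikes <- function(truth, estimate, window) {
  stopifnot(window > 0)
  tt <- spikeTimes(truth); et <- spikeTimes(estimate)
  nT <- length(tt); nE <- length(et)
  if (nT == 0L || nE == 0L)
    return(list(hits = 0L, misses = nT, falsePositives = nE,
                pairedErrors = numeric(), matchedTruth = numeric(),
                matchedEstimates = numeric()))
  # suffix DP; an optimal matching of sorted trains can be taken
  # non-crossing (uncrossing never lowers hits nor raises cost)
  H <- matrix(0L, nT + 1L, nE + 1L)
  Cst <- matrix(0, nT + 1L, nE + 1L)
  for (i in nT:1) for (j in nE:1) {
    d <- abs(tt[i] - et[j])
    # preference order under ties: match, skip truth, skip estimate
    bh <- -1L; bc <- Inf
    if (d < window) { bh <- H[i + 1L, j + 1L] + 1L
                      bc <- Cst[i + 1L, j + 1L] + d }
    if (H[i + 1L, j] > bh ||
        (H[i + 1L, j] == bh && Cst[i + 1L, j] < bc)) {
      bh <- H[i + 1L, j]; bc <- Cst[i + 1L, j]
    }
    if (H[i, j + 1L] > bh ||
        (H[i, j + 1L] == bh && Cst[i, j + 1L] < bc)) {
      bh <- H[i, j + 1L]; bc <- Cst[i, j + 1L]
    }
    H[i, j] <- bh; Cst[i, j] <- bc
  }
  mT <- integer(); mE <- integer()
  i <- 1L; j <- 1L
  while (i <= nT && j <= nE) {
    d <- abs(tt[i] - et[j])
    if (d < window && H[i, j] == H[i + 1L, j + 1L] + 1L &&
        Cst[i, j] == Cst[i + 1L, j + 1L] + d) {
      mT <- c(mT, i); mE <- c(mE, j); i <- i + 1L; j <- j + 1L
    } else if (H[i, j] == H[i + 1L, j] && Cst[i, j] == Cst[i + 1L, j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  list(hits = length(mT), misses = nT - length(mT),
       falsePositives = nE - length(mE),
       pairedErrors = et[mE] - tt[mT],
       matchedTruth = tt[mT], matchedEstimates = et[mE])
}

#' Sensitivity, precision and F1 from matching counts
#'
#' Sensitivity = Hit/(Hit + misses), Precision = Hit/(Hit + FP),
#' F1 = 2 (Sens x Prec)/(Sens + Prec). Empty denominators give 0
#' (conservative convention).
#'
#' @param hits,misses,falsePositives non-negative counts.
#' @return named numeric vector \code{c(sensitivity=, precision=, f1=)}.
#' @export
rocScores <- function(hits, misses, falsePositives) {
  sens <- if (hits + misses > 0) hits / (hits + misses) else 0
  prec <- if (hits + falsePositives > 0) hits / (hits + falsePositives)
          else 0
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  c(sensitivity = sens, precision = prec, f1 = f1)
}

#' Weighted spike-train edit distance (Victor-Purpura style)
#'
#' Minimal cost of reconstructing the truth from the estimate with
#' insertion/deletion cost 1 and shift cost \eqn{q |\Delta t|},
#' \eqn{q = 1/\mathrm{window}} per second, computed by the standard dynamic
#' program and normalized by the number of ground-truth spikes. The
#' inverse is capped (default 100) for (near-)zero distances.
#'
#' @param truth,estimate \code{SpikeTrain}s.
#' @param window matching window (s); the shift cost is its inverse.
#' @param cap cap for the reported inverse distance.
#' @return list with \code{distance}, \code{inverse} and
#'   \code{normalized} (FALSE when the truth is empty and the raw insertion
#'   count is returned).
#' @export
spikeDistance <- function(truth, estimate, window, cap = 100) {
  stopifnot(window > 0)
  tt <- spikeTimes(truth); et <- spikeTimes(estimate)
  q <- 1 / window
  nT <- length(tt); nE <- length(et)
  D <- matrix(0, nT + 1L, nE + 1L)
  D[, 1] <- 0:nT
  D[1, ] <- 0:nE
  for (i in seq_len(nT)) for (j in seq_len(nE))
    D[i + 1L, j + 1L] <- min(D[i, j + 1L] + 1, D[i + 1L, j] + 1,
                             D[i, j] + q * abs(tt[i] - et[j]))
  raw <- D[nT + 1L, nE + 1L]
  if (nT == 0L) {
    d <- raw
    normalized <- FALSE
  } else {
    d <- raw / nT
    normalized <- TRUE
  }
  inv <- if (d < 1 / cap) cap else 1 / d
  list(distance = d, inverse = inv, normalized = normalized)
}

#' CosMIC spike-train overlap score
#'
#' Membership functions are formed by convolving each train with the
#' triangle kernel \eqn{p(t) = (e - |t|)/e} on \eqn{|t| < e}; the score is
#' \eqn{2\,\lVert \min(y, y_{est}) \rVert / (\lVert y \rVert + \lVert
#' y_{est} \rVert)} with the L1 norm, evaluated numerically on a fine grid
#' (kernel width / 200).
#'
#' @param truth,estimate \code{SpikeTrain}s.
#' @param e triangle kernel half-width (s); defaults to the matching
#'   window.
#' @return score in [0, 1]; 1 (flagged via attribute \code{"trivial"})
#'   when both trains are empty.
#' @export
cosmic <- function(truth, estimate, e) {
  stopifnot(e > 0)
  tt <- spikeTimes(truth); et <- spikeTimes(estimate)
  if (!length(tt) && !length(et)) {
    out <- 1
    attr(out, "trivial") <- TRUE
    return(out)
  }
  if (!length(tt) || !length(et)) return(0)
  lo <- min(tt, et) - e; hi <- max(tt, et) + e
  step <- e / 200
  grid <- seq(lo, hi, by = step)
  memb <- function(st) {
    y <- numeric(length(grid))
    for (T in st) {
      idx <- which(abs(grid - T) < e)
      y[idx] <- y[idx] + (e - abs(grid[idx] - T)) / e
    }
    y
  }
  y <- memb(tt); ye <- memb(et)
  l1 <- function(v) sum((v[-1] + v[-length(v)]) / 2) * step
  2 * l1(pmin(y, ye)) / (l1(y) + l1(ye))
}

#' Hyperacuity index
#'
#' Ratio of the sampling interval to the mean absolute spike-timing error
#' over hit cases; 2 corresponds to the grid-quantization (Nyquist)
#' baseline. The mean error is floored at 1e-6 s.
#'
#' @param pairedErrors signed timing errors of hit cases (s).
#' @param samplingRate imaging rate (Hz).
#' @return the index (dimensionless).
#' @export
hyperacuityIndex <- function(pairedErrors, samplingRate) {
  if (!length(pairedErrors)) stop("no paired errors (no hit cases)")
  (1 / samplingRate) / max(mean(abs(pairedErrors)), 1e-6)
}

#' Compose all evaluation metrics for one (truth, estimate) pair
#'
#' Applies the window rule (half the sampling interval; 50 ms at 30 Hz and
#' above) unless a window is supplied, then computes matching counts,
#' sensitivity/precision/F1, the weighted spike distance and its inverse,
#' CosMIC (kernel width = window) and the hyperacuity index (NA when there
#' are no hits).
#'
#' @param truth,estimate \code{SpikeTrain}s.
#' @param samplingRate imaging rate (Hz).
#' @param window optional override of the matching window (s).
#' @return an \code{\linkS4class{EvalReport}}.
#' @export
evaluateSpikes <- function(truth, estimate, samplingRate, window = NULL) {
  if (is.null(window)) window <- matchWindowRule(samplingRate)
  m <- matchSpikes(truth, estimate, window)
  roc <- rocScores(m$hits, m$misses, m$falsePositives)
  sd_ <- spikeDistance(truth, estimate, window)
  cs <- as.numeric(cosmic(truth, estimate, window))
  hai <- if (m$hits > 0) hyperacuityIndex(m$pairedErrors, samplingRate)
         else NA_real_
  new("EvalReport", hits = as.integer(m$hits),
      misses = as.integer(m$misses),
      falsePositives = as.integer(m$falsePositives),
      sensitivity = unname(roc["sensitivity"]),
      precision = unname(roc["precision"]), f1 = unname(roc["f1"]),
      spikeDistance = sd_$distance, invSpikeDistance = sd_$inverse,
      cosmic = cs, hyperacuityIndex = hai,
      pairedErrors = m$pairedErrors, window = window)
}

#' Leave-one-out cross-validation over cells
#'
#' For each cell in turn, trains the supervised pipeline on the remaining
#' cells and evaluates on the held-out cell.
#'
#' @param cells list of cells, each \code{list(trace=, spikes=)} with
#'   ground truth.
#' @param ... passed to \code{\link{runSupervised}}.
#' @return list of \code{EvalReport}s, one per cell, with attribute
#'   \code{"summary"}: a data.frame of mean and 2 SEM per metric.
#' @export
loocv <- function(cells, ...) {
  if (length(cells) < 2L) stop("leave-one-out needs at least 2 cells")
  reports <- lapply(seq_along(cells), function(i) {
    run <- runSupervised(cells[-i], cells[i], ...)
    run$reports[[1]]
  })
  attr(reports, "summary") <- summarizeReports(reports)
  reports
}

#' Summarize a list of EvalReports as mean +/- 2 SEM
#'
#' @param reports list of \code{EvalReport}s.
#' @return data.frame with one row per metric.
#' @export
summarizeReports <- function(reports) {
  df <- do.call(rbind, lapply(reports, as.data.frame))
  metrics <- c("sensitivity", "precision", "f1", "spikeDistance",
               "invSpikeDistance", "cosmic", "hyperacuityIndex")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(df[[m]], na.rm = TRUE),
                  numeric(1)),
    twoSEM = vapply(metrics, function(m) {
      v <- df[[m]][!is.na(df[[m]])]
      if (length(v) < 2L) 0 else 2 * stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL)
}
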