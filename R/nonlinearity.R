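# Nonlinearity analysis: scatter the observed trace against the linear
# model prediction, fit a linear and two exponential transfer families, and
# compensate the trace through the inverse of the selected curve.

# RSS-optimal (c1, c3) are linear in exp(c2 * x); profile the 1-D RSS over
# c2 on each sign bracket.
.fitExpFamily <- function(x, y, sign = c("neg", "pos")) {
  sign <- match.arg(sign)
  xr <- diff(range(x))
  if (xr <= 0) return(NULL)
  rssAt <- function(c2) {
    b <- exp(c2 * (x - min(x)))          # scaled for conditioning
    fit <- stats::lm.fit(cbind(1, b), y)
    sum(fit$residuals^2)
  }
  bracket <- if (sign == "neg") c(-10 / xr, -1e-8 / xr)
             else c(1e-8 / xr, 10 / xr)
  opt <- tryCatch(stats::optimize(rssAt, bracket), error = function(e) NULL)
  if (is.null(opt)) return(NULL)
  c2 <- opt$minimum
  b <- exp(c2 * (x - min(x)))
  fit <- stats::lm.fit(cbind(1, b), y)
  # un-scale: c1 * exp(c2 x) + c3 with c1 = coef2 * exp(-c2 * min(x))
  c1 <- fit$coefficients[2] * exp(-c2 * min(x))
  c3 <- fit$coefficients[1]
  params <- c(c1 = unname(c1), c2 = unname(c2), c3 = unname(c3))
  if (!all(is.finite(params))) return(NULL)
  if (c1 * c2 <= 0) return(NULL)         # not strictly increasing
  list(params = params, rss = sum(fit$residuals^2), k = 3L)
}

.aicc <- function(rss, n, k) {
  # +1 for the noise variance
  kk <- k + 1L
  n * log(max(rss, 1e-300) / n) + 2 * kk +
    2 * kk * (kk + 1) / max(n - kk - 1, 1)
}

#' Quantify trace nonlinearity against the linear model prediction
#'
#' Builds (x, y) pairs of (linear prediction, observed amplitude) at all
#' frames, fits a through-origin linear model and a saturating and a growing
#' exponential \eqn{y = c_1 e^{c_2 x} + c_3}, and selects the family by the
#' small-sample-corrected information criterion (AICc). Exponential fits
#' that are not strictly increasing on the fit range are rejected. When the
#' scatter spans less than one single-spike amplitude the linear family is
#' returned with a warning (insufficient dynamic range).
#'
#' @param traces a \code{CalciumTrace} or list of them.
#' @param spikes matching \code{SpikeTrain}(s) (ground truth).
#' @param model a fitted \code{CaSpikeModel}.
#' @return a \code{\linkS4class{NonlinearityModel}}.
#' @export
analyzeNonlinearity <- function(traces, spikes, model) {
  if (is(traces, "CalciumTrace")) traces <- list(traces)
  if (is(spikes, "SpikeTrain")) spikes <- list(spikes)
  x <- unlist(lapply(seq_along(traces), function(i)
    linearPrediction(spikes[[i]], model, frameTimes(traces[[i]]))),
    use.names = FALSE)
  y <- unlist(lapply(traces, traceValues), use.names = FALSE)
  fitRange <- range(x)
  slope <- sum(x * y) / sum(x * x)
  linRSS <- sum((y - slope * x)^2)
  if (diff(fitRange) < singleSpikePeak(model)) {
    warning("insufficient dynamic range for nonlinearity analysis; ",
            "returning linear family")
    return(new("NonlinearityModel", family = "linear",
               params = c(slope = slope), fitRange = fitRange))
  }
  n <- length(x)
  cand <- list(list(family = "linear", params = c(slope = slope),
                    aicc = .aicc(linRSS, n, 1L)))
  for (sg in c("neg", "pos")) {
    f <- .fitExpFamily(x, y, sg)
    if (!is.null(f))
      cand[[length(cand) + 1L]] <- list(
        family = if (sg == "neg") "saturating-exponential"
                 else "growing-exponential",
        params = f$params, aicc = .aicc(f$rss, n, f$k))
  }
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aicc"))]]
  new("NonlinearityModel", family = best$family, params = best$params,
      fitRange = fitRange)
}

.nlCurve <- function(nl, x) {
  if (nl@family == "linear") nl@params[[1]] * x
  else nl@params[[1]] * exp(nl@params[[2]] * x) + nl@params[[3]]
}

#' Compensate a trace through the inverse nonlinearity
#'
#' Maps observed amplitudes through the inverse of the fitted transfer
#' curve so that compensated values are approximately linear in the
#' underlying model prediction. The linear family divides by the slope.
#' Exponential families are inverted numerically (vectorized bisection to
#' 1e-9) on the fit range; values below the curve's value at the lower fit
#' edge pass through unchanged, values above the upper edge continue with
#' the inverse slope at the edge.
#'
#' @param trace a \code{CalciumTrace}.
#' @param nl a \code{NonlinearityModel}.
#' @return the compensated \code{CalciumTrace}.
#' @export
compensateTrace <- function(trace, nl) {
  y <- traceValues(trace)
  if (nl@family == "linear")
    return(CalciumTrace(y / nl@params[[1]], samplingRate(trace),
                        startTime(trace)))
  xlo <- nl@fitRange[1]; xhi <- nl@fitRange[2]
  ylo <- .nlCurve(nl, xlo); yhi <- .nlCurve(nl, xhi)
  if (yhi <= ylo) stop("nonlinearity model is not invertible on fitRange")
  out <- y
  mid <- y >= ylo & y <= yhi
  if (any(mid)) {
    lo <- rep(xlo, sum(mid)); hi <- rep(xhi, sum(mid))
    target <- y[mid]
    for (i in seq_len(60)) {            # bisection: (xhi-xlo) / 2^60 << 1e-9
      m <- (lo + hi) / 2
      up <- .nlCurve(nl, m) < target
      lo[up] <- m[up]; hi[!up] <- m[!up]
    }
    out[mid] <- (lo + hi) / 2
  }
  hiSlope <- nl@params[[1]] * nl@params[[2]] * exp(nl@params[[2]] * xhi)
  out[y > yhi] <- xhi + (y[y > yhi] - yhi) / hiSlope
  # below the fit range: pass through unchanged
  CalciumTrace(out, samplingRate(trace), startTime(trace))
}
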