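# Candidate spike detection: matched-filter coincidence score, threshold
# crossings, detection hyperparameter search, and the SVM spike/non-spike
# classifier.

#' Matched-filter coincidence score
#'
#' Cross-correlates the first differences of the trace with the sampled
#' first differences of the spike kernel (support covering at least
#' 5 decay constants), aligned so the score at frame \eqn{k} reflects a
#' spike onset at frame \eqn{k}. The output is standardized to zero median
#' and unit robust SD (MAD) so thresholds are in robust-SD units.
#'
#' @param trace a \code{CalciumTrace}.
#' @param model a fitted \code{CaSpikeModel}.
#' @return numeric vector of standardized scores, one per frame (trailing
#'   frames without full kernel support are zero); attribute \code{"raw"}
#'   holds the unstandardized score.
#' @export
coincidenceScore <- function(trace, model) {
  y <- traceValues(trace)
  dt <- 1 / samplingRate(trace)
  m <- ceiling(5 * model@tau2 / dt)
  if (m + 1L > length(y))
    stop("kernel support exceeds trace length")
  gk <- kernelValue((0:m) * dt, 0, model@tau1, model@tau2)
  dg <- diff(gk)
  # zero-pad the derivative so late onsets keep a (truncated) template
  # match instead of a dead zone at the trace end
  dy <- c(diff(y), numeric(m))
  r <- stats::filter(dy, rev(dg), method = "convolution", sides = 1)
  valid <- seq_len(length(y) - 1L)
  raw <- numeric(length(y))
  raw[valid] <- r[valid + m - 1L]
  med <- stats::median(raw[valid])
  s <- stats::mad(raw[valid])
  if (s == 0) s <- stats::sd(raw[valid])
  std <- if (is.na(s) || s == 0) raw * 0 else (raw - med) / s
  std[length(y)] <- 0
  attr(std, "raw") <- raw
  std
}

#' Extract candidate segments at score threshold crossings
#'
#' One candidate per upward crossing of the threshold; the pseudo-spike
#' time PT is the onset time of the crossing frame. Segments span
#' \code{[PT - segmentPre, PT + segmentPost]} frames of both the trace and
#' the score, edge-padded by replication.
#'
#' @param trace a \code{CalciumTrace}.
#' @param scores standardized score vector from
#'   \code{\link{coincidenceScore}}.
#' @param config a \code{DetectionConfig}.
#' @return a \code{\linkS4class{CandidateSet}} (possibly empty), labels
#'   \code{"unknown"}.
#' @export
extractCandidates <- function(trace, scores, config) {
  thr <- config@scoreThreshold
  above <- scores >= thr
  cross <- which(above & !c(FALSE, above[-length(above)]))
  pre <- config@segmentPre; post <- config@segmentPost
  len <- pre + 1L + post
  n <- length(scores)
  y <- traceValues(trace)
  tt <- frameTimes(trace)
  if (!length(cross))
    return(new("CandidateSet", frames = matrix(numeric(), 0, len),
               scores = matrix(numeric(), 0, len), pt = numeric(),
               label = character()))
  idx <- vapply(cross, function(k) pmin(pmax(k + (-pre):post, 1L), n),
                integer(len))
  idx <- matrix(idx, nrow = len)        # segment frames x candidates
  new("CandidateSet",
      frames = t(matrix(y[idx], nrow = len)),
      scores = t(matrix(scores[idx], nrow = len)),
      pt = tt[cross],
      label = rep("unknown", length(cross)))
}

#' Label candidates against ground truth
#'
#' Matches candidate pseudo-spike times to true spike times with the
#' windowed one-to-one matcher; matched candidates are labelled
#' \code{"spike"}, the rest \code{"non-spike"}.
#'
#' @param candidates a \code{CandidateSet}.
#' @param truth a \code{SpikeTrain}.
#' @param window matching window (s).
#' @return the relabelled \code{CandidateSet}.
#' @export
labelCandidates <- function(candidates, truth, window) {
  if (!length(candidates)) return(candidates)
  m <- matchSpikes(truth, SpikeTrain(sort(candidates@pt)), window)
  hitTimes <- m$matchedEstimates
  lab <- ifelse(candidates@pt %in% hitTimes, "spike", "non-spike")
  # a PT can only be used once; duplicates beyond the matched count revert
  if (any(duplicated(candidates@pt[lab == "spike"]))) {
    for (ptv in unique(hitTimes)) {
      ix <- which(candidates@pt == ptv & lab == "spike")
      keep <- sum(hitTimes == ptv)
      if (length(ix) > keep) lab[ix[-seq_len(keep)]] <- "non-spike"
    }
  }
  new("CandidateSet", frames = candidates@frames,
      scores = candidates@scores, pt = candidates@pt, label = lab)
}

#' Optimize the detection threshold and segment length
#'
#' Grid search over score thresholds (0.5 to 5 robust-SD units in steps of
#' 0.5), \code{segmentPre} in \{1, 2, 3\} and \code{segmentPost} in
#' \{2, 4, 6, 8\} frames, maximizing the F1 score of the trained detector
#' on the training cells: for each configuration, candidates are
#' extracted and labelled per cell, the classifier is trained on the
#' remaining cells (leave-one-cell-out when 3 or more cells are
#' available) and the accepted detections of the held-out cell are
#' matched to its ground truth by the evaluation window rule. The
#' threshold is searched first at a mid-grid segment size, then the
#' segment grid at the selected threshold. Ties break toward the lower
#' threshold, then the shorter segment.
#'
#' @param cells list of training cells, each \code{list(trace=, spikes=)}.
#' @param model a fitted \code{CaSpikeModel}.
#' @param vernierFactor vernier factor recorded in the returned config.
#' @param thresholds,segmentPre,segmentPost optional custom grids.
#' @return the optimal \code{\linkS4class{DetectionConfig}}, with
#'   attribute \code{"f1"} (the cross-validated detector F1 achieved).
#' @export
optimizeDetection <- function(cells, model, vernierFactor = 10,
                              thresholds = seq(0.5, 5, by = 0.5),
                              segmentPre = 1:3,
                              segmentPost = c(2L, 4L, 6L, 8L)) {
  if (!length(cells)) stop("no training cells")
  if (any(vapply(cells, function(c) is.null(c$spikes), logical(1))))
    stop("optimizeDetection requires ground truth on every training cell")
  rate <- samplingRate(cells[[1]]$trace)
  window <- matchWindowRule(rate)
  scoresList <- lapply(cells, function(c) coincidenceScore(c$trace, model))
  detectorF1 <- function(thr, pre, post) {
    cfg <- DetectionConfig(thr, pre, post, vernierFactor, window)
    cand <- lapply(seq_along(cells), function(i)
      labelCandidates(
        extractCandidates(cells[[i]]$trace, scoresList[[i]], cfg),
        cells[[i]]$spikes, window))
    folds <- if (length(cells) >= 3L) seq_along(cells) else 0L
    f1s <- vapply(folds, function(hold) {
      trainIdx <- if (hold == 0L) seq_along(cells) else
        setdiff(seq_along(cells), hold)
      testIdx <- if (hold == 0L) seq_along(cells) else hold
      pool <- .bindCandidates(cand[trainIdx])
      clf <- if (length(pool) &&
                 length(unique(candidateLabels(pool))) >= 2L)
        trainClassifier(pool) else NULL
      mean(vapply(testIdx, function(i) {
        cc <- cand[[i]]
        lab <- if (is.null(clf) || !length(cc))
          rep("spike", length(cc)) else classifyCandidates(clf, cc)
        est <- SpikeTrain(sort(pseudoTimes(cc)[lab == "spike"]))
        m <- matchSpikes(cells[[i]]$spikes, est, window)
        rocScores(m$hits, m$misses, m$falsePositives)[["f1"]]
      }, numeric(1)))
    }, numeric(1))
    mean(f1s)
  }
  midPre <- segmentPre[ceiling(length(segmentPre) / 2)]
  midPost <- segmentPost[ceiling(length(segmentPost) / 2)]
  f1Thr <- vapply(thresholds, detectorF1, numeric(1), pre = midPre,
                  post = midPost)
  bestThr <- thresholds[which.max(f1Thr)]      # ties -> lower threshold
  segGrid <- expand.grid(pre = segmentPre, post = segmentPost)
  segGrid <- segGrid[order(segGrid$pre + segGrid$post, segGrid$post), ]
  f1Seg <- mapply(detectorF1, pre = segGrid$pre, post = segGrid$post,
                  MoreArgs = list(thr = bestThr))
  bestSeg <- segGrid[which.max(f1Seg), ]       # ties -> shorter segment
  cfg <- DetectionConfig(scoreThreshold = bestThr,
                         segmentPre = bestSeg$pre,
                         segmentPost = bestSeg$post,
                         vernierFactor = vernierFactor,
                         matchWindow = window)
  attr(cfg, "f1") <- max(f1Seg)
  cfg
}

.candidateFeatures <- function(candidates) {
  cbind(candidates@frames, candidates@scores)
}

#' Train the spike/non-spike classifier
#'
#' A radial-basis support vector machine on the concatenated feature vector
#' [segment frames, segment scores], standardized by training-set
#' statistics, with class weights inversely proportional to class
#' frequency (candidate sets are dominated by false crossings).
#'
#' @param candidates a labelled \code{CandidateSet} (no \code{"unknown"}
#'   labels, both classes present).
#' @return a \code{\linkS4class{SpikeClassifier}}.
#' @export
trainClassifier <- function(candidates) {
  lab <- candidateLabels(candidates)
  if (any(lab == "unknown")) stop("candidates must be labelled")
  if (length(unique(lab)) < 2L)
    stop("training candidates contain a single class")
  X <- .candidateFeatures(candidates)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  yf <- factor(lab, levels = c("non-spike", "spike"))
  w <- length(yf) / (2 * table(yf))
  fit <- e1071::svm(Xs, yf, kernel = "radial", scale = FALSE,
                    class.weights = c("non-spike" = unname(w[1]),
                                      "spike" = unname(w[2])))
  new("SpikeClassifier", svm = fit, center = ctr, scale = scl,
      featureLength = ncol(X))
}

#' Classify candidates as spikes or non-spikes
#'
#' @param classifier a trained \code{SpikeClassifier}.
#' @param candidates a \code{CandidateSet}.
#' @return character vector of labels, one per candidate.
#' @export
classifyCandidates <- function(classifier, candidates) {
  if (!length(candidates)) return(character())
  X <- .candidateFeatures(candidates)
  if (ncol(X) != classifier@featureLength)
    stop("feature length mismatch between training and test candidates")
  Xs <- scale(X, classifier@center, classifier@scale)
  as.character(stats::predict(classifier@svm, Xs))
}
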