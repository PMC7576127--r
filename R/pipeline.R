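# Pipeline orchestration: supervised train/test runs and the unsupervised
# batch driver. A "cell" is list(trace = CalciumTrace, spikes = SpikeTrain)
# with spikes optional on test cells.

#' Run the supervised pipeline
#'
#' Training: fit the spike model on the training cells, analyze (and if a
#' non-linear family is selected, compensate) the nonlinearity, optimize
#' the detection threshold/segment, and train the spike/non-spike
#' classifier on labelled candidates. Testing, per cell: compensate,
#' score, extract candidates, classify, vernier-refine accepted spikes,
#' and (when ground truth is present) evaluate. A failing test cell is
#' isolated: its error is recorded and the batch continues. The run is
#' deterministic given its inputs.
#'
#' @param trainCells,testCells lists of cells; training cells must carry
#'   ground truth.
#' @param vernierFactor sub-frame refinement factor.
#' @param compensate apply nonlinearity compensation when a non-linear
#'   family is selected.
#' @param windowPost residual-window extent for jitter estimation (s).
#' @return list with components \code{model}, \code{nonlinearity},
#'   \code{config}, \code{classifier}, and per test cell:
#'   \code{estimates} (refined \code{SpikeTrain}s), \code{gridEstimates}
#'   (the same detections with SJ forced to 0), \code{reports}
#'   (\code{EvalReport}s or NULL), \code{gridReports},
#'   \code{candidateSensitivity} (candidate-level, pre-classifier) and
#'   \code{errors} (per-cell error messages or NULL).
#' @export
runSupervised <- function(trainCells, testCells, vernierFactor = 10,
                          compensate = TRUE, windowPost = 0.25) {
  if (!length(trainCells)) stop("no training cells")
  if (any(vapply(trainCells, function(c) is.null(c$spikes) ||
                   length(c$spikes) == 0L, logical(1))))
    stop("every training cell needs ground-truth spikes")
  model <- fitSpikeModel(lapply(trainCells, `[[`, "trace"),
                         lapply(trainCells, `[[`, "spikes"),
                         vernierFactor = vernierFactor)
  nl <- analyzeNonlinearity(lapply(trainCells, `[[`, "trace"),
                            lapply(trainCells, `[[`, "spikes"), model)
  doComp <- compensate && nl@family != "linear"
  compCell <- function(cell) {
    if (doComp) cell$trace <- compensateTrace(cell$trace, nl)
    cell
  }
  trainC <- lapply(trainCells, compCell)
  cfg <- optimizeDetection(trainC, model, vernierFactor = vernierFactor)
  labelled <- lapply(trainC, function(cell) {
    sc <- coincidenceScore(cell$trace, model)
    labelCandidates(extractCandidates(cell$trace, sc, cfg), cell$spikes,
                    cfg@matchWindow)
  })
  pool <- .bindCandidates(labelled)
  clf <- if (length(pool) && length(unique(candidateLabels(pool))) >= 2L)
    trainClassifier(pool) else NULL
  out <- list(model = model, nonlinearity = nl, config = cfg,
              classifier = clf, estimates = list(),
              gridEstimates = list(), reports = list(),
              gridReports = list(), candidateSensitivity = numeric(),
              errors = list(),
              manifest = list(
                package = "hyperspike",
                version = as.character(utils::packageVersion("hyperspike")),
                mode = "supervised", nTrain = length(trainCells),
                nTest = length(testCells),
                vernierFactor = vernierFactor, compensate = compensate,
                windowPost = windowPost))
  for (i in seq_along(testCells)) {
    res <- tryCatch({
      cell <- compCell(testCells[[i]])
      sc <- coincidenceScore(cell$trace, model)
      cands <- extractCandidates(cell$trace, sc, cfg)
      lab <- if (is.null(clf) || !length(cands))
        rep("spike", length(cands)) else classifyCandidates(clf, cands)
      accepted <- cands[lab == "spike"]
      est <- refineSpikeTimes(cell$trace, model, accepted, cfg,
                              windowPost = windowPost)
      grid <- refineSpikeTimes(cell$trace, model, accepted, cfg,
                               refine = FALSE)
      rate <- samplingRate(cell$trace)
      truth <- testCells[[i]]$spikes
      rep_ <- gridRep <- NULL
      candSens <- NA_real_
      if (!is.null(truth)) {
        rep_ <- evaluateSpikes(truth, est, rate)
        gridRep <- evaluateSpikes(truth, grid, rate)
        allRefined <- refineSpikeTimes(cell$trace, model, cands, cfg,
                                       windowPost = windowPost)
        mAll <- matchSpikes(truth, allRefined, cfg@matchWindow)
        candSens <- rocScores(mAll$hits, mAll$misses,
                              mAll$falsePositives)[["sensitivity"]]
      }
      list(est = est, grid = grid, rep = rep_, gridRep = gridRep,
           candSens = candSens, err = NULL)
    }, error = function(e) list(est = SpikeTrain(), grid = SpikeTrain(),
                                rep = NULL, gridRep = NULL,
                                candSens = NA_real_,
                                err = conditionMessage(e)))
    out$estimates[[i]] <- res$est
    out$gridEstimates[[i]] <- res$grid
    out$reports[i] <- list(res$rep)
    out$gridReports[i] <- list(res$gridRep)
    out$candidateSensitivity[i] <- res$candSens
    out$errors[i] <- list(res$err)
  }
  out
}

#' Run the unsupervised pipeline over a batch of cells
#'
#' Delegates to \code{\link{unsupervisedPipeline}} per cell. Ground truth,
#' when supplied, is used exclusively for evaluation, never for training:
#' the detection path sees only the trace.
#'
#' @param cells list of cells (\code{spikes} optional).
#' @param seed master seed; per-cell seeds are derived from it.
#' @param ... passed to \code{\link{unsupervisedPipeline}}.
#' @return list with \code{estimates} (one \code{SpikeTrain} per cell),
#'   \code{reports} (\code{EvalReport} or NULL per cell) and
#'   \code{errors}.
#' @export
runUnsupervised <- function(cells, seed = 1, ...) {
  out <- list(estimates = list(), reports = list(), errors = list(),
              manifest = list(
                package = "hyperspike",
                version = as.character(utils::packageVersion("hyperspike")),
                mode = "unsupervised", nCells = length(cells),
                seed = seed))
  for (i in seq_along(cells)) {
    res <- tryCatch({
      est <- unsupervisedPipeline(cells[[i]]$trace,
                                  seed = .deriveSeed(seed, i), ...)
      rep_ <- if (!is.null(cells[[i]]$spikes))
        evaluateSpikes(cells[[i]]$spikes, est,
                       samplingRate(cells[[i]]$trace)) else NULL
      list(est = est, rep = rep_, err = NULL)
    }, error = function(e) list(est = SpikeTrain(), rep = NULL,
                                err = conditionMessage(e)))
    out$estimates[[i]] <- res$est
    out$reports[i] <- list(res$rep)
    out$errors[i] <- list(res$err)
  }
  out
}
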