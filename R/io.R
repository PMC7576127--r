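# Readers/writers for traces, spike trains, evaluation reports and datasets.
# Delimited dialect: comma or tab (autodetected), "#" starts a comment line.

.readDelim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(matrix(numeric(), 0, 0))
  sep <- if (any(grepl(",", lines, fixed = TRUE))) "," else "\t"
  parts <- strsplit(lines, sep, fixed = TRUE)
  # fall back to whitespace when neither separator is present
  if (sep == "\t" && all(lengths(parts) == 1L))
    parts <- strsplit(lines, "[[:space:]]+")
  ncol <- max(lengths(parts))
  vals <- vapply(parts, function(p) {
    p <- trimws(p)
    out <- suppressWarnings(as.numeric(p))
    if (anyNA(out)) stop("non-numeric entry in ", path, ": ",
                         paste(p, collapse = sep))
    c(out, rep(NA_real_, ncol - length(out)))
  }, numeric(ncol))
  t(matrix(vals, nrow = ncol))
}

.readMeta <- function(path) {
  lines <- grep("^#", readLines(path, warn = FALSE), value = TRUE)
  meta <- list()
  for (key in c("sampling_rate", "start_time")) {
    hit <- grep(paste0(key, "\\s*[:=]"), lines, value = TRUE)
    if (length(hit))
      meta[[key]] <- as.numeric(sub(paste0(".*", key, "\\s*[:=]\\s*"), "",
                                    hit[[1]]))
  }
  meta
}

#' Read a calcium trace from disk
#'
#' Delimited files carry either (time, value) columns or a single value
#' column with the sampling rate declared via \code{samplingRate} or a
#' \code{# sampling_rate:} header comment. When a time column is present the
#' sampling rate is inferred as 1 / median inter-frame interval and frame
#' times are checked for uniformity to a relative tolerance of 1e-3.
#' Feather files (\code{format = "feather"}, requires \pkg{arrow}) carry
#' columns \code{time} and \code{value}.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"delimited"} or
#'   \code{"feather"}.
#' @param samplingRate declared rate (Hz) for single-column files.
#' @return a \code{\linkS4class{CalciumTrace}}.
#' @export
readTrace <- function(path, format = c("auto", "delimited", "feather"),
                      samplingRate = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(feather|arrow)$", path)) "feather" else
      "delimited"
  if (format == "feather") {
    .needArrow()
    df <- as.data.frame(arrow::read_feather(path))
    return(.traceFromColumns(df$time, df$value))
  }
  m <- .readDelim(path)
  if (nrow(m) < 2L) stop("trace file has fewer than 2 frames: ", path)
  meta <- .readMeta(path)
  if (ncol(m) >= 2L && !anyNA(m[, 2])) {
    .traceFromColumns(m[, 1], m[, 2])
  } else {
    rate <- samplingRate %||% meta$sampling_rate
    if (is.null(rate))
      stop("single-column trace file needs a declared sampling rate")
    CalciumTrace(m[, 1], rate, meta$start_time %||% 0)
  }
}

.traceFromColumns <- function(times, values) {
  dt <- diff(times)
  step <- stats::median(dt)
  if (step <= 0) stop("non-increasing time column")
  if (any(abs(dt - step) > 1e-3 * step))
    stop("non-uniform frame times (beyond 1e-3 relative tolerance)")
  CalciumTrace(values, 1 / step, times[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a calcium trace to disk
#'
#' Delimited output is two comma-separated columns (time, value) with the
#' rate recorded in a header comment, so that
#' \code{readTrace(writeTrace(x))} is the identity.
#'
#' @param trace a \code{CalciumTrace}.
#' @param path destination path.
#' @param format \code{"delimited"} or \code{"feather"}.
#' @return \code{path}, invisibly.
#' @export
writeTrace <- function(trace, path,
                       format = c("auto", "delimited", "feather")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(feather|arrow)$", path)) "feather" else
      "delimited"
  tt <- frameTimes(trace)
  if (format == "feather") {
    .needArrow()
    arrow::write_feather(data.frame(time = tt, value = traceValues(trace)),
                         path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate: %.12g", samplingRate(trace)),
               sprintf("# start_time: %.12g", startTime(trace)),
               "# time,value",
               sprintf("%.12g,%.12g", tt, traceValues(trace))), con)
  invisible(path)
}

.needArrow <- function() {
  if (!requireNamespace("arrow", quietly = TRUE))
    stop("the 'arrow' package is required for feather I/O")
}

#' Read spike times from disk
#'
#' One spike time (s) per line, or the first column of a delimited file.
#' Unsorted files are sorted with a warning; negative times are an error.
#'
#' @param path file path.
#' @return a \code{\linkS4class{SpikeTrain}}.
#' @export
readSpikes <- function(path) {
  m <- .readDelim(path)
  if (!length(m)) return(SpikeTrain(numeric()))
  times <- m[, 1]
  if (any(times < 0)) stop("negative spike time in ", path)
  if (is.unsorted(times)) {
    warning("spike times in ", path, " were unsorted; sorting")
    times <- sort(times)
  }
  SpikeTrain(times)
}

#' Write spike times to disk
#'
#' @param spikes a \code{SpikeTrain}.
#' @param path destination path.
#' @return \code{path}, invisibly.
#' @export
writeSpikes <- function(spikes, path) {
  writeLines(sprintf("%.12g", spikeTimes(spikes)), path)
  invisible(path)
}

#' Write / read an evaluation report (JSON)
#'
#' @param report an \code{EvalReport}.
#' @param path destination path.
#' @return \code{path} (write) or an \code{EvalReport} (read).
#' @export
writeReport <- function(report, path) {
  x <- as.data.frame(report)
  obj <- c(as.list(x), list(pairedErrors = report@pairedErrors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("EvalReport", hits = as.integer(obj$hits),
      misses = as.integer(obj$misses),
      falsePositives = as.integer(obj$falsePositives),
      sensitivity = obj$sensitivity, precision = obj$precision,
      f1 = obj$f1, spikeDistance = obj$spikeDistance,
      invSpikeDistance = obj$invSpikeDistance, cosmic = obj$cosmic,
      hyperacuityIndex = obj$hyperacuityIndex,
      pairedErrors = as.numeric(obj$pairedErrors %||% numeric()),
      window = obj$window)
}

#' Write / read a simulated dataset as a columnar binary container
#'
#' Stores all cells of a dataset (traces, sampling rate, optional ground
#' truth) in a single Feather file with columns \code{kind}
#' (\code{"trace"} / \code{"spike"}), \code{cell}, \code{time},
#' \code{value} and \code{rate}. Requires \pkg{arrow}.
#'
#' @param dataset a list of cells, each \code{list(trace=, spikes=)} as
#'   returned by \code{\link{generateDataset}}.
#' @param path destination \code{.feather} path.
#' @return \code{path} (write) or the dataset list (read).
#' @export
writeDataset <- function(dataset, path) {
  .needArrow()
  rows <- lapply(seq_along(dataset), function(i) {
    cell <- dataset[[i]]
    tr <- cell$trace
    out <- data.frame(kind = "trace", cell = i, time = frameTimes(tr),
                      value = traceValues(tr), rate = samplingRate(tr))
    if (!is.null(cell$spikes) && length(cell$spikes))
      out <- rbind(out, data.frame(kind = "spike", cell = i,
                                   time = spikeTimes(cell$spikes),
                                   value = NA_real_,
                                   rate = samplingRate(tr)))
    out
  })
  arrow::write_feather(do.call(rbind, rows), path)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) {
  .needArrow()
  df <- as.data.frame(arrow::read_feather(path))
  lapply(sort(unique(df$cell)), function(i) {
    tr <- df[df$cell == i & df$kind == "trace", ]
    sp <- df[df$cell == i & df$kind == "spike", ]
    list(trace = CalciumTrace(tr$value, tr$rate[1], tr$time[1]),
         spikes = SpikeTrain(sort(sp$time)))
  })
}
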