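# Shared fixtures, built in code at test time.

# a small noiseless trace with known spikes
noiselessCell <- function(spikeTimes, model = CaSpikeModel(0.01, 0.5, 1, 0),
                          rate = 60, duration = 10) {
  st <- SpikeTrain(spikeTimes)
  list(trace = synthesizeTrace(st, model, alpha = 1, snr = Inf,
                               samplingRate = rate, duration = duration),
       spikes = st, model = model)
}

# exhaustive optimal one-to-one matching oracle: maximize hits, then
# minimize total |dt|; enumerates all injective assignments
oracleMatch <- function(truth, estimate, window) {
  tt <- spikeTimes(truth); et <- spikeTimes(estimate)
  nT <- length(tt); nE <- length(et)
  best <- list(hits = -1L, cost = Inf)
  assign_ <- function(i, used, hits, cost) {
    if (i > nT) {
      if (hits > best$hits ||
          (hits == best$hits && cost < best$cost))
        best <<- list(hits = hits, cost = cost)
      return(invisible())
    }
    assign_(i + 1L, used, hits, cost)          # truth i unmatched
    for (j in seq_len(nE)) {
      if (!used[j] && abs(tt[i] - et[j]) < window) {
        used[j] <- TRUE
        assign_(i + 1L, used, hits + 1L, cost + abs(tt[i] - et[j]))
        used[j] <- FALSE
      }
    }
  }
  assign_(1L, logical(nE), 0L, 0)
  best
}

# brute-force spike distance: enumerate all monotone injective pairings
oracleSpikeDistance <- function(truth, estimate, window) {
  tt <- spikeTimes(truth); et <- spikeTimes(estimate)
  q <- 1 / window
  nT <- length(tt); nE <- length(et)
  best <- Inf
  rec <- function(i, j, cost) {
    if (cost >= best) return(invisible())
    if (i > nT && j > nE) { best <<- min(best, cost); return(invisible()) }
    if (i > nT) { best <<- min(best, cost + (nE - j + 1L)); return(invisible()) }
    if (j > nE) { best <<- min(best, cost + (nT - i + 1L)); return(invisible()) }
    rec(i + 1L, j, cost + 1)                   # delete truth i
    rec(i, j + 1L, cost + 1)                   # delete estimate j
    rec(i + 1L, j + 1L, cost + q * abs(tt[i] - et[j]))  # shift
  }
  rec(1L, 1L, 0)
  best
}
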