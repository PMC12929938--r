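# Independent brute-force oracles used to validate the implementations.
# These deliberately avoid the package's own code paths.

# Per-bin standard deviation by explicit formula (N-1 denominator), with
# the bin partition re-derived from the documented contract (near-equal
# contiguous bins, remainder on the leading bins).
oracleBinSds <- function(x, nBins) {
  n <- length(x)
  base <- n %/% nBins
  rem <- n %% nBins
  out <- numeric(nBins)
  pos <- 1L
  for (i in seq_len(nBins)) {
    size <- base + if (i <= rem) 1L else 0L
    seg <- x[pos:(pos + size - 1L)]
    pos <- pos + size
    if (size > 1L) {
      mu <- sum(seg) / size
      out[i] <- sqrt(sum((seg - mu)^2) / (size - 1L))
    } else out[i] <- 0
  }
  out
}

oracleBinStarts <- function(n, nBins) {
  base <- n %/% nBins
  rem <- n %% nBins
  sizes <- base + c(rep(1L, rem), rep(0L, nBins - rem))
  c(0L, cumsum(sizes)[-nBins])
}

# Brute-force MSD delay rule: enumerate every (start, length) pair of
# consecutive bins, check every bin of the candidate run is below the
# threshold and inside the delay region, and the run is strictly longer
# than minRun.
oracleMsdDelayed <- function(x, nBins, threshold, minRun, fracPos) {
  sds <- oracleBinSds(x, nBins)
  n <- length(x)
  base <- n %/% nBins
  rem <- n %% nBins
  sizes <- base + c(rep(1L, rem), rep(0L, nBins - rem))
  starts <- c(0L, cumsum(sizes)[-nBins])
  inRegion <- starts / n >= fracPos
  for (s in seq_len(nBins)) {
    for (e in s:nBins) {
      len <- e - s + 1L
      if (len <= minRun) next
      if (all(inRegion[s:e]) && all(sds[s:e] < threshold)) return(TRUE)
    }
  }
  FALSE
}

# Score-only Smith-Waterman DP (no traceback machinery).
oracleSwScore <- function(read, ref, match = 5L, mismatch = -4L, gap = -8L) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  n <- length(a)
  m <- length(b)
  H <- matrix(0L, n + 1L, m + 1L)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      H[i + 1L, j + 1L] <- max(0L, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# Exhaustive DTW: enumerate every monotone warping path on the full grid
# and take the cheapest. Feasible for lengths <= 5.
oracleDtw <- function(a, b) {
  n <- length(a)
  m <- length(b)
  best <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + abs(a[i] - b[j])
    if (cost >= best) return()
    if (i == n && j == m) {
      best <<- cost
      return()
    }
    if (i < n && j < m) walk(i + 1L, j + 1L, cost)
    if (i < n) walk(i + 1L, j, cost)
    if (j < m) walk(i, j + 1L, cost)
  }
  walk(1L, 1L, 0)
  best
}

# Definitional confusion-matrix metrics.
oracleMetrics <- function(tp, fp, fn, tn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = prec, recall = rec, f1 = f1, mcc = mcc)
}

# AUC by explicit pair counting with half credit for ties.
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == "delayed" | labels == TRUE]
  neg <- scores[!(labels == "delayed" | labels == TRUE)]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
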