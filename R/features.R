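# Signal-level features shared by the rule classifiers: normalization,
# binned standard deviation, spectral entropy, DTW.

#' Min-max normalize a trace
#'
#' Rescales a current trace affinely to the unit interval, the scale on
#' which the MSD sigma threshold (default 0.003) is defined. Order-preserving
#' and idempotent.
#'
#' @param trace an [EventTrace-class] or a numeric vector.
#' @return numeric vector with minimum 0 and maximum 1.
#' @examples
#' normalizeTrace(c(200, 450, 700))
#' @export
normalizeTrace <- function(trace) {
  x <- if (is(trace, "EventTrace")) traceSamples(trace) else as.numeric(trace)
  r <- range(x)
  if (!is.finite(r[1]) || !is.finite(r[2]))
    stop("trace contains non-finite samples")
  if (r[1] == r[2])
    stop("degenerate input: constant trace cannot be min-max normalized")
  (x - r[1]) / (r[2] - r[1])
}

#' Binned standard-deviation profile
#'
#' Partitions a (normalized) trace into \code{nBins} contiguous, near-equal
#' bins (any remainder is spread over the leading bins) and computes the
#' per-bin sample standard deviation (N-1 denominator). This binned moving
#' standard deviation is the feature the MSD delay rule thresholds.
#'
#' @param x numeric vector, usually output of [normalizeTrace()].
#' @param nBins number of bins (>= 2).
#' @return an [MsdProfile-class] object.
#' @examples
#' prof <- msdProfile(normalizeTrace(rnorm(1500, 450, 12)), 75)
#' prof
#' @export
msdProfile <- function(x, nBins) {
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2")
  n <- length(x)
  if (n < nBins) stop("event shorter than the number of bins")
  base <- n %/% nBins
  rem <- n %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, rem), rep(0L, nBins - rem))
  ends <- cumsum(sizes)
  starts <- c(0L, ends[-nBins])
  sig <- vapply(seq_len(nBins), function(i) {
    seg <- x[(starts[i] + 1L):ends[i]]
    if (length(seg) > 1L) sd(seg) else 0
  }, numeric(1))
  new("MsdProfile", sigmaBins = sig, binStarts = as.integer(starts),
      binEnds = as.integer(ends), nBins = nBins)
}

# Shared helper: normalized Shannon entropy of a nonnegative power vector.
.powerEntropy <- function(S) {
  tot <- sum(S)
  if (tot <= 0) return(0)  # perfectly flat frame: minimal entropy
  P <- S / tot
  P <- P[P > 0]
  -sum(P * log2(P)) / log2(length(S))
}

.taper <- function(n, shape) {
  if (shape == "hamming") 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  else rep(1, n)
}

#' Global spectral entropy of a signal
#'
#' Power-normalized Shannon entropy of the discrete Fourier spectrum,
#' divided by \code{log2(N)} where N is the number of retained frequency
#' components, so the result lies in [0, 1]. The signal mean is removed
#' before the transform (the DC component would otherwise dominate the
#' power distribution) and only positive frequencies are retained. A value
#' near 1 indicates broadband, noise-like content (all components
#' contributing equally attains exactly 1); a flat or tonal signal with few
#' distinct components scores near 0.
#'
#' @param x numeric vector, length >= 4, not constant.
#' @return spectral entropy in [0, 1].
#' @examples
#' spectralEntropy(sin(2 * pi * 8 * (0:255) / 256))  # pure tone, ~0
#' @export
spectralEntropy <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("signal too short for spectral entropy (need >= 4)")
  x <- x - mean(x)
  if (all(x == 0)) stop("undefined entropy: signal has no variation")
  X <- fft(x)
  N <- n %/% 2L
  S <- Mod(X[2:(N + 1L)])^2
  .powerEntropy(S)
}

#' Instantaneous spectral entropy
#'
#' Splits the event into overlapping spectrogram frames and computes the
#' normalized spectral entropy of each frame's power spectrum (per-frame
#' probability distribution over frequencies). Each frame is mean-removed
#' and tapered before the transform; a frame with no variation (a perfectly
#' flat plateau) scores 0, the minimal-entropy limit. Frames are assigned a
#' fractional position by their center sample.
#'
#' @param trace an [EventTrace-class] or numeric vector.
#' @param spec a [SpectrogramSpec-class]; defaults: 128-sample Hamming
#'   frames, 50\% overlap.
#' @return an [SeTrace-class] with one value per frame.
#' @examples
#' se <- instantaneousSE(rnorm(2000, 450, 12))
#' se
#' @export
instantaneousSE <- function(trace, spec = spectrogramSpec()) {
  x <- if (is(trace, "EventTrace")) traceSamples(trace) else as.numeric(trace)
  validObject(spec)
  n <- length(x)
  win <- spec@windowLen
  if (n < win) stop("event shorter than the spectrogram window")
  hop <- as.integer(floor(win * (1 - spec@overlapFrac)))
  nFrames <- (n - win) %/% hop + 1L
  w <- .taper(win, spec@windowShape)
  nfft <- spec@fftLen
  N <- nfft %/% 2L
  se <- numeric(nFrames)
  centers <- numeric(nFrames)
  for (i in seq_len(nFrames)) {
    s <- (i - 1L) * hop
    fr <- x[(s + 1L):(s + win)]
    fr <- (fr - mean(fr)) * w
    if (nfft > win) fr <- c(fr, rep(0, nfft - win))
    X <- fft(fr)
    S <- Mod(X[2:(N + 1L)])^2
    se[i] <- .powerEntropy(S)
    centers[i] <- s + (win - 1) / 2
  }
  new("SeTrace", seValues = se, frameCenters = centers,
      frameFracs = centers / n)
}

#' Dynamic time warping distance
#'
#' Accumulated optimal-path cost of the classic DTW dynamic program:
#' absolute-difference local cost, symmetric step pattern (diagonal,
#' vertical, horizontal), no warping window, no normalization. Zero for
#' identical signals; symmetric in its arguments. Used to quantify the
#' similarity of delayed-event signatures and localize the delay region.
#'
#' @param a,b non-empty numeric vectors.
#' @return nonnegative accumulated cost.
#' @examples
#' dtwDistance(c(0, 0, 1), c(0, 1))  # 0: warping absorbs the repeat
#' @export
dtwDistance <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("empty input")
  .dtw_cpp(a, b)
}

#' Export feature profiles to a data.frame
#'
#' Tidy per-bin / per-frame representation suitable for CSV export and
#' plotting.
#'
#' @param object an [MsdProfile-class] or [SeTrace-class].
#' @return a data.frame.
#' @export
setGeneric("featureTable", function(object) standardGeneric("featureTable"))

#' @rdname featureTable
#' @export
setMethod("featureTable", "MsdProfile", function(object) {
  data.frame(bin_index = seq_len(object@nBins) - 1L,
             start = object@binStarts, end = object@binEnds,
             sigma = object@sigmaBins)
})

#' @rdname featureTable
#' @export
setMethod("featureTable", "SeTrace", function(object) {
  data.frame(frame_center = object@frameCenters,
             frame_frac = object@frameFracs, se = object@seValues)
})
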