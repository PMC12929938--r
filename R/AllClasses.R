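# S4 classes for the central data objects.

#' Simulator configuration
#'
#' Parameters of the synthetic nanopore event generator. Defaults emulate the
#' acquisition conditions of the assay this package models: 5 kHz sampling,
#' currents clipped to the 200-700 pA band, a stepped barcode-level
#' background with ~12 pA broadband noise, and a quiet delay plateau whose
#' onset falls at a fractional position of at least 0.7.
#'
#' @slot samplingRate sampling rate in Hz (default 5000).
#' @slot baseLevel mean open-channel blockade level in pA (default 450).
#' @slot bandLow,bandHigh clipping band in pA (defaults 200, 700); every
#'   emitted sample lies inside the band.
#' @slot eventLenRange integer pair, event length range in samples
#'   (default 1500-4000).
#' @slot stepBlockLenRange integer pair, samples per barcode-like current
#'   step (default 150-400).
#' @slot stepAmpSd between-block current-level spread in pA (default 20).
#' @slot noiseSd within-block broadband noise sd in pA (default 12).
#' @slot delayOnsetFracRange pair in [0,1], delay onset fraction
#'   (default 0.70-0.80).
#' @slot delayLenFracRange pair in (0,1], delay length as a fraction of the
#'   event (default 0.17-0.25).
#' @slot delayNoiseSd marginal sd of the slow wander inside the delay
#'   plateau, in pA (default 1); must be smaller than \code{noiseSd} - the
#'   delay segment is quieter by construction.
#' @slot noisyDelayProb probability that a delayed event is a "noisy delay"
#'   contaminant whose plateau carries broadband bursts (default 0).
#' @slot noisyDelayBurstSd sd of the contaminant bursts in pA (default 12).
#' @slot seed integer seed recorded with the configuration.
#'
#' @seealso [simConfig()], [generateEvent()]
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    samplingRate = "numeric",
    baseLevel = "numeric",
    bandLow = "numeric",
    bandHigh = "numeric",
    eventLenRange = "integer",
    stepBlockLenRange = "integer",
    stepAmpSd = "numeric",
    noiseSd = "numeric",
    delayOnsetFracRange = "numeric",
    delayLenFracRange = "numeric",
    delayNoiseSd = "numeric",
    noisyDelayProb = "numeric",
    noisyDelayBurstSd = "numeric",
    seed = "integer"
  ),
  prototype(
    samplingRate = 5000,
    baseLevel = 450,
    bandLow = 200,
    bandHigh = 700,
    eventLenRange = c(1500L, 4000L),
    stepBlockLenRange = c(150L, 400L),
    stepAmpSd = 20,
    noiseSd = 12,
    delayOnsetFracRange = c(0.70, 0.80),
    delayLenFracRange = c(0.17, 0.25),
    delayNoiseSd = 1,
    noisyDelayProb = 0,
    noisyDelayBurstSd = 12,
    seed = 1L
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (!(object@bandLow < object@baseLevel && object@baseLevel < object@bandHigh))
    msg <- c(msg, "bandLow < baseLevel < bandHigh required")
  for (nm in c("eventLenRange", "stepBlockLenRange",
               "delayOnsetFracRange", "delayLenFracRange")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, sprintf("%s must be an ordered pair (low <= high)", nm))
  }
  if (any(object@delayOnsetFracRange < 0) || any(object@delayOnsetFracRange > 1))
    msg <- c(msg, "delayOnsetFracRange must lie in [0, 1]")
  if (object@delayLenFracRange[1] <= 0 || object@delayLenFracRange[2] > 1)
    msg <- c(msg, "delayLenFracRange must lie in (0, 1]")
  if (object@delayNoiseSd < 0 || object@noiseSd < 0 ||
      object@stepAmpSd < 0 || object@noisyDelayBurstSd < 0)
    msg <- c(msg, "noise parameters must be nonnegative")
  if (object@delayNoiseSd >= object@noiseSd)
    msg <- c(msg, "delayNoiseSd must be smaller than noiseSd (delay is quieter)")
  if (object@noisyDelayProb < 0 || object@noisyDelayProb > 1)
    msg <- c(msg, "noisyDelayProb must be a probability")
  if (length(msg)) msg else TRUE
})

#' One translocation event
#'
#' A single nanopore translocation event: a vector of ionic-current samples
#' (pA) with its sampling rate, an optional ground-truth label, and a
#' free-form metadata list (true delay-onset fraction, concentration,
#' replicate, noisy-delay flag, ...).
#'
#' @slot eventId character scalar identifier.
#' @slot samples numeric current samples in pA (length >= 64).
#' @slot samplingRate positive sampling rate in Hz.
#' @slot label one of \code{"delayed"}, \code{"non_delayed"}, \code{"unknown"}.
#' @slot meta named list; for \code{label == "delayed"} it carries the true
#'   onset fraction in \code{meta$onset_frac}.
#'
#' @seealso [eventTrace()], [generateEvent()]
#' @exportClass EventTrace
setClass("EventTrace",
  representation(
    eventId = "character",
    samples = "numeric",
    samplingRate = "numeric",
    label = "character",
    meta = "list"
  ),
  prototype(eventId = "event", samplingRate = 5000,
            label = "unknown", meta = list())
)

setValidity("EventTrace", function(object) {
  msg <- character()
  if (length(object@eventId) != 1L) msg <- c(msg, "eventId must be a scalar")
  if (length(object@samples) < 64L) msg <- c(msg, "samples must have length >= 64")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (!object@label %in% c("delayed", "non_delayed", "unknown"))
    msg <- c(msg, "label must be delayed, non_delayed or unknown")
  if (object@label == "delayed") {
    of <- object@meta$onset_frac
    if (is.null(of) || !is.numeric(of) || of < 0 || of > 1)
      msg <- c(msg, "delayed events must carry meta$onset_frac in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Binned standard-deviation profile of an event
#'
#' Per-bin sample standard deviations of a min-max-normalized trace, the
#' feature underlying the MSD delay rule. Bins are contiguous, near-equal,
#' half-open sample-index intervals partitioning the event.
#'
#' @slot sigmaBins numeric vector of per-bin standard deviations
#'   (normalized-signal units), length \code{nBins}.
#' @slot binStarts,binEnds 0-based half-open bin boundaries.
#' @slot nBins number of bins.
#' @seealso [msdProfile()]
#' @exportClass MsdProfile
setClass("MsdProfile",
  representation(sigmaBins = "numeric", binStarts = "integer",
                 binEnds = "integer", nBins = "integer"))

setValidity("MsdProfile", function(object) {
  msg <- character()
  n <- object@nBins
  if (length(object@sigmaBins) != n || length(object@binStarts) != n ||
      length(object@binEnds) != n)
    msg <- c(msg, "sigmaBins/binStarts/binEnds must all have length nBins")
  if (any(object@sigmaBins < 0)) msg <- c(msg, "sigmaBins must be >= 0")
  if (n > 1L && !all(object@binStarts[-1] == object@binEnds[-n]))
    msg <- c(msg, "bins must partition the event without overlap")
  if (length(msg)) msg else TRUE
})

#' Spectrogram settings for instantaneous spectral entropy
#'
#' @slot windowLen frame length in samples (default 128).
#' @slot overlapFrac frame overlap fraction in [0,1) (default 0.5).
#' @slot fftLen FFT length, at least \code{windowLen} (default = windowLen).
#' @slot windowShape taper identifier; \code{"hamming"} (default) or
#'   \code{"rectangular"}.
#' @seealso [instantaneousSE()]
#' @exportClass SpectrogramSpec
setClass("SpectrogramSpec",
  representation(windowLen = "integer", overlapFrac = "numeric",
                 fftLen = "integer", windowShape = "character"),
  prototype(windowLen = 128L, overlapFrac = 0.5, fftLen = 128L,
            windowShape = "hamming"))

setValidity("SpectrogramSpec", function(object) {
  msg <- character()
  if (object@windowLen < 4L) msg <- c(msg, "windowLen must be >= 4")
  if (object@overlapFrac < 0 || object@overlapFrac >= 1)
    msg <- c(msg, "overlapFrac must lie in [0, 1)")
  if (object@fftLen < object@windowLen)
    msg <- c(msg, "fftLen must be >= windowLen")
  if (floor(object@windowLen * (1 - object@overlapFrac)) < 1)
    msg <- c(msg, "hop = windowLen * (1 - overlapFrac) must be >= 1")
  if (!object@windowShape %in% c("hamming", "rectangular"))
    msg <- c(msg, "windowShape must be 'hamming' or 'rectangular'")
  if (length(msg)) msg else TRUE
})

#' Instantaneous spectral-entropy trace
#'
#' One normalized spectral-entropy value per spectrogram frame, each tagged
#' with its frame-center sample index and fractional position.
#'
#' @slot seValues numeric vector in [0,1].
#' @slot frameCenters 0-based frame-center sample indices.
#' @slot frameFracs fractional positions (center / event length) in [0,1].
#' @seealso [instantaneousSE()]
#' @exportClass SeTrace
setClass("SeTrace",
  representation(seValues = "numeric", frameCenters = "numeric",
                 frameFracs = "numeric"))

setValidity("SeTrace", function(object) {
  msg <- character()
  if (any(object@seValues < -1e-12) || any(object@seValues > 1 + 1e-12))
    msg <- c(msg, "all spectral-entropy values must lie in [0, 1]")
  if (length(object@seValues) != length(object@frameCenters) ||
      length(object@seValues) != length(object@frameFracs))
    msg <- c(msg, "seValues, frameCenters, frameFracs must be parallel")
  if (length(msg)) msg else TRUE
})

#' Grayscale rendering of an event trace
#'
#' @slot pixels numeric \code{resolution x resolution} matrix of intensities
#'   in [0,1]; the trace line is high-valued on a zero background.
#' @slot resolution image side length in pixels.
#' @slot eventId identifier of the source event.
#' @seealso [renderImage()]
#' @exportClass TraceImage
setClass("TraceImage",
  representation(pixels = "matrix", resolution = "integer",
                 eventId = "character"))

setValidity("TraceImage", function(object) {
  msg <- character()
  if (nrow(object@pixels) != object@resolution ||
      ncol(object@pixels) != object@resolution)
    msg <- c(msg, "pixels must be a square resolution x resolution matrix")
  if (any(object@pixels < 0) || any(object@pixels > 1))
    msg <- c(msg, "pixel intensities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Trained convolutional classifier handle
#'
#' Holds the architecture description, trained parameters, per-epoch
#' training history, and the image-normalization constants computed from the
#' training set (reused verbatim at prediction and Grad-CAM time).
#'
#' @slot spec named list: \code{convFilters} (integer pair), \code{kernelSize},
#'   \code{poolSize}, \code{fcUnits}, \code{nClasses}, \code{inputResolution}.
#' @slot weights named list of parameter arrays.
#' @slot history data.frame with one row per epoch (losses, accuracies).
#' @slot normMean,normSd image normalization constants from training.
#' @slot trained logical.
#' @seealso [cnnTrain()], [cnnPredict()], [gradCam()]
#' @exportClass CnnModel
setClass("CnnModel",
  representation(spec = "list", weights = "list", history = "data.frame",
                 normMean = "numeric", normSd = "numeric",
                 trained = "logical"),
  prototype(trained = FALSE, normMean = 0, normSd = 1))

#' Hill-equation dose-response fit
#'
#' Unweighted nonlinear least-squares fit of
#' \eqn{response(C) = V_{max} C^{n_h} / (K_e^{n_h} + C^{n_h})}
#' to baseline-corrected percent-delayed responses. \code{ke} is the
#' half-maximal concentration (EC50).
#'
#' @slot nh Hill coefficient (cooperativity).
#' @slot ke EC50 in nM.
#' @slot vmax maximal response in percentage points.
#' @slot r2 coefficient of determination (1 - SSres/SStot).
#' @slot stderr named numeric vector of parameter standard errors.
#' @slot data data.frame of the points actually fitted (conc_nM, response).
#' @seealso [fitHill()]
#' @exportClass HillFit
setClass("HillFit",
  representation(nh = "numeric", ke = "numeric", vmax = "numeric",
                 r2 = "numeric", stderr = "numeric", data = "data.frame"))

setValidity("HillFit", function(object) {
  msg <- character()
  if (object@nh <= 0 || object@ke <= 0)
    msg <- c(msg, "nh and ke must be positive")
  if (!is.na(object@r2) && object@r2 > 1 + 1e-12)
    msg <- c(msg, "r2 cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' Concentration cohort specification
#'
#' Describes a dose-response experiment: per-concentration event counts,
#' replicates, and the generating Hill curve for the expected percentage of
#' delayed events, \eqn{p(C) = baseline + V_{max} C^{n_h}/(K_e^{n_h}+C^{n_h})}
#' (all in percent).
#'
#' @slot concentrations nonnegative concentrations in nM.
#' @slot nEventsPerConc events simulated per (concentration, replicate) cell.
#' @slot nReplicates number of replicates (default 3).
#' @slot hillNh,hillKe,hillVmax generating Hill parameters (Ke in nM,
#'   Vmax in percent).
#' @slot baselinePct delayed percentage at 0 nM.
#' @seealso [cohortSpec()], [generateDoseResponse()]
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(concentrations = "numeric", nEventsPerConc = "integer",
                 nReplicates = "integer", hillNh = "numeric",
                 hillKe = "numeric", hillVmax = "numeric",
                 baselinePct = "numeric"),
  prototype(concentrations = c(0, 0.1, 0.5, 1, 2.5, 5, 10, 50, 100),
            nEventsPerConc = 200L, nReplicates = 3L,
            hillNh = 2.25, hillKe = 1.19, hillVmax = 36.59,
            baselinePct = 2))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be nonnegative")
  if (object@nEventsPerConc < 1L) msg <- c(msg, "nEventsPerConc must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@hillNh <= 0 || object@hillKe <= 0)
    msg <- c(msg, "hillNh and hillKe must be positive")
  if (object@hillVmax <= 0 || object@hillVmax > 100)
    msg <- c(msg, "hillVmax must lie in (0, 100]")
  if (object@baselinePct < 0) msg <- c(msg, "baselinePct must be nonnegative")
  pmax <- object@baselinePct + object@hillVmax
  if (pmax > 100)
    msg <- c(msg, "expected delayed fraction exceeds 100% at saturation")
  if (length(msg)) msg else TRUE
})

#' MSD rule parameters
#'
#' Defaults are the shipped operating point of the moving-standard-deviation
#' classifier: normalized-sd threshold 0.003, 75 bins, a strict run of more
#' than 10 consecutive quiet bins, and a delay fractional position of 0.7.
#'
#' @slot sigmaThreshold per-bin sd threshold on the normalized trace.
#' @slot totalBins number of bins the event is partitioned into.
#' @slot minRunBins minimum run length; a delay needs strictly more than
#'   this many consecutive below-threshold bins.
#' @slot fracPosition delay region gate in [0,1]; the qualifying run must
#'   start at or beyond this fractional position (see \code{overlapOk}).
#' @slot overlapOk if TRUE the run may straddle the boundary (it only needs
#'   to overlap the region); default FALSE (start-after semantics).
#' @seealso [classifyMsd()]
#' @exportClass MsdParams
setClass("MsdParams",
  representation(sigmaThreshold = "numeric", totalBins = "integer",
                 minRunBins = "integer", fracPosition = "numeric",
                 overlapOk = "logical"),
  prototype(sigmaThreshold = 0.003, totalBins = 75L, minRunBins = 10L,
            fracPosition = 0.7, overlapOk = FALSE))

setValidity("MsdParams", function(object) {
  msg <- character()
  if (object@sigmaThreshold <= 0) msg <- c(msg, "sigmaThreshold must be > 0")
  if (object@minRunBins > object@totalBins)
    msg <- c(msg, "minRunBins must be <= totalBins")
  if (object@fracPosition < 0 || object@fracPosition > 1)
    msg <- c(msg, "fracPosition must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Spectral-entropy rule parameters
#'
#' @slot seThreshold instantaneous-SE threshold in (0,1) (default 0.495);
#'   frames below it in the delay region mark the event delayed.
#' @slot fracPosition delay region gate (default 0.7); only frames with
#'   fractional position strictly greater are inspected.
#' @slot spec a [SpectrogramSpec-class] describing the frames.
#' @seealso [classifySe()]
#' @exportClass SeParams
setClass("SeParams",
  representation(seThreshold = "numeric", fracPosition = "numeric",
                 spec = "SpectrogramSpec"),
  prototype(seThreshold = 0.495, fracPosition = 0.7,
            spec = new("SpectrogramSpec")))

setValidity("SeParams", function(object) {
  msg <- character()
  if (object@seThreshold < 0 || object@seThreshold >= 1)
    msg <- c(msg, "seThreshold must lie in [0, 1)")
  if (object@fracPosition < 0 || object@fracPosition > 1)
    msg <- c(msg, "fracPosition must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Local-alignment scoring scheme
#'
#' @slot match match reward (default +5).
#' @slot mismatch mismatch penalty (default -4).
#' @slot gap linear per-position gap penalty (default -8).
#' @seealso [localAlign()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(match = "integer", mismatch = "integer", gap = "integer"),
  prototype(match = 5L, mismatch = -4L, gap = -8L))

setValidity("ScoringScheme", function(object) {
  if (object@match > 0 && object@mismatch < 0 && object@gap < 0) TRUE
  else "require match > 0 > mismatch, gap"
})
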