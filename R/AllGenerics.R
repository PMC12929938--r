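# Generics, constructors, accessors and show methods.

#' Construct a simulator configuration
#'
#' @param samplingRate sampling rate in Hz.
#' @param baseLevel mean blockade level in pA.
#' @param bandLow,bandHigh clipping band in pA.
#' @param eventLenRange integer pair of event lengths (samples).
#' @param stepBlockLenRange integer pair of per-step block lengths (samples).
#' @param stepAmpSd between-block level spread (pA).
#' @param noiseSd within-block broadband noise sd (pA).
#' @param delayOnsetFracRange pair in [0,1], delay-onset fraction range.
#' @param delayLenFracRange pair in (0,1], delay-length fraction range.
#' @param delayNoiseSd marginal sd of the delay-plateau wander (pA).
#' @param noisyDelayProb probability a delayed event is a noisy-delay
#'   contaminant.
#' @param noisyDelayBurstSd burst noise sd of the contaminant (pA).
#' @param seed integer seed stored with the configuration.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig()
#' cfg
#' @export
simConfig <- function(samplingRate = 5000, baseLevel = 450,
                      bandLow = 200, bandHigh = 700,
                      eventLenRange = c(1500L, 4000L),
                      stepBlockLenRange = c(150L, 400L),
                      stepAmpSd = 20, noiseSd = 12,
                      delayOnsetFracRange = c(0.70, 0.80),
                      delayLenFracRange = c(0.17, 0.25),
                      delayNoiseSd = 1, noisyDelayProb = 0,
                      noisyDelayBurstSd = 12, seed = 1L) {
  new("SimConfig", samplingRate = samplingRate, baseLevel = baseLevel,
      bandLow = bandLow, bandHigh = bandHigh,
      eventLenRange = as.integer(eventLenRange),
      stepBlockLenRange = as.integer(stepBlockLenRange),
      stepAmpSd = stepAmpSd, noiseSd = noiseSd,
      delayOnsetFracRange = delayOnsetFracRange,
      delayLenFracRange = delayLenFracRange,
      delayNoiseSd = delayNoiseSd, noisyDelayProb = noisyDelayProb,
      noisyDelayBurstSd = noisyDelayBurstSd, seed = as.integer(seed))
}

#' Construct an event trace
#'
#' @param samples numeric current samples in pA.
#' @param eventId identifier.
#' @param samplingRate sampling rate in Hz.
#' @param label one of "delayed", "non_delayed", "unknown".
#' @param meta named metadata list.
#' @return an [EventTrace-class] object.
#' @examples
#' ev <- eventTrace(450 + rnorm(2000, sd = 12))
#' ev
#' @export
eventTrace <- function(samples, eventId = "event", samplingRate = 5000,
                       label = "unknown", meta = list()) {
  new("EventTrace", eventId = as.character(eventId),
      samples = as.numeric(samples), samplingRate = samplingRate,
      label = label, meta = meta)
}

#' Construct a cohort specification
#'
#' @param concentrations concentrations in nM (must include 0 for
#'   baseline correction downstream).
#' @param nEventsPerConc events per (concentration, replicate) cell.
#' @param nReplicates replicates per concentration.
#' @param hillNh,hillKe,hillVmax generating Hill parameters.
#' @param baselinePct delayed percentage at 0 nM.
#' @return a [CohortSpec-class] object.
#' @export
cohortSpec <- function(concentrations = c(0, 0.1, 0.5, 1, 2.5, 5, 10, 50, 100),
                       nEventsPerConc = 200L, nReplicates = 3L,
                       hillNh = 2.25, hillKe = 1.19, hillVmax = 36.59,
                       baselinePct = 2) {
  new("CohortSpec", concentrations = concentrations,
      nEventsPerConc = as.integer(nEventsPerConc),
      nReplicates = as.integer(nReplicates),
      hillNh = hillNh, hillKe = hillKe, hillVmax = hillVmax,
      baselinePct = baselinePct)
}

#' @rdname SpectrogramSpec-class
#' @param windowLen,overlapFrac,fftLen,windowShape see slots.
#' @return a [SpectrogramSpec-class] object.
#' @export
spectrogramSpec <- function(windowLen = 128L, overlapFrac = 0.5,
                            fftLen = windowLen, windowShape = "hamming") {
  new("SpectrogramSpec", windowLen = as.integer(windowLen),
      overlapFrac = overlapFrac, fftLen = as.integer(fftLen),
      windowShape = windowShape)
}

#' @rdname MsdParams-class
#' @param sigmaThreshold,totalBins,minRunBins,fracPosition,overlapOk see slots.
#' @return an [MsdParams-class] object.
#' @export
msdParams <- function(sigmaThreshold = 0.003, totalBins = 75L,
                      minRunBins = 10L, fracPosition = 0.7,
                      overlapOk = FALSE) {
  new("MsdParams", sigmaThreshold = sigmaThreshold,
      totalBins = as.integer(totalBins), minRunBins = as.integer(minRunBins),
      fracPosition = fracPosition, overlapOk = overlapOk)
}

#' @rdname SeParams-class
#' @param seThreshold,fracPosition see slots.
#' @param spec a [SpectrogramSpec-class].
#' @return an [SeParams-class] object.
#' @export
seParams <- function(seThreshold = 0.495, fracPosition = 0.7,
                     spec = spectrogramSpec()) {
  new("SeParams", seThreshold = seThreshold, fracPosition = fracPosition,
      spec = spec)
}

#' @rdname ScoringScheme-class
#' @param match,mismatch,gap integer scores.
#' @return a [ScoringScheme-class] object.
#' @export
scoringScheme <- function(match = 5L, mismatch = -4L, gap = -8L) {
  new("ScoringScheme", match = as.integer(match),
      mismatch = as.integer(mismatch), gap = as.integer(gap))
}

# ---- accessors -------------------------------------------------------------

#' @title Accessors for event traces and derived objects
#' @description Small accessor generics: slot access is internal to the
#'   package; user code should go through these.
#' @param object an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eventId", function(object) standardGeneric("eventId"))
#' @rdname accessors
#' @export
setMethod("eventId", "EventTrace", function(object) object@eventId)
#' @rdname accessors
#' @export
setMethod("eventId", "TraceImage", function(object) object@eventId)

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))
#' @rdname accessors
#' @export
setMethod("traceSamples", "EventTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "EventTrace", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("eventLabel", function(object) standardGeneric("eventLabel"))
#' @rdname accessors
#' @export
setMethod("eventLabel", "EventTrace", function(object) object@label)

#' @rdname accessors
#' @export
setGeneric("eventMeta", function(object) standardGeneric("eventMeta"))
#' @rdname accessors
#' @export
setMethod("eventMeta", "EventTrace", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("sigmaBins", function(object) standardGeneric("sigmaBins"))
#' @rdname accessors
#' @export
setMethod("sigmaBins", "MsdProfile", function(object) object@sigmaBins)

#' @rdname accessors
#' @export
setGeneric("binBounds", function(object) standardGeneric("binBounds"))
#' @rdname accessors
#' @export
setMethod("binBounds", "MsdProfile", function(object)
  data.frame(start = object@binStarts, end = object@binEnds))

#' @rdname accessors
#' @export
setGeneric("seValues", function(object) standardGeneric("seValues"))
#' @rdname accessors
#' @export
setMethod("seValues", "SeTrace", function(object) object@seValues)

#' @rdname accessors
#' @export
setGeneric("frameFracs", function(object) standardGeneric("frameFracs"))
#' @rdname accessors
#' @export
setMethod("frameFracs", "SeTrace", function(object) object@frameFracs)

#' @rdname accessors
#' @export
setGeneric("imagePixels", function(object) standardGeneric("imagePixels"))
#' @rdname accessors
#' @export
setMethod("imagePixels", "TraceImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("imageResolution", function(object) standardGeneric("imageResolution"))
#' @rdname accessors
#' @export
setMethod("imageResolution", "TraceImage", function(object) object@resolution)

#' @rdname accessors
#' @export
setGeneric("modelSpec", function(object) standardGeneric("modelSpec"))
#' @rdname accessors
#' @export
setMethod("modelSpec", "CnnModel", function(object) object@spec)

#' @rdname accessors
#' @export
setGeneric("trainHistory", function(object) standardGeneric("trainHistory"))
#' @rdname accessors
#' @export
setMethod("trainHistory", "CnnModel", function(object) object@history)

#' @rdname accessors
#' @export
setGeneric("normConstants", function(object) standardGeneric("normConstants"))
#' @rdname accessors
#' @export
setMethod("normConstants", "CnnModel", function(object)
  c(mean = object@normMean, sd = object@normSd))

#' @rdname accessors
#' @export
setGeneric("hillCoefficients", function(object)
  standardGeneric("hillCoefficients"))
#' @rdname accessors
#' @export
setMethod("hillCoefficients", "HillFit", function(object)
  c(nh = object@nh, ke = object@ke, vmax = object@vmax, r2 = object@r2))

# ---- show methods ----------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@samplingRate, "Hz, band [",
      object@bandLow, ",", object@bandHigh, "] pA, base",
      object@baseLevel, "pA\n")
  cat("  event length", object@eventLenRange[1], "-",
      object@eventLenRange[2], "samples; noise sd", object@noiseSd,
      "pA; delay wander sd", object@delayNoiseSd, "pA\n")
  cat("  delay onset frac [", object@delayOnsetFracRange[1], ",",
      object@delayOnsetFracRange[2], "], length frac [",
      object@delayLenFracRange[1], ",", object@delayLenFracRange[2],
      "], noisy-delay prob", object@noisyDelayProb, "\n")
})

setMethod("show", "EventTrace", function(object) {
  cat("EventTrace", object@eventId, ":", length(object@samples),
      "samples @", object@samplingRate, "Hz, label =", object@label, "\n")
  s <- object@samples
  cat(sprintf("  current range [%.1f, %.1f] pA\n", min(s), max(s)))
})

setMethod("show", "MsdProfile", function(object) {
  cat("MsdProfile:", object@nBins, "bins, sigma in [",
      sprintf("%.3g", min(object@sigmaBins)), ",",
      sprintf("%.3g", max(object@sigmaBins)), "]\n")
})

setMethod("show", "SeTrace", function(object) {
  cat("SeTrace:", length(object@seValues), "frames, SE in [",
      sprintf("%.3f", min(object@seValues)), ",",
      sprintf("%.3f", max(object@seValues)), "]\n")
})

setMethod("show", "TraceImage", function(object) {
  cat("TraceImage", object@eventId, ":", object@resolution, "x",
      object@resolution, "px\n")
})

setMethod("show", "CnnModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "CnnModel: conv(%d)->pool->conv(%d)->pool->fc(%d)->fc(%d), input %dx%d\n",
    s$convFilters[1], s$convFilters[2], s$fcUnits, s$nClasses,
    s$inputResolution, s$inputResolution))
  if (object@trained) {
    h <- object@history
    cat(sprintf("  trained %d epochs; final val accuracy %.3f\n",
                nrow(h), h$val_accuracy[nrow(h)]))
  } else cat("  untrained\n")
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf(
    "HillFit: nh = %.3f, Ke = %.3f nM, Vmax = %.2f%%, R^2 = %.4f\n",
    object@nh, object@ke, object@vmax, object@r2))
})
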