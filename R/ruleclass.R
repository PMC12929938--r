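# Threshold-based delay classifiers (MSD and SE), calibration sweeps, and
# the dynamic-range criterion.

.emptyCall <- function(eventId, method) {
  data.frame(event_id = eventId, method = method, label = NA_character_,
             score = NA_real_, delay_start_frac = NA_real_,
             run_length = NA_integer_, indeterminate = TRUE,
             stringsAsFactors = FALSE)
}

# Runs of TRUE in a logical vector: data.frame(start, length), 1-based.
.runsOf <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

#' Classify one event with the moving-standard-deviation rule
#'
#' Normalizes the trace, bins it into \code{totalBins} bins, and calls the
#' event delayed when more than \code{minRunBins} consecutive bins inside
#' the delay region (bins whose start lies at fractional position
#' \code{fracPosition} or beyond) have standard deviation strictly below
#' \code{sigmaThreshold}. With \code{overlapOk = TRUE} a quiet run that
#' straddles the region boundary qualifies by its total length instead.
#' The continuous score is the minimum bin sd inside the region (lower =
#' stronger delay evidence), usable for ROC analysis.
#'
#' @param trace an [EventTrace-class].
#' @param p an [MsdParams-class] (defaults: threshold 0.003, 75 bins,
#'   run > 10 bins, region >= 0.7).
#' @return one-row data.frame: event_id, method, label, score,
#'   delay_start_frac, run_length, indeterminate.
#' @examples
#' ev <- generateEvent(simConfig(), "delayed", seed = 3)
#' classifyMsd(ev)
#' @export
classifyMsd <- function(trace, p = msdParams()) {
  validObject(p)
  x <- normalizeTrace(trace)
  prof <- msdProfile(x, p@totalBins)
  n <- length(x)
  startFracs <- prof@binStarts / n
  below <- prof@sigmaBins < p@sigmaThreshold
  inRegion <- startFracs >= p@fracPosition
  score <- min(prof@sigmaBins[inRegion])

  if (p@overlapOk) {
    runs <- .runsOf(below)
    runs <- runs[runs$length > p@minRunBins &
                   (runs$start + runs$length - 1L) >= which(inRegion)[1], ,
                 drop = FALSE]
  } else {
    # runs are counted inside the region only
    regionBelow <- below & inRegion
    runs <- .runsOf(regionBelow)
    runs <- runs[runs$length > p@minRunBins, , drop = FALSE]
  }

  if (nrow(runs) > 0L) {
    run <- runs[1L, ]
    data.frame(event_id = eventId(trace), method = "msd", label = "delayed",
               score = score,
               delay_start_frac = prof@binStarts[run$start] / n,
               run_length = run$length, indeterminate = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(event_id = eventId(trace), method = "msd",
               label = "non_delayed", score = score,
               delay_start_frac = NA_real_, run_length = NA_integer_,
               indeterminate = FALSE, stringsAsFactors = FALSE)
  }
}

#' Classify one event with the spectral-entropy rule
#'
#' Computes the instantaneous spectral entropy and calls the event delayed
#' when any frame whose fractional position exceeds \code{fracPosition}
#' drops strictly below \code{seThreshold}. The score is the minimum SE
#' over that region. Events too short to place a frame beyond the region
#' boundary raise an indeterminate-event error (use
#' [classifyEvents()] to collect such events with a flag instead).
#'
#' @param trace an [EventTrace-class].
#' @param p an [SeParams-class] (defaults: threshold 0.495, region > 0.7,
#'   128-sample Hamming frames at 50\% overlap).
#' @return one-row data.frame as in [classifyMsd()].
#' @export
classifySe <- function(trace, p = seParams()) {
  validObject(p)
  se <- instantaneousSE(trace, p@spec)
  region <- se@frameFracs > p@fracPosition
  if (!any(region))
    stop(structure(
      class = c("poreDelay_indeterminate", "error", "condition"),
      list(message = sprintf(
             "event %s has no spectrogram frame beyond fractional position %g",
             eventId(trace), p@fracPosition),
           call = sys.call(-1))))
  vals <- se@seValues[region]
  below <- vals < p@seThreshold
  score <- min(vals)
  if (any(below)) {
    runs <- .runsOf(below)
    data.frame(event_id = eventId(trace), method = "se", label = "delayed",
               score = score,
               delay_start_frac = se@frameFracs[region][which(below)[1]],
               run_length = max(runs$length), indeterminate = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(event_id = eventId(trace), method = "se",
               label = "non_delayed", score = score,
               delay_start_frac = NA_real_, run_length = NA_integer_,
               indeterminate = FALSE, stringsAsFactors = FALSE)
  }
}

#' Classify a list of events
#'
#' Applies [classifyMsd()] or [classifySe()] to every event; events the SE
#' rule cannot judge (too short for a frame beyond the region) are reported
#' with \code{indeterminate = TRUE} rather than silently non-delayed.
#'
#' @param events list of [EventTrace-class] objects.
#' @param method \code{"msd"} or \code{"se"}.
#' @param p parameter object matching the method.
#' @return data.frame with one row per event.
#' @export
classifyEvents <- function(events, method = c("msd", "se"),
                           p = NULL) {
  method <- match.arg(method)
  if (is.null(p)) p <- if (method == "msd") msdParams() else seParams()
  rows <- lapply(events, function(ev) {
    if (method == "msd") classifyMsd(ev, p)
    else tryCatch(classifySe(ev, p), poreDelay_indeterminate = function(e)
      .emptyCall(eventId(ev), "se"))
  })
  do.call(rbind, rows)
}

#' Threshold sweep of a rule classifier
#'
#' Re-runs the chosen rule across a grid of thresholds and reports the
#' percentage of events called delayed per threshold and per group (for
#' example, per concentration). Because lowering the bar for "quiet" only
#' ever adds bins or frames below it, the percentage is nondecreasing in
#' the threshold for both methods. Feature profiles are computed once per
#' event and reused across thresholds.
#'
#' @param events list of [EventTrace-class] objects.
#' @param groups grouping vector parallel to \code{events}.
#' @param method \code{"msd"} or \code{"se"}.
#' @param thresholds numeric vector of thresholds to evaluate.
#' @param p parameter object of the method (its threshold slot is ignored).
#' @return data.frame with columns group, threshold, pct_delayed, n.
#' @export
sweepThreshold <- function(events, groups, method = c("msd", "se"),
                           thresholds, p = NULL) {
  method <- match.arg(method)
  if (is.null(p)) p <- if (method == "msd") msdParams() else seParams()
  stopifnot(length(events) == length(groups))
  keep <- !is.na(groups)
  grouped <- split(seq_along(events)[keep], groups[keep])
  empty <- lengths(grouped) == 0L
  if (any(empty)) {
    warning("excluding empty group(s): ",
            paste(names(grouped)[empty], collapse = ", "))
    grouped <- grouped[!empty]
  }

  # cache per-event features
  feats <- lapply(events, function(ev) {
    if (method == "msd") {
      x <- normalizeTrace(ev)
      prof <- msdProfile(x, p@totalBins)
      list(values = prof@sigmaBins,
           inRegion = prof@binStarts / length(x) >= p@fracPosition)
    } else {
      se <- tryCatch(instantaneousSE(ev, p@spec), error = function(e) NULL)
      if (is.null(se)) return(NULL)
      list(values = se@seValues, inRegion = se@frameFracs > p@fracPosition)
    }
  })

  delayedAt <- function(f, thr) {
    if (is.null(f) || !any(f$inRegion)) return(NA)
    below <- f$values < thr & f$inRegion
    if (method == "msd") {
      runs <- .runsOf(below)
      nrow(runs[runs$length > p@minRunBins, , drop = FALSE]) > 0L
    } else any(below)
  }

  out <- expand.grid(group = names(grouped), threshold = thresholds,
                     stringsAsFactors = FALSE)
  out$pct_delayed <- NA_real_
  out$n <- NA_integer_
  for (r in seq_len(nrow(out))) {
    idx <- grouped[[out$group[r]]]
    calls <- vapply(feats[idx], delayedAt, logical(1), thr = out$threshold[r])
    out$pct_delayed[r] <- 100 * mean(calls, na.rm = TRUE)
    out$n[r] <- sum(!is.na(calls))
  }
  out[order(out$group, out$threshold), , drop = FALSE]
}

#' Dynamic range of a threshold sweep
#'
#' The difference in delayed percentage between a high-target and a
#' zero-target group per threshold - the criterion used to select the
#' operating window of the rule classifiers (the threshold range where the
#' separation between target-containing and control samples plateaus).
#'
#' @param sweep output of [sweepThreshold()].
#' @param highGroup,lowGroup group labels to difference (high - low).
#' @return data.frame with columns threshold, dynamic_range.
#' @export
dynamicRange <- function(sweep, highGroup, lowGroup) {
  hi <- sweep[sweep$group == highGroup, c("threshold", "pct_delayed")]
  lo <- sweep[sweep$group == lowGroup, c("threshold", "pct_delayed")]
  if (nrow(hi) == 0L) stop("missing group: ", highGroup)
  if (nrow(lo) == 0L) stop("missing group: ", lowGroup)
  m <- merge(hi, lo, by = "threshold", suffixes = c("_high", "_low"))
  data.frame(threshold = m$threshold,
             dynamic_range = m$pct_delayed_high - m$pct_delayed_low)
}
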