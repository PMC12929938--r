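# Confusion-matrix metrics, ROC/AUC, radar scaling, MAD gate, baseline
# correction, SEM summaries.

#' Confusion counts
#'
#' Tabulates a binary confusion matrix with the delayed class as positive.
#'
#' @param labels,predictions equal-length vectors of "delayed" /
#'   "non_delayed" (or logicals, TRUE = delayed).
#' @return named integer vector with elements tp, fp, fn, tn.
#' @examples
#' confusionCounts(c("delayed", "non_delayed"), c("delayed", "delayed"))
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  toPos <- function(v) {
    if (is.logical(v)) return(v)
    v == "delayed"
  }
  y <- toPos(labels)
  p <- toPos(predictions)
  c(tp = sum(y & p), fp = sum(!y & p), fn = sum(y & !p), tn = sum(!y & !p))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F1 (harmonic mean of precision and
#' recall), Matthews correlation coefficient
#' \eqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},
#' and (when scores are supplied) the ROC AUC. Metrics with a zero
#' denominator are reported as NA and listed in the \code{undefined}
#' attribute, never silently coerced to 0.
#'
#' @param counts output of [confusionCounts()] (or any named vector with
#'   tp, fp, fn, tn).
#' @param scores optional per-event scores oriented so that higher = more
#'   likely delayed; required for AUC.
#' @param labels labels parallel to \code{scores} (required with scores).
#' @return one-row data.frame: accuracy, precision, recall, f1, mcc, auc;
#'   attribute \code{undefined} names the NA metrics.
#' @examples
#' computeMetrics(c(tp = 470, fp = 30, fn = 530, tn = 970))
#' @export
computeMetrics <- function(counts, scores = NULL, labels = NULL) {
  tp <- as.numeric(counts[["tp"]])
  fp <- as.numeric(counts[["fp"]])
  fn <- as.numeric(counts[["fn"]])
  tn <- as.numeric(counts[["tn"]])
  tot <- tp + fp + fn + tn
  if (tot <= 0) stop("empty confusion matrix")
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (tp + tn) / tot
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- if (!is.na(precision) && !is.na(recall)) {
    if (precision + recall == 0) {
      undefined <- c(undefined, "f1")
      NA_real_
    } else 2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1")
    NA_real_
  }
  mccDen <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mccDen == 0) {
    undefined <- c(undefined, "mcc")
    NA_real_
  } else (tp * tn - fp * fn) / mccDen
  auc <- if (!is.null(scores)) {
    if (is.null(labels)) stop("labels required alongside scores for AUC")
    rocAuc(scores, labels)
  } else NA_real_
  out <- data.frame(accuracy = accuracy, precision = precision,
                    recall = recall, f1 = f1, mcc = mcc, auc = auc)
  attr(out, "undefined") <- unique(undefined)
  out
}

#' ROC area under the curve
#'
#' Rank-based AUC (trapezoidal integration of the empirical ROC with
#' midrank tie handling), equal to the probability that a randomly drawn
#' positive outranks a randomly drawn negative. Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric scores, higher = more likely positive (delayed).
#' @param labels parallel labels ("delayed"/"non_delayed" or logical).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "delayed"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Min-max scaling across classifiers for radar plots
#'
#' Per metric (column), maps the minimum observed value across rows to 0
#' and the maximum to 1, preserving the within-metric ordering. Constant
#' columns have no defined scale and are returned as NA with a warning.
#'
#' @param metricTable data.frame with one row per classifier or resolution
#'   and numeric metric columns; non-numeric columns are carried through.
#' @return data.frame of the same shape with metrics scaled to [0, 1].
#' @export
minmaxRadar <- function(metricTable) {
  if (nrow(metricTable) < 2L)
    stop("min-max scaling needs at least two rows")
  out <- metricTable
  for (nm in names(out)) {
    v <- out[[nm]]
    if (!is.numeric(v)) next
    lo <- min(v, na.rm = TRUE)
    hi <- max(v, na.rm = TRUE)
    if (hi == lo) {
      warning("metric '", nm, "' is constant across rows; scale undefined")
      out[[nm]] <- rep(NA_real_, length(v))
    } else out[[nm]] <- (v - lo) / (hi - lo)
  }
  out
}

#' MAD outlier gate
#'
#' Excludes values deviating from the median by more than three times the
#' median absolute deviation (MAD, unscaled - no normal-consistency
#' factor). When the MAD is zero, only values equal to the median are kept
#' and a warning is raised.
#'
#' @param values numeric vector (length >= 1).
#' @param k multiple of the MAD beyond which values are excluded
#'   (default 3).
#' @return list with \code{kept} (values retained) and \code{excluded}
#'   (integer indices of removed values).
#' @examples
#' madFilter(c(10, 10, 10, 50))  # MAD = 0: 50 excluded
#' @export
madFilter <- function(values, k = 3) {
  stopifnot(length(values) >= 1L)
  med <- median(values)
  m <- mad(values, constant = 1)
  if (m == 0) {
    out <- values != med
    if (any(out))
      warning("MAD is zero; excluding all values different from the median")
  } else {
    out <- abs(values - med) > k * m
  }
  list(kept = values[!out], excluded = which(out))
}

#' Baseline-correct a dose table
#'
#' Subtracts, per replicate, that replicate's 0 nM percent-delayed value
#' from all of its rows, expressing every response relative to the control
#' baseline; corrected 0 nM rows are exactly 0.
#'
#' @param table data.frame with columns conc_nM, replicate, pct_delay.
#' @return the table with an added \code{corrected} column.
#' @export
baselineCorrect <- function(table) {
  stopifnot(all(c("conc_nM", "replicate", "pct_delay") %in% names(table)))
  out <- table
  out$corrected <- NA_real_
  for (r in unique(table$replicate)) {
    sel <- table$replicate == r
    zero <- table$pct_delay[sel & table$conc_nM == 0]
    if (length(zero) == 0L)
      stop("no 0 nM row for replicate ", r)
    out$corrected[sel] <- table$pct_delay[sel] - zero[1]
  }
  out
}

#' Per-concentration mean and SEM
#'
#' @param table data.frame with columns conc_nM and a value column.
#' @param value name of the value column (default "pct_delay").
#' @return data.frame: conc_nM, n, mean, sem (sd/sqrt(n), N-1 denominator;
#'   NA with a flag column \code{sem_defined} when n = 1).
#' @export
summarizeDose <- function(table, value = "pct_delay") {
  stopifnot(value %in% names(table))
  concs <- sort(unique(table$conc_nM))
  rows <- lapply(concs, function(cc) {
    v <- table[[value]][table$conc_nM == cc]
    n <- length(v)
    data.frame(conc_nM = cc, n = n, mean = mean(v),
               sem = if (n > 1L) sd(v) / sqrt(n) else NA_real_,
               sem_defined = n > 1L)
  })
  do.call(rbind, rows)
}

#' Fit the Hill equation to a dose-response table
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' \eqn{response(C) = V_{max} C^{n_h} / (K_e^{n_h} + C^{n_h})} to the
#' per-concentration means of MAD-filtered, baseline-corrected replicate
#' responses. Initialization: \eqn{V_{max}} at the maximum corrected
#' response, \eqn{K_e} at the concentration nearest half-max, \eqn{n_h} at
#' 1; all parameters bounded below by a small positive constant. Reports
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} and per-parameter standard errors.
#'
#' @param table data.frame with columns conc_nM, replicate, and either a
#'   \code{corrected} column or (with \code{correct = TRUE}) a raw
#'   \code{pct_delay} column to be baseline-corrected first.
#' @param correct baseline-correct the table first (default TRUE when no
#'   corrected column is present).
#' @param madK MAD multiple of the outlier gate (default 3).
#' @return a [HillFit-class].
#' @export
fitHill <- function(table, correct = is.null(table$corrected), madK = 3) {
  if (correct) table <- baselineCorrect(table)
  stopifnot("corrected" %in% names(table))
  concs <- sort(unique(table$conc_nM))
  if (length(concs) < 4L || !0 %in% concs)
    stop("need at least 4 distinct concentrations including 0 nM")
  pts <- lapply(concs, function(cc) {
    v <- table$corrected[table$conc_nM == cc]
    kept <- madFilter(v, k = madK)$kept
    data.frame(conc_nM = cc, response = mean(kept))
  })
  pts <- do.call(rbind, pts)

  vmax0 <- max(pts$response)
  if (vmax0 <= 0) stop("no positive response to fit")
  ke0 <- pts$conc_nM[which.min(abs(pts$response - vmax0 / 2))]
  if (ke0 <= 0) ke0 <- min(pts$conc_nM[pts$conc_nM > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ vmax * conc_nM^nh / (ke^nh + conc_nM^nh),
      data = pts, start = list(vmax = vmax0, ke = ke0, nh = 1),
      lower = c(vmax = 1e-9, ke = 1e-9, nh = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit did not converge: ",
                             conditionMessage(e)))
  co <- coef(fit)
  res <- pts$response - predict(fit)
  sstot <- sum((pts$response - mean(pts$response))^2)
  r2 <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3),
                                              c("vmax", "ke", "nh")))
  new("HillFit", nh = unname(co["nh"]), ke = unname(co["ke"]),
      vmax = unname(co["vmax"]), r2 = r2,
      stderr = c(nh = unname(se["nh"]), ke = unname(se["ke"]),
                 vmax = unname(se["vmax"])),
      data = pts)
}

#' Predicted Hill response
#'
#' @param fit a [HillFit-class].
#' @param conc concentrations in nM.
#' @return predicted baseline-corrected responses.
#' @export
hillResponse <- function(fit, conc) {
  fit@vmax * conc^fit@nh / (fit@ke^fit@nh + conc^fit@nh)
}
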