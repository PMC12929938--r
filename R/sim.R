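# Synthetic nanopore event simulator: delayed / non-delayed / noisy-delay
# traces, labeled datasets, concentration cohorts, barcode reads.

# Reference barcode embedded in generated reads (38-mer).
.BARCODE <- "GGGATCGCTACGCCTTCGGCTCGTAATCATAGTCGAGT"

#' Default reference barcode
#'
#' The 38-nt identifying barcode carried by the DNA probe; generated reads
#' embed it and the alignment filter anchors on its initial GGG motif.
#' @return character scalar.
#' @export
referenceBarcode <- function() .BARCODE

# Slow smooth wander used inside delay plateaus: integrated AR(1)
# innovations, rescaled to an exact marginal sd. A stalled probe-target
# duplex holds a quiet level that drifts slowly, so its power concentrates
# at low frequencies instead of the broadband noise of a translocating
# barcode - this is what both the MSD and SE rules key on.
.smoothWander <- function(len, sdTarget) {
  if (sdTarget <= 0 || len < 3L) return(rep(0, len))
  z <- as.numeric(filter(rnorm(len), 0.9, method = "recursive"))
  w <- cumsum(z)
  w <- w - mean(w)
  s <- sd(w)
  if (s == 0) return(rep(0, len))
  w * (sdTarget / s)
}

# Core trace builder; assumes the RNG state is already set by the caller.
.buildEvent <- function(cfg, cls) {
  n <- sample(cfg@eventLenRange[1]:cfg@eventLenRange[2], 1L)

  # open-pore flank at the event start pins the top of the current range
  flankLen <- sample(15:30, 1L)
  # short C3-spacer-like dip shortly after pins the bottom
  dipStart <- flankLen + sample(30:80, 1L)
  dipLen <- sample(30:60, 1L)

  # stepped barcode-level background
  level <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    blockLen <- sample(cfg@stepBlockLenRange[1]:cfg@stepBlockLenRange[2], 1L)
    end <- min(n, pos + blockLen - 1L)
    level[pos:end] <- cfg@baseLevel + rnorm(1L, 0, cfg@stepAmpSd)
    pos <- end + 1L
  }
  level[1:flankLen] <- cfg@bandHigh - 5
  level[dipStart:min(n, dipStart + dipLen - 1L)] <- cfg@bandLow + 5

  x <- level + rnorm(n, 0, cfg@noiseSd)
  meta <- list(noisy_delay = FALSE)

  if (cls == "delayed") {
    onsetFrac <- runif(1L, cfg@delayOnsetFracRange[1], cfg@delayOnsetFracRange[2])
    lenFrac <- runif(1L, cfg@delayLenFracRange[1], cfg@delayLenFracRange[2])
    start <- as.integer(round(onsetFrac * n))
    end <- min(as.integer(round((onsetFrac + lenFrac) * n)),
               as.integer(round(0.97 * n)), n)
    idx <- start:end
    plateau <- level[start]
    x[idx] <- plateau + .smoothWander(length(idx), cfg@delayNoiseSd)
    meta$onset_frac <- start / n
    meta$delay_len_frac <- length(idx) / n
    if (cfg@noisyDelayProb > 0 && runif(1L) < cfg@noisyDelayProb) {
      # broadband bursts spaced so no quiet stretch survives longer than
      # ~10 of 75 bins: this is the contaminant mode that defeats the MSD
      # run rule while the plateau level itself is unchanged
      L <- length(idx)
      nb <- max(2L, as.integer(ceiling(L / (0.10 * n))))
      centers <- start + as.integer(round((seq_len(nb) - 0.5) * L / nb)) +
        sample(-as.integer(0.01 * n):as.integer(0.01 * n), nb, replace = TRUE)
      halfw <- as.integer(round(0.012 * n))
      for (ct in centers) {
        b0 <- max(start, ct - halfw)
        b1 <- min(end, ct + halfw)
        if (b1 >= b0)
          x[b0:b1] <- x[b0:b1] + rnorm(b1 - b0 + 1L, 0, cfg@noisyDelayBurstSd)
      }
      meta$noisy_delay <- TRUE
    }
  }

  x <- pmin(pmax(x, cfg@bandLow), cfg@bandHigh)
  list(samples = x, meta = meta)
}

#' Generate one synthetic translocation event
#'
#' Emits a stepped, noisy current trace emulating a DNA-barcoded probe
#' translocation. A delayed event additionally carries one contiguous
#' low-variability plateau starting at a drawn onset fraction of at least
#' 0.7 (the stall of the probe-target duplex); a non-delayed event has the
#' stepped structure throughout. With probability \code{noisyDelayProb} a
#' delayed event becomes a "noisy delay" whose plateau receives broadband
#' noise bursts at an unchanged mean level. All samples are clipped to the
#' configured band; generation is deterministic for a fixed seed.
#'
#' @param cfg a [SimConfig-class].
#' @param cls \code{"delayed"} or \code{"non_delayed"}.
#' @param seed integer seed.
#' @param eventId identifier for the emitted event.
#' @return an [EventTrace-class].
#' @examples
#' ev <- generateEvent(simConfig(), "delayed", seed = 1)
#' ev
#' @export
generateEvent <- function(cfg, cls, seed, eventId = sprintf("%s_%d", cls, seed)) {
  validObject(cfg)
  if (!cls %in% c("delayed", "non_delayed"))
    stop("cls must be 'delayed' or 'non_delayed'")
  built <- withr::with_seed(as.integer(seed), .buildEvent(cfg, cls))
  eventTrace(built$samples, eventId = eventId,
             samplingRate = cfg@samplingRate, label = cls, meta = built$meta)
}

#' Generate a labeled event dataset
#'
#' Generates the requested number of delayed and non-delayed events and
#' shuffles them deterministically by seed. Event seeds are drawn from one
#' seeded stream, so the full dataset is reproducible.
#'
#' @param cfg a [SimConfig-class].
#' @param nDelayed,nNondelayed class counts (>= 0).
#' @param seed integer seed.
#' @param idPrefix prefix for generated event identifiers.
#' @return list of [EventTrace-class] objects, length
#'   \code{nDelayed + nNondelayed}, in shuffled order.
#' @export
generateDataset <- function(cfg, nDelayed, nNondelayed, seed,
                            idPrefix = "ev") {
  validObject(cfg)
  if (nDelayed < 0 || nNondelayed < 0) stop("counts must be >= 0")
  nTot <- nDelayed + nNondelayed
  if (nTot == 0L) return(list())
  plan <- withr::with_seed(as.integer(seed), {
    list(seeds = sample.int(.Machine$integer.max, nTot),
         perm = sample.int(nTot))
  })
  cls <- c(rep("delayed", nDelayed), rep("non_delayed", nNondelayed))
  events <- lapply(seq_len(nTot), function(i)
    generateEvent(cfg, cls[i], plan$seeds[i],
                  eventId = sprintf("%s_%05d", idPrefix, i)))
  events[plan$perm]
}

# Expected delayed percentage of the generating Hill curve.
.hillExpectedPct <- function(cohort, conc) {
  cohort@baselinePct +
    cohort@hillVmax * conc^cohort@hillNh /
      (cohort@hillKe^cohort@hillNh + conc^cohort@hillNh)
}

#' Generate a dose-response cohort
#'
#' For every (concentration, replicate) cell, draws each event's class as a
#' Bernoulli trial with the Hill-curve success probability
#' \eqn{p(C) = baseline + V_{max} C^{n_h}/(K_e^{n_h} + C^{n_h})} (percent),
#' then generates the events. Returns the events grouped by cell together
#' with a ground-truth table carrying realized and expected percentages.
#'
#' @param cohort a [CohortSpec-class].
#' @param cfg a [SimConfig-class].
#' @param seed integer seed.
#' @return list with \code{events} (named list of event lists, one per
#'   \code{conc<...>_rep<...>} cell) and \code{truth} (data.frame with
#'   columns conc_nM, replicate, n_events, n_delayed, expected_pct,
#'   realized_pct).
#' @export
generateDoseResponse <- function(cohort, cfg, seed) {
  validObject(cohort)
  validObject(cfg)
  cells <- expand.grid(conc = cohort@concentrations,
                       replicate = seq_len(cohort@nReplicates))
  cells <- cells[order(cells$conc, cells$replicate), , drop = FALSE]
  nCells <- nrow(cells)
  plan <- withr::with_seed(as.integer(seed),
                           matrix(sample.int(.Machine$integer.max,
                                             2L * nCells), nrow = 2L))
  events <- vector("list", nCells)
  truth <- vector("list", nCells)
  for (i in seq_len(nCells)) {
    conc <- cells$conc[i]
    rep_ <- cells$replicate[i]
    pct <- .hillExpectedPct(cohort, conc)
    if (pct > 100) stop("expected delayed fraction exceeds 100%")
    nEv <- cohort@nEventsPerConc
    nDel <- withr::with_seed(plan[1L, i], rbinom(1L, nEv, pct / 100))
    cellEvents <- generateDataset(
      cfg, nDel, nEv - nDel, seed = plan[2L, i],
      idPrefix = sprintf("c%g_r%d", conc, rep_))
    cellEvents <- lapply(cellEvents, function(ev) {
      ev@meta$conc_nM <- conc
      ev@meta$replicate <- rep_
      ev
    })
    events[[i]] <- cellEvents
    truth[[i]] <- data.frame(conc_nM = conc, replicate = rep_,
                             n_events = nEv, n_delayed = nDel,
                             expected_pct = pct,
                             realized_pct = 100 * nDel / nEv)
  }
  names(events) <- sprintf("conc%g_rep%d", cells$conc, cells$replicate)
  list(events = events, truth = do.call(rbind, truth))
}

#' Generate synthetic barcode-bearing reads
#'
#' Each read embeds the reference barcode - with substitutions, insertions
#' and deletions drawn per base - inside random flanking sequence.
#' Substitutions occur at \code{errorRate} per base; insertions and
#' deletions each at a tenth of that rate (a documented convention; the
#' dominant nanopore basecall error mode emulated here is the substitution).
#' Ground-truth edit counts are returned per read.
#'
#' @param n number of reads.
#' @param errorRate per-base substitution probability in [0, 0.5).
#' @param seed integer seed.
#' @param barcode barcode sequence to embed (default [referenceBarcode()]).
#' @param flankLenRange integer pair of flank lengths.
#' @return list with \code{reads} (named character vector) and \code{truth}
#'   (data.frame: read_id, n_sub, n_ins, n_del).
#' @export
generateReads <- function(n, errorRate, seed, barcode = referenceBarcode(),
                          flankLenRange = c(10L, 40L)) {
  if (errorRate < 0 || errorRate >= 0.5)
    stop("errorRate must lie in [0, 0.5)")
  bases <- c("A", "C", "G", "T")
  bc <- strsplit(barcode, "")[[1]]
  withr::with_seed(as.integer(seed), {
    reads <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      out <- character(0)
      nSub <- nIns <- nDel <- 0L
      for (b in bc) {
        if (runif(1L) < errorRate / 10) { nDel <- nDel + 1L; next }
        if (runif(1L) < errorRate) {
          out <- c(out, sample(setdiff(bases, b), 1L))
          nSub <- nSub + 1L
        } else out <- c(out, b)
        if (runif(1L) < errorRate / 10) {
          out <- c(out, sample(bases, 1L))
          nIns <- nIns + 1L
        }
      }
      fl <- sample(flankLenRange[1]:flankLenRange[2], 2L, replace = TRUE)
      reads[i] <- paste0(
        paste(sample(bases, fl[1], replace = TRUE), collapse = ""),
        paste(out, collapse = ""),
        paste(sample(bases, fl[2], replace = TRUE), collapse = ""))
      truth[[i]] <- data.frame(read_id = sprintf("read_%05d", i),
                               n_sub = nSub, n_ins = nIns, n_del = nDel)
    }
    names(reads) <- sprintf("read_%05d", seq_len(n))
    list(reads = reads, truth = do.call(rbind, truth))
  })
}
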