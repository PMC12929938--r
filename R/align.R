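# Barcode alignment and the four-rule read filter.

#' Smith-Waterman local alignment
#'
#' Optimal local alignment with linear (per-position) gap penalty and
#' deterministic tie-breaking: among equal-scoring alignments the one with
#' fewer gap positions is preferred, then the one starting earliest in the
#' read. \code{N} scores as a mismatch against any base. The empty
#' alignment (score 0) is returned when no positive-scoring local
#' alignment exists.
#'
#' @param read,ref sequences over A, C, G, T, N (character scalars).
#' @param scheme a [ScoringScheme-class] (defaults +5 / -4 / -8).
#' @return list with elements \code{score}, \code{read_span} and
#'   \code{ref_span} (0-based half-open), \code{n_match},
#'   \code{n_mismatch}, \code{n_gap_positions}, and \code{aligned_pairs}
#'   (data.frame of 0-based read_idx / ref_idx, NA marking a gap).
#' @examples
#' localAlign(referenceBarcode(), referenceBarcode())$score  # 38 * 5
#' @export
localAlign <- function(read, ref, scheme = scoringScheme()) {
  validObject(scheme)
  read <- toupper(as.character(read))
  ref <- toupper(as.character(ref))
  if (nchar(read) == 0L || nchar(ref) == 0L) stop("empty sequence")
  if (grepl("[^ACGTN]", read) || grepl("[^ACGTN]", ref))
    stop("sequences must be over A, C, G, T, N")
  out <- .sw_align_cpp(read, ref, scheme@match, scheme@mismatch, scheme@gap)
  list(score = out$score,
       read_span = c(out$read_span[1], out$read_span[2]),
       ref_span = c(out$ref_span[1], out$ref_span[2]),
       n_match = out$n_match, n_mismatch = out$n_mismatch,
       n_gap_positions = out$n_gap_positions,
       aligned_pairs = data.frame(read_idx = out$read_idx,
                                  ref_idx = out$ref_idx))
}

#' Apply the four barcode read filters
#'
#' A read passes when its best local alignment to the reference barcode
#' (i) matches at least 15 bases, (ii) has at most 3 mismatches (gaps are
#' counted separately and do not count as mismatches), (iii) begins at
#' reference position 0 with the three aligned read bases equal to the
#' barcode's initial GGG motif, and (iv) has at most 3 mismatches among
#' aligned pairs within the first 10 reference positions.
#'
#' @param aln result of [localAlign()] against \code{ref}.
#' @param ref the reference barcode used for the alignment.
#' @return list with \code{passed} (logical) and \code{reasons} (character
#'   vector, empty iff passed) drawn from \code{too_few_matches},
#'   \code{too_many_mismatches}, \code{missing_GGG_start},
#'   \code{early_mismatches}.
#' @export
applyFilters <- function(aln, ref) {
  readSeq <- attr(aln, "read_seq")
  if (is.null(readSeq))
    stop("alignment lacks stored sequences; produce it with alignRead()")
  ref <- toupper(as.character(ref))
  reasons <- character(0)
  if (aln$n_match < 15L) reasons <- c(reasons, "too_few_matches")
  if (aln$n_mismatch > 3L) reasons <- c(reasons, "too_many_mismatches")

  pairs <- aln$aligned_pairs
  baseAt <- function(seq, idx0) substring(seq, idx0 + 1L, idx0 + 1L)

  # (iii) alignment anchored at reference position 0 with G,G,G aligned
  gggOk <- FALSE
  if (aln$score > 0 && aln$ref_span[1] == 0L) {
    k <- match(0:2, pairs$ref_idx)
    if (all(!is.na(k))) {
      ridx <- pairs$read_idx[k]
      gggOk <- all(!is.na(ridx)) && all(baseAt(readSeq, ridx) == "G")
    }
  }
  if (!gggOk) reasons <- c(reasons, "missing_GGG_start")

  # (iv) mismatches among aligned pairs within reference positions 0-9
  early <- pairs[!is.na(pairs$ref_idx) & pairs$ref_idx <= 9L &
                   !is.na(pairs$read_idx), , drop = FALSE]
  if (nrow(early) > 0L) {
    a <- baseAt(readSeq, early$read_idx)
    b <- baseAt(ref, early$ref_idx)
    nEarlyMismatch <- sum(a != b | a == "N")
    if (nEarlyMismatch > 3L) reasons <- c(reasons, "early_mismatches")
  }

  list(passed = length(reasons) == 0L, reasons = reasons)
}

#' Align a read and keep sequences for filtering
#'
#' [localAlign()] plus the original sequences attached, as required by
#' [applyFilters()] to verify base identity at specific positions.
#'
#' @inheritParams localAlign
#' @return as [localAlign()], with the sequences stored as attributes.
#' @export
alignRead <- function(read, ref, scheme = scoringScheme()) {
  aln <- localAlign(read, ref, scheme)
  attr(aln, "read_seq") <- toupper(as.character(read))
  attr(aln, "ref_seq") <- toupper(as.character(ref))
  aln
}

#' Filter a batch of reads against the barcode
#'
#' Aligns every read to the reference barcode and applies the four read
#' filters. Input may be a named character vector of sequences or a path
#' to a FASTA/FASTQ file (gzip transparent, parsed with Biostrings).
#' Malformed records are skipped with a warning and counted.
#'
#' @param reads named character vector, or a file path.
#' @param ref reference barcode (default [referenceBarcode()]).
#' @param scheme a [ScoringScheme-class].
#' @return list with \code{verdicts} (data.frame: read_id, score, n_match,
#'   n_mismatch, n_gap_positions, passed, reasons) and \code{summary}
#'   (list: n_reads, n_passed, pass_rate, n_skipped).
#' @export
filterReads <- function(reads, ref = referenceBarcode(),
                        scheme = scoringScheme()) {
  nSkipped <- 0L
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    parsed <- .readSequenceFile(reads)
    reads <- parsed$seqs
    nSkipped <- parsed$n_skipped
  }
  if (length(reads) == 0L) {
    return(list(
      verdicts = data.frame(read_id = character(0), score = integer(0),
                            n_match = integer(0), n_mismatch = integer(0),
                            n_gap_positions = integer(0),
                            passed = logical(0), reasons = character(0)),
      summary = list(n_reads = 0L, n_passed = 0L, pass_rate = NA_real_,
                     n_skipped = nSkipped)))
  }
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  rows <- lapply(seq_along(reads), function(i) {
    aln <- alignRead(reads[[i]], ref, scheme)
    v <- applyFilters(aln, ref)
    data.frame(read_id = ids[i], score = aln$score, n_match = aln$n_match,
               n_mismatch = aln$n_mismatch,
               n_gap_positions = aln$n_gap_positions, passed = v$passed,
               reasons = paste(v$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  verdicts <- do.call(rbind, rows)
  list(verdicts = verdicts,
       summary = list(n_reads = nrow(verdicts),
                      n_passed = sum(verdicts$passed),
                      pass_rate = mean(verdicts$passed),
                      n_skipped = nSkipped))
}
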