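# Round-trip IO: events as JSON-lines, reads as FASTA/FASTQ, calls as TSV,
# configurations as YAML.

#' Write events as JSON-lines
#'
#' One JSON object per line with keys event_id, sampling_rate_hz, samples
#' (pA), label, meta.
#'
#' @param events list of [EventTrace-class] objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ev in events) {
    obj <- list(event_id = eventId(ev),
                sampling_rate_hz = samplingRate(ev),
                samples = traceSamples(ev),
                label = eventLabel(ev),
                meta = eventMeta(ev))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read events from JSON-lines
#'
#' Malformed lines are skipped with a warning; the number skipped is
#' attached as attribute \code{n_skipped}.
#'
#' @param path JSON-lines file written by [writeEvents()].
#' @return list of [EventTrace-class] objects.
#' @export
readEvents <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nBad <- 0L
  events <- list()
  for (ln in lines) {
    obj <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || is.null(obj$samples) || is.null(obj$event_id)) {
      nBad <- nBad + 1L
      next
    }
    meta <- if (is.null(obj$meta)) list() else as.list(obj$meta)
    events[[length(events) + 1L]] <-
      eventTrace(obj$samples, eventId = obj$event_id,
                 samplingRate = obj$sampling_rate_hz %||% 5000,
                 label = obj$label %||% "unknown", meta = meta)
  }
  if (nBad > 0L)
    warning(nBad, " malformed line(s) skipped")
  attr(events, "n_skipped") <- nBad
  events
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reads as FASTA or FASTQ
#'
#' FASTQ records carry a uniform quality string.
#'
#' @param reads named character vector of sequences.
#' @param path output file; format chosen by \code{format}.
#' @param format "fasta" or "fastq".
#' @param quality uniform per-base quality character for FASTQ.
#' @return \code{path}, invisibly.
#' @export
writeReads <- function(reads, path, format = c("fasta", "fastq"),
                       quality = "I") {
  format <- match.arg(format)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(reads))
  x <- Biostrings::DNAStringSet(unname(reads))
  names(x) <- ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  } else {
    q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
      paste(rep(quality, n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

# Parse FASTA/FASTQ with Biostrings; count unparseable files as skipped
# records is not possible record-wise here, so malformed files raise.
.readSequenceFile <- function(path) {
  firstChar <- substr(readLines(path, n = 1L, warn = FALSE), 1, 1)
  x <- if (identical(firstChar, "@"))
    Biostrings::readDNAStringSet(path, format = "fastq")
  else Biostrings::readDNAStringSet(path, format = "fasta")
  list(seqs = setNames(as.character(x), names(x)), n_skipped = 0L)
}

#' Write classification calls as TSV
#'
#' @param calls data.frame from [classifyEvents()] / [classifyCnn()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Serialize / restore a run configuration
#'
#' Run configurations are nested named lists (see [runConfig()]); they
#' round-trip through YAML so that a saved configuration re-runs to
#' identical outputs for all deterministic stages.
#'
#' @param cfg named list.
#' @param path YAML file.
#' @return \code{path} invisibly (write); the restored list (read).
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  yaml::read_yaml(path)
}

#' Export a trace image as an 8-bit PGM file
#'
#' Plain-text (P2) portable graymap, viewable by standard image tools and
#' safe to store under version control.
#'
#' @param image a [TraceImage-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeImagePgm <- function(image, path) {
  px <- round(imagePixels(image) * 255)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
  apply(px, 1, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
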