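# Read screening: quality filtering to "high quality" (HQ) reads, then host
# subtraction (removal of reads aligning end-to-end to the host genome or
# transcript set) to "screened" reads. HQ read counts are the normalization
# denominator everywhere downstream.

#' Screening configuration
#'
#' @param min_mean_phred minimum mean Phred score for a read to count as
#'   high quality.
#' @param max_n_bases maximum number of ambiguous (N) bases per HQ read.
#' @param host_kmer_size seed k-mer size for the host screen.
#' @param max_mismatches_host substitutions tolerated in a full-length host
#'   alignment.
#' @return list with class `hervex_screening_config`.
#' @export
screening_config <- function(min_mean_phred = 20, max_n_bases = 2L,
                             host_kmer_size = 14L, max_mismatches_host = 2L) {
  stopifnot(min_mean_phred >= 0, max_n_bases >= 0, host_kmer_size >= 1,
            max_mismatches_host >= 0)
  structure(list(min_mean_phred = min_mean_phred,
                 max_n_bases = as.integer(max_n_bases),
                 host_kmer_size = as.integer(host_kmer_size),
                 max_mismatches_host = as.integer(max_mismatches_host)),
            class = "hervex_screening_config")
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(as.integer(charToRaw(q))) - 33, 0,
         USE.NAMES = FALSE)
}

#' Quality-filter reads to the high-quality (HQ) set
#'
#' Retains reads with mean Phred at least `min_mean_phred` and at most
#' `max_n_bases` ambiguous bases; input order is preserved.
#'
#' @param reads a [seq_records] set with qualities.
#' @param config a [screening_config()].
#' @return list: `reads` (the HQ subset), `summary` (list with
#'   `total_reads`, `hq_reads`).
#' @export
quality_filter <- function(reads, config = screening_config()) {
  if (nrow(reads) > 0 && any(is.na(reads$qual))) {
    stop("reads lack quality scores; supply FASTQ input (or pre-filter ",
         "externally and skip quality_filter)")
  }
  if (nrow(reads) == 0L) {
    return(list(reads = reads, summary = list(total_reads = 0L,
                                              hq_reads = 0L)))
  }
  mp <- mean_phred(reads$qual)
  n_amb <- nchar(reads$seq) - nchar(gsub("[Nn]", "", reads$seq))
  keep <- mp >= config$min_mean_phred & n_amb <= config$max_n_bases
  list(reads = reads[keep, , drop = FALSE],
       summary = list(total_reads = nrow(reads),
                      hq_reads = sum(keep)))
}

#' Remove host-derived reads from the HQ set
#'
#' A read is host-derived if a k-mer seed extends to a full-length
#' (end-to-end) alignment with at most `max_mismatches_host` substitutions
#' against the host genome or host transcript set, on either strand; such
#' reads are removed. Reads aligning to both host and viral sequence are
#' removed (host wins), since screening precedes the viral search.
#'
#' @param reads HQ [seq_records].
#' @param host_genome [seq_records] (or character vector) of host genomic
#'   sequence.
#' @param host_transcripts optional [seq_records] of host transcripts.
#' @param config a [screening_config()].
#' @return list: `reads` (screened subset), `summary` (list with
#'   `hq_reads`, `host_removed`, `screened_reads`).
#' @export
host_subtract <- function(reads, host_genome, host_transcripts = NULL,
                          config = screening_config()) {
  refs <- c(if (is.character(host_genome)) host_genome else host_genome$seq,
            if (!is.null(host_transcripts)) host_transcripts$seq)
  if (length(refs) == 0L || any(!nzchar(refs))) {
    stop("host references must be non-empty")
  }
  if (nrow(reads) == 0L) {
    return(list(reads = reads, summary = list(hq_reads = 0L,
                                              host_removed = 0L,
                                              screened_reads = 0L)))
  }
  is_host <- cpp_match_any(reads$seq, refs, config$max_mismatches_host,
                           config$host_kmer_size)
  list(reads = reads[!is_host, , drop = FALSE],
       summary = list(hq_reads = nrow(reads),
                      host_removed = sum(is_host),
                      screened_reads = sum(!is_host)))
}

#' Full screening stage for one specimen
#'
#' [quality_filter()] followed by [host_subtract()], with a combined
#' per-specimen summary satisfying `total >= hq >= screened` and
#' `hq - host_removed = screened`.
#'
#' @inheritParams quality_filter
#' @inheritParams host_subtract
#' @return list: `hq_reads`, `screened_reads` ([seq_records]), `summary`
#'   (one-row data.frame: `total_reads`, `hq_reads`, `host_removed`,
#'   `screened_reads`).
#' @export
screen_reads <- function(reads, host_genome, host_transcripts = NULL,
                         config = screening_config()) {
  qf <- quality_filter(reads, config)
  hs <- host_subtract(qf$reads, host_genome, host_transcripts, config)
  list(hq_reads = qf$reads, screened_reads = hs$reads,
       summary = data.frame(total_reads = qf$summary$total_reads,
                            hq_reads = qf$summary$hq_reads,
                            host_removed = hs$summary$host_removed,
                            screened_reads = hs$summary$screened_reads))
}
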