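# Retroviral gene catalog (RVGC) construction: six-frame translation of the
# genome, local protein alignment of stop-free translated segments against a
# retroviral domain-protein set, an E-value cutoff, a subject-coverage rule,
# and union-merging of overlapping same-domain hits into named nucleotide
# catalog entries.

#' Six-frame translation
#'
#' Translates a nucleotide sequence in frames 0-2 of the forward strand and
#' of the reverse complement, using the standard genetic code. Stop codons
#' are rendered `*`; codons containing IUPAC ambiguity letters translate to
#' `X`.
#'
#' @param seq nucleotide string (length >= 3).
#' @return data.frame: `strand` (`+`/`-`), `frame` (0-2), `aa`.
#' @export
six_frame_translate <- function(seq) {
  stopifnot(length(seq) == 1L)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  dna <- tryCatch(Biostrings::DNAString(seq),
                  error = function(e) stop("non-IUPAC characters in sequence"))
  rc <- Biostrings::reverseComplement(dna)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (f in 0:2) {
      n <- length(s) - f
      n <- n - n %% 3L
      if (n < 3L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(s, start = f + 1L, width = n),
        if.fuzzy.codon = "X")))
      rows[[length(rows) + 1L]] <- data.frame(
        strand = strand, frame = f, aa = aa, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Split a translation into stop-free segments with 0-based aa offsets.
split_at_stops <- function(aa, min_len) {
  parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
  if (length(parts) == 0L) return(data.frame(offset = integer(0),
                                             seg = character(0)))
  offs <- cumsum(c(0L, nchar(parts) + 1L))[seq_along(parts)]
  keep <- nchar(parts) >= min_len
  data.frame(offset = offs[keep], seg = parts[keep],
             stringsAsFactors = FALSE)
}

#' Translated homology search of a genome against domain proteins
#'
#' Local protein alignment (BLOSUM62, affine gaps) of every stop-free
#' six-frame translated segment against every domain protein. Scores are
#' converted to E-values with ungapped Karlin-Altschul parameters
#' (`lambda`, `K`) over a search space of (total translated residues) x
#' (protein length); hits with E at most `expect_cutoff` are reported with
#' their genomic coordinates mapped back through frame and strand.
#'
#' @param genome a [seq_records] set (or a single string) of genomic
#'   sequence.
#' @param proteins data.frame with `protein_id`, `domain_type`,
#'   `recognition_domain`, `seq` (as from [simulate_domain_proteins()]).
#' @param expect_cutoff E-value cutoff (default 0.1).
#' @param min_segment_aa shortest translated segment aligned.
#' @param lambda,K Karlin-Altschul parameters for BLOSUM62.
#' @param gap_open,gap_ext affine gap penalties.
#' @return data.frame of translated hits with 0-based half-open genome
#'   coordinates (`start`, `end`), `strand`, `frame`, protein metadata,
#'   `aln_length_aa`, `subject_length_aa`, `score`, `bits`, `expect`.
#' @export
translated_search <- function(genome, proteins, expect_cutoff = 0.1,
                              min_segment_aa = 20L, lambda = 0.318,
                              K = 0.13, gap_open = 11, gap_ext = 1) {
  if (is.character(genome)) genome <- seq_records("genome", genome)
  stopifnot(nrow(genome) >= 1L, nrow(proteins) >= 1L)
  segs <- list()
  for (gi in seq_len(nrow(genome))) {
    tr <- six_frame_translate(genome$seq[gi])
    for (k in seq_len(nrow(tr))) {
      sp <- split_at_stops(tr$aa[k], min_segment_aa)
      if (nrow(sp) == 0L) next
      sp$source_id <- genome$id[gi]
      sp$source_len <- nchar(genome$seq[gi])
      sp$strand <- tr$strand[k]
      sp$frame <- tr$frame[k]
      segs[[length(segs) + 1L]] <- sp
    }
  }
  if (length(segs) == 0L) return(empty_translated_hits())
  segs <- do.call(rbind, segs)
  seg_set <- Biostrings::AAStringSet(segs$seg)
  m_total <- sum(nchar(segs$seg))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62 <- get("BLOSUM62", envir = environment())
  out <- list()
  for (pi in seq_len(nrow(proteins))) {
    subj <- Biostrings::AAString(proteins$seq[pi])
    n_subj <- nchar(proteins$seq[pi])
    # raw-score threshold equivalent to the E-value cutoff
    s_min <- log(K * m_total * n_subj / expect_cutoff) / lambda
    aln <- Biostrings::pairwiseAlignment(
      seg_set, subj, type = "local", substitutionMatrix = BLOSUM62,
      gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = FALSE)
    sc <- Biostrings::score(aln)
    keep <- which(sc >= s_min)
    if (length(keep) == 0L) next
    sub <- aln[keep]
    p_start <- IRanges::start(Biostrings::pattern(sub))
    p_end <- IRanges::end(Biostrings::pattern(sub))
    aln_len <- Biostrings::nchar(sub)
    meta <- segs[keep, , drop = FALSE]
    aa_lo <- meta$offset + p_start - 1L   # 0-based aa within frame
    aa_hi <- meta$offset + p_end          # 0-based exclusive
    nt_lo <- meta$frame + 3L * aa_lo
    nt_hi <- meta$frame + 3L * aa_hi
    start <- ifelse(meta$strand == "+", nt_lo, meta$source_len - nt_hi)
    end <- ifelse(meta$strand == "+", nt_hi, meta$source_len - nt_lo)
    bits <- (lambda * sc[keep] - log(K)) / log(2)
    expect <- m_total * n_subj * 2^(-bits)
    out[[length(out) + 1L]] <- data.frame(
      source_id = meta$source_id, start = as.integer(start),
      end = as.integer(end), strand = meta$strand, frame = meta$frame,
      protein_id = proteins$protein_id[pi],
      domain_type = proteins$domain_type[pi],
      recognition_domain = proteins$recognition_domain[pi],
      aln_length_aa = as.integer(aln_len),
      subject_length_aa = n_subj, score = sc[keep], bits = bits,
      expect = expect, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_translated_hits())
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits[hits$expect <= expect_cutoff, , drop = FALSE]
}

empty_translated_hits <- function() {
  data.frame(source_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0),
             protein_id = character(0), domain_type = character(0),
             recognition_domain = character(0), aln_length_aa = integer(0),
             subject_length_aa = integer(0), score = numeric(0),
             bits = numeric(0), expect = numeric(0),
             stringsAsFactors = FALSE)
}

#' Subject-coverage filter for translated hits
#'
#' Keeps hits whose alignment length (in residues, gaps included) is at
#' least `min_coverage` of the subject protein length; the boundary is
#' inclusive.
#'
#' @param hits data.frame from [translated_search()].
#' @param min_coverage minimum alignment/subject length ratio (default 0.5).
#' @return the retained rows.
#' @export
coverage_filter <- function(hits, min_coverage = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  hits[hits$aln_length_aa >= min_coverage * hits$subject_length_aa, ,
       drop = FALSE]
}

#' Build the retroviral gene catalog from filtered hits
#'
#' Overlapping hits of the same domain type on the same strand (and source)
#' are union-merged into a single entry; entries are numbered sequentially
#' within each domain type (ordered by source and position) and named with
#' the [encode_entry_name()] codec. Each entry's nucleotide sequence is the
#' genome substring at its coordinates, reverse-complemented for
#' minus-strand entries.
#'
#' @param hits coverage-filtered hits.
#' @param genome the [seq_records] genome set (or single string) the hits
#'   refer to.
#' @return list: `records` ([seq_records] whose ids are encoded entry
#'   names), `table` (data.frame: `code`, `domain_type`, `unique_index`,
#'   `recognition_domain`, `source_id`, `start` (1-based), `length`,
#'   `strand`).
#' @export
build_catalog <- function(hits, genome) {
  if (is.character(genome)) genome <- seq_records("genome", genome)
  if (nrow(hits) == 0L) {
    return(list(records = seq_records(character(0), character(0)),
                table = data.frame()))
  }
  glen <- stats::setNames(nchar(genome$seq), genome$id)
  if (any(hits$start < 0 | hits$end > glen[hits$source_id])) {
    stop("hit coordinates out of genome bounds")
  }
  entries <- list()
  for (dt in unique(hits$domain_type)) {
    sub_dt <- hits[hits$domain_type == dt, , drop = FALSE]
    merged <- list()
    for (src in unique(sub_dt$source_id)) {
      for (st in unique(sub_dt$strand[sub_dt$source_id == src])) {
        h <- sub_dt[sub_dt$source_id == src & sub_dt$strand == st, ,
                    drop = FALSE]
        ir <- IRanges::IRanges(start = h$start + 1L, end = h$end)
        red <- IRanges::reduce(ir)
        ov <- IRanges::findOverlaps(red, ir)
        for (k in seq_along(red)) {
          members <- h[S4Vectors::subjectHits(ov)[
            S4Vectors::queryHits(ov) == k], , drop = FALSE]
          best <- members[which.max(members$score), ]
          merged[[length(merged) + 1L]] <- data.frame(
            domain_type = dt,
            recognition_domain = best$recognition_domain,
            source_id = src, start = IRanges::start(red)[k],
            length = IRanges::width(red)[k], strand = st,
            stringsAsFactors = FALSE)
        }
      }
    }
    merged <- do.call(rbind, merged)
    merged <- merged[order(merged$source_id, merged$start, merged$strand), ,
                     drop = FALSE]
    merged$unique_index <- seq_len(nrow(merged))
    entries[[length(entries) + 1L]] <- merged
  }
  tab <- do.call(rbind, entries)
  tab$code <- mapply(encode_entry_name, tab$domain_type, tab$unique_index,
                     tab$recognition_domain, tab$source_id, tab$start,
                     tab$length)
  gseq <- stats::setNames(genome$seq, genome$id)
  seqs <- substring(gseq[tab$source_id], tab$start,
                    tab$start + tab$length - 1L)
  minus <- tab$strand == "-"
  if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
  tab <- tab[, c("code", "domain_type", "unique_index",
                 "recognition_domain", "source_id", "start", "length",
                 "strand")]
  rownames(tab) <- NULL
  list(records = seq_records(tab$code, unname(seqs)), table = tab)
}

#' Build a catalog directly from genome and protein inputs
#'
#' Convenience wrapper: [translated_search()], [coverage_filter()],
#' [build_catalog()].
#'
#' @inheritParams translated_search
#' @inheritParams coverage_filter
#' @return as [build_catalog()].
#' @export
build_catalog_from_genome <- function(genome, proteins, expect_cutoff = 0.1,
                                      min_coverage = 0.5, ...) {
  hits <- translated_search(genome, proteins, expect_cutoff = expect_cutoff,
                            ...)
  build_catalog(coverage_filter(hits, min_coverage), genome)
}
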