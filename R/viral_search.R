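# Viral hit-rate screen: screened reads are aligned to the viral reference
# set by exact-word seeding (28 nt by default) with ungapped extension,
# distinct hit reads are counted per taxon, normalized by the specimen's HQ
# read count into viral hit rates (VHR), and taxa are screened for
# per-specimen overrepresentation with a Bonferroni-corrected Z-test.

#' Seed-and-extend alignment of reads against viral references
#'
#' For each exact `word_size` nucleotide match (either strand) the alignment
#' is extended ungapped in both directions while the cumulative identity
#' stays at or above `min_identity`; extensions of at least `min_length` nt
#' are reported, at most one (the best-scoring) per read/reference pair.
#' Reads shorter than `word_size` yield no hits.
#'
#' @param reads [seq_records] of screened reads.
#' @param viral_refs [seq_records] of viral reference sequences.
#' @param word_size exact seed word size (default 28 nt).
#' @param min_identity minimum cumulative identity during extension.
#' @param min_length minimum reported alignment length (nt).
#' @return data.frame: `read_id`, `viral_record_id`, `strand`,
#'   `seed_position` (1-based on the reference), `extended_length`,
#'   `extended_identity`, `score`.
#' @export
seed_and_extend <- function(reads, viral_refs, word_size = 28L,
                            min_identity = 0.9, min_length = 40L) {
  stopifnot(word_size >= 1L, min_identity > 0, min_identity <= 1,
            min_length >= word_size)
  if (nrow(reads) == 0L || nrow(viral_refs) == 0L) {
    return(data.frame(read_id = character(0), viral_record_id = character(0),
                      strand = character(0), seed_position = integer(0),
                      extended_length = integer(0),
                      extended_identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  raw <- cpp_seed_extend(reads$seq, viral_refs$seq, as.integer(word_size),
                         min_identity, as.integer(min_length))
  data.frame(read_id = reads$id[raw$read],
             viral_record_id = viral_refs$id[raw$ref],
             strand = ifelse(raw$strand > 0, "+", "-"),
             seed_position = raw$seed_pos + 1L,
             extended_length = raw$length,
             extended_identity = raw$identity,
             score = raw$score, stringsAsFactors = FALSE)
}

#' Tabulate viral hit rates
#'
#' The hit count for a (specimen, taxon) cell is the number of distinct
#' reads with at least one alignment to any record of that taxon; the VHR is
#' that count divided by the specimen's HQ read count.
#'
#' @param hits_by_specimen named list (specimen id -> data.frame from
#'   [seed_and_extend()]).
#' @param taxa data.frame mapping `record_id` to `taxon`; every aligned
#'   record must be mapped exactly once.
#' @param hq_counts named integer vector of HQ read counts per specimen.
#' @return list with class `hervex_vhr`: `vhr` (specimen x taxon matrix),
#'   `counts` (integer matrix), `hq` (named vector).
#' @export
tabulate_vhr <- function(hits_by_specimen, taxa, hq_counts) {
  stopifnot(!is.null(names(hits_by_specimen)),
            all(names(hits_by_specimen) %in% names(hq_counts)))
  if (anyDuplicated(taxa$record_id)) {
    stop("viral record(s) mapped to more than one taxon")
  }
  taxon_of <- stats::setNames(taxa$taxon, taxa$record_id)
  taxa_levels <- unique(taxa$taxon)
  specimens <- names(hits_by_specimen)
  counts <- matrix(0L, nrow = length(specimens), ncol = length(taxa_levels),
                   dimnames = list(specimens, taxa_levels))
  for (sid in specimens) {
    h <- hits_by_specimen[[sid]]
    if (nrow(h) == 0L) next
    unmapped <- setdiff(unique(h$viral_record_id), names(taxon_of))
    if (length(unmapped)) {
      stop("viral record(s) missing from the taxon map: ",
           paste(unmapped, collapse = ", "))
    }
    per_taxon <- tapply(h$read_id, taxon_of[h$viral_record_id],
                        function(r) length(unique(r)))
    counts[sid, names(per_taxon)] <- as.integer(per_taxon)
  }
  hq <- hq_counts[specimens]
  structure(list(vhr = counts / as.numeric(hq), counts = counts, hq = hq),
            class = "hervex_vhr")
}

#' Log-transformed hit rates for display
#'
#' Cells with a zero hit count are rendered at a "below detection" floor of
#' `log10(0.5 / hq)` (half a hit); others as `log10(vhr)`.
#'
#' @param table a `hervex_vhr` from [tabulate_vhr()].
#' @param base logarithm base (default 10).
#' @return numeric matrix of log hit rates.
#' @export
log_hit_rates <- function(table, base = 10) {
  stopifnot(inherits(table, "hervex_vhr"))
  out <- log(table$vhr, base = base)
  floor_vals <- log(0.5 / as.numeric(table$hq), base = base)
  zero <- table$counts == 0L
  out[zero] <- floor_vals[row(out)[zero]]
  out
}

#' Screen taxa for per-specimen overrepresentation
#'
#' For every case specimen (demyelination or OND) and taxon, the case VHR is
#' compared against the control set with [z_test_case_vs_controls()]; the
#' Bonferroni family is (number of case specimens) x (number of taxa). A
#' taxon is retained when at least one case specimen exceeds the control
#' mean with corrected p below `alpha`. Taxa whose control variance is zero
#' while a case deviates from the control mean are flagged degenerate and
#' retained for manual review.
#'
#' @param table a `hervex_vhr` from [tabulate_vhr()].
#' @param design design table with `specimen_id` and `group`.
#' @param alpha significance level after correction (default 0.05).
#' @return data.frame per taxon: `taxon`, `min_corrected_p`, `n_significant`,
#'   `degenerate`, `retained`.
#' @export
screen_overrepresented_taxa <- function(table, design, alpha = 0.05) {
  stopifnot(inherits(table, "hervex_vhr"))
  specimens <- rownames(table$vhr)
  grp <- stats::setNames(design$group, design$specimen_id)[specimens]
  ctrl <- specimens[grp == "control"]
  cases <- specimens[grp %in% c("demyelination", "OND")]
  if (length(ctrl) < 2L) stop("need at least 2 control specimens")
  m <- length(cases) * ncol(table$vhr)
  out <- data.frame(taxon = colnames(table$vhr),
                    min_corrected_p = NA_real_, n_significant = 0L,
                    degenerate = FALSE, retained = FALSE,
                    stringsAsFactors = FALSE)
  for (t in seq_len(ncol(table$vhr))) {
    cvals <- table$vhr[ctrl, t]
    cmean <- mean(cvals)
    ps <- rep(NA_real_, length(cases))
    degen <- FALSE
    for (ci in seq_along(cases)) {
      x <- table$vhr[cases[ci], t]
      tst <- z_test_case_vs_controls(x, cvals)
      if (isTRUE(tst$degenerate)) {
        if (x > cmean) degen <- TRUE
        next
      }
      if (x > cmean) ps[ci] <- bonferroni(tst$p_value, m)
    }
    sig <- !is.na(ps) & ps < alpha
    out$min_corrected_p[t] <- if (all(is.na(ps))) NA_real_ else
      min(ps, na.rm = TRUE)
    out$n_significant[t] <- sum(sig)
    out$degenerate[t] <- degen
    out$retained[t] <- any(sig) || degen
  }
  out
}
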