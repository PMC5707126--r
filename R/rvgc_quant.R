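# Catalog quantification: end-to-end alignment of reads against the
# retroviral gene catalog, read counting under the Best-Alignment (each
# read once, to its best match) and Comprehensive-Alignment (every
# reported alignment) schemes, FPKM x 1000 reporting, and the
# demyelination-vs-control group comparison (Mann-Whitney + per-domain
# Benjamini-Hochberg FDR).

#' Align reads end-to-end against the catalog
#'
#' Reports every full-read-span alignment (either strand) with at most
#' `max_mismatches` substitutions; each alignment is scored
#' `-(mismatches)`. Unaligned reads are simply absent from the result.
#'
#' @param reads [seq_records] of reads.
#' @param catalog a catalog list from [build_catalog()] (or a
#'   [seq_records] of entries).
#' @param max_mismatches substitution budget per alignment (default 3).
#' @param kmer seed size for the pigeonhole index; must satisfy
#'   `kmer <= floor(read_length / (max_mismatches + 1))` for the search to
#'   be exhaustive at 50 nt reads.
#' @return data.frame: `read_id`, `entry_code`, `mismatches`, `score`,
#'   `strand`.
#' @export
align_to_catalog <- function(reads, catalog, max_mismatches = 3L,
                             kmer = 12L) {
  entries <- if (is.data.frame(catalog)) catalog else catalog$records
  if (nrow(entries) == 0L) stop("catalog is empty")
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), entry_code = character(0),
                      mismatches = integer(0), score = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  raw <- cpp_align_end_to_end(reads$seq, entries$seq,
                              as.integer(max_mismatches), as.integer(kmer))
  data.frame(read_id = reads$id[raw$read],
             entry_code = entries$id[raw$ref],
             mismatches = raw$mismatches,
             score = -raw$mismatches,
             strand = ifelse(raw$strand > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Best-alignment read counts
#'
#' Each read contributes exactly one count, to its best-scoring entry; ties
#' are broken by the lexicographically smallest entry code so counting is
#' deterministic.
#'
#' @param alignments data.frame from [align_to_catalog()].
#' @param entry_codes all catalog entry codes (zero counts included).
#' @return named integer vector of per-entry counts.
#' @export
count_best <- function(alignments, entry_codes) {
  counts <- stats::setNames(integer(length(entry_codes)), entry_codes)
  if (nrow(alignments) == 0L) return(counts)
  o <- order(alignments$read_id, -alignments$score, alignments$entry_code)
  a <- alignments[o, , drop = FALSE]
  best <- a[!duplicated(a$read_id), , drop = FALSE]
  tab <- table(best$entry_code)
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  counts
}

#' Comprehensive-alignment read counts
#'
#' Every reported alignment contributes one count; a multi-mapping read may
#' contribute to many entries (at most once per entry).
#'
#' @inheritParams count_best
#' @return named integer vector of per-entry counts.
#' @export
count_comprehensive <- function(alignments, entry_codes) {
  counts <- stats::setNames(integer(length(entry_codes)), entry_codes)
  if (nrow(alignments) == 0L) return(counts)
  a <- alignments[!duplicated(alignments[c("read_id", "entry_code")]), ,
                  drop = FALSE]
  tab <- table(a$entry_code)
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  counts
}

#' FPKM x 1000
#'
#' `FPKM = count / ((length/1000) * (norm_mass/1e6))`, reported x 1000. The
#' normalization mass is the number of fragments aligned to the catalog for
#' the specimen under the active counting scheme.
#'
#' @param counts named per-entry counts.
#' @param entry_lengths entry lengths in nt (same order/names).
#' @param norm_mass fragment normalization mass (> 0).
#' @return numeric vector of FPKM x 1000 values.
#' @export
fpkm_x1000 <- function(counts, entry_lengths, norm_mass) {
  stopifnot(length(counts) == length(entry_lengths), norm_mass > 0)
  if (any(entry_lengths <= 0)) stop("zero-length catalog entry")
  1000 * counts / ((entry_lengths / 1000) * (norm_mass / 1e6))
}

#' Quantify catalog expression across specimens
#'
#' Aligns each specimen's reads to the catalog and produces count and
#' FPKM x 1000 matrices under both counting schemes.
#'
#' The normalization mass per specimen is either `"library"` (the number of
#' reads supplied for the specimen, i.e. its HQ reads -- the stand-in for a
#' library-wide mapped-fragment total) or `"aligned"` (the scheme's total
#' catalog count). Library-wide is the default: a catalog-wide denominator
#' rises with any group-wide expression effect and so biases every
#' entry's between-group FPKM ratio toward (and past) 1.
#'
#' @param reads_by_specimen named list of [seq_records].
#' @param catalog catalog list from [build_catalog()].
#' @param max_mismatches,kmer see [align_to_catalog()].
#' @param norm_mass `"library"` or `"aligned"` (see Details).
#' @return list with class `hervex_expression`: `counts_best`,
#'   `counts_comprehensive`, `fpkm_best`, `fpkm_comprehensive` (entry x
#'   specimen matrices), `aligned_reads` (named vector), `norm_mass`,
#'   `catalog_table`.
#' @export
quantify_expression <- function(reads_by_specimen, catalog,
                                max_mismatches = 3L, kmer = 12L,
                                norm_mass = c("library", "aligned")) {
  norm_mass <- match.arg(norm_mass)
  codes <- catalog$table$code
  lens <- catalog$table$length
  specimens <- names(reads_by_specimen)
  mk <- function() matrix(0, nrow = length(codes), ncol = length(specimens),
                          dimnames = list(codes, specimens))
  cb <- mk(); cc <- mk(); fb <- mk(); fc <- mk()
  aligned <- stats::setNames(integer(length(specimens)), specimens)
  for (sid in specimens) {
    aln <- align_to_catalog(reads_by_specimen[[sid]], catalog,
                            max_mismatches, kmer)
    b <- count_best(aln, codes)
    k <- count_comprehensive(aln, codes)
    cb[, sid] <- b
    cc[, sid] <- k
    aligned[sid] <- length(unique(aln$read_id))
    nm_b <- if (norm_mass == "library") nrow(reads_by_specimen[[sid]]) else
      sum(b)
    nm_k <- if (norm_mass == "library") nrow(reads_by_specimen[[sid]]) else
      sum(k)
    if (nm_b > 0 && sum(b) > 0) fb[, sid] <- fpkm_x1000(b, lens, nm_b)
    if (nm_k > 0 && sum(k) > 0) fc[, sid] <- fpkm_x1000(k, lens, nm_k)
  }
  structure(list(counts_best = cb, counts_comprehensive = cc,
                 fpkm_best = fb, fpkm_comprehensive = fc,
                 aligned_reads = aligned, norm_mass = norm_mass,
                 catalog_table = catalog$table),
            class = "hervex_expression")
}

#' Group comparison of catalog expression
#'
#' Per entry: ratio of case to control group means of FPKM x 1000, a
#' two-sided Mann-Whitney p, and Benjamini-Hochberg q computed within each
#' domain type separately. Entries that are all-zero in both groups are
#' assigned p = 1 and flagged uninformative.
#'
#' @param fpkm entry x specimen matrix of FPKM x 1000 values.
#' @param catalog_table catalog table (for domain types and recognition
#'   domains).
#' @param design design table; `diagnosis` column required for
#'   `grouping = "ppms"`.
#' @param grouping `"demyelination"` (whole group) or `"ppms"` (PPMS
#'   specimens only) versus normal controls.
#' @param q_threshold FDR threshold for the `significant` flag.
#' @return data.frame per entry: `entry_code`, `domain_type`,
#'   `recognition_domain`, `mean_case`, `mean_control`, `ratio`, `p`, `q`,
#'   `significant`, `uninformative`.
#' @export
group_compare <- function(fpkm, catalog_table, design,
                          grouping = c("demyelination", "ppms"),
                          q_threshold = 0.05) {
  grouping <- match.arg(grouping)
  grp <- stats::setNames(design$group, design$specimen_id)
  case_ids <- if (grouping == "demyelination") {
    design$specimen_id[design$group == "demyelination"]
  } else {
    if (is.null(design$diagnosis)) {
      stop("grouping='ppms' needs a 'diagnosis' column in the design table")
    }
    design$specimen_id[design$group == "demyelination" &
                         design$diagnosis == "PPMS"]
  }
  ctrl_ids <- design$specimen_id[design$group == "control"]
  case_ids <- intersect(case_ids, colnames(fpkm))
  ctrl_ids <- intersect(ctrl_ids, colnames(fpkm))
  if (length(case_ids) < 3L || length(ctrl_ids) < 3L) {
    stop("need at least 3 specimens per group")
  }
  codes <- rownames(fpkm)
  meta <- catalog_table[match(codes, catalog_table$code), ]
  out <- data.frame(entry_code = codes, domain_type = meta$domain_type,
                    recognition_domain = meta$recognition_domain,
                    mean_case = rowMeans(fpkm[, case_ids, drop = FALSE]),
                    mean_control = rowMeans(fpkm[, ctrl_ids, drop = FALSE]),
                    ratio = NA_real_, p = NA_real_, q = NA_real_,
                    significant = FALSE, uninformative = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(codes)) {
    x <- fpkm[i, case_ids]
    y <- fpkm[i, ctrl_ids]
    if (all(x == 0) && all(y == 0)) {
      out$p[i] <- 1
      out$uninformative[i] <- TRUE
      next
    }
    out$ratio[i] <- if (out$mean_control[i] > 0)
      out$mean_case[i] / out$mean_control[i] else Inf
    out$p[i] <- mann_whitney_u(x, y)$p_value
  }
  for (dt in unique(out$domain_type)) {
    idx <- which(out$domain_type == dt)
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  out$significant <- !out$uninformative & out$q <= q_threshold
  rownames(out) <- NULL
  out
}
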