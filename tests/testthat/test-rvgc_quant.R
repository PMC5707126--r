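# Catalog alignment (vs an exhaustive oracle), the two counting schemes,
# FPKM arithmetic, and the group comparison.

toy_catalog <- function(dup = FALSE) {
  set.seed(31)
  e1 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  e2 <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- c(e1, e2, if (dup) e1)
  ids <- c("ENV_U1|r|s|1|300", "GAG_U1|r|s|1|400",
           if (dup) "ENV_U2|r|s|1|300")
  list(records = seq_records(ids, seqs),
       table = data.frame(code = ids, domain_type = sub("_.*", "", ids),
                          recognition_domain = "r", length = nchar(seqs),
                          stringsAsFactors = FALSE))
}

test_that("catalog alignment equals the exhaustive-scan oracle on toy data", {
  cat0 <- toy_catalog()
  set.seed(8)
  reads <- list()
  for (i in 1:30) {
    src <- sample(1:2, 1)
    off <- sample(nchar(cat0$records$seq[src]) - 50, 1)
    s <- substr(cat0$records$seq[src], off, off + 49)
    nmut <- sample(0:4, 1)
    for (m in seq_len(nmut)) {
      p <- sample(50, 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    if (runif(1) < 0.5) {
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    }
    reads[[i]] <- s
  }
  reads <- seq_records(sprintf("r%02d", 1:30), unlist(reads),
                       qual = strrep("I", 50))
  got <- align_to_catalog(reads, cat0, max_mismatches = 3)
  want <- oracle_align(reads, cat0$records, 3)
  key <- function(df) sort(sprintf("%s:%s:%s:%d", df$read_id,
                                   df$entry_code, df$strand,
                                   df$mismatches))
  expect_equal(key(got), key(want))
})

test_that("best counting assigns each read once with the lexicographic tie rule", {
  aln <- data.frame(
    read_id = c("r1", "r1", "r2", "r2", "r3"),
    entry_code = c("ENV_U2", "ENV_U1", "ENV_U2", "ENV_U1", "GAG_U1"),
    mismatches = c(0L, 1L, 2L, 2L, 0L),
    score = c(0L, -1L, -2L, -2L, 0L),
    strand = "+", stringsAsFactors = FALSE)
  codes <- c("ENV_U1", "ENV_U2", "GAG_U1")
  b <- count_best(aln, codes)
  expect_equal(unname(b), c(1L, 1L, 1L)) # r1 -> ENV_U2 (best score),
  # r2 -> ENV_U1 (tie, lexicographically smaller), r3 -> GAG_U1
  expect_equal(sum(b), length(unique(aln$read_id)))
  k <- count_comprehensive(aln, codes)
  expect_equal(unname(k), c(2L, 2L, 1L))
  expect_true(all(k >= b))
})

test_that("counting properties hold on randomized inputs; duplicate-free catalogs equalize schemes", {
  cat0 <- toy_catalog(dup = FALSE)
  catd <- toy_catalog(dup = TRUE)
  reads <- random_reads(40, seed = 5)
  # also spike in reads copied from entries so some align
  spiked <- seq_records(
    c(reads$id, sprintf("s%02d", 1:20)),
    c(reads$seq, vapply(1:20, function(i) {
      src <- sample(1:2, 1)
      off <- sample(nchar(cat0$records$seq[src]) - 50, 1)
      substr(cat0$records$seq[src], off, off + 49)
    }, "")),
    qual = strrep("I", 50))
  for (cc in list(cat0, catd)) {
    aln <- align_to_catalog(spiked, cc)
    b <- count_best(aln, cc$table$code)
    k <- count_comprehensive(aln, cc$table$code)
    expect_equal(sum(b), length(unique(aln$read_id)))
    expect_true(all(k >= b))
  }
  # no duplicated sequence -> comprehensive equals best
  alnu <- align_to_catalog(spiked, cat0)
  expect_equal(count_best(alnu, cat0$table$code),
               count_comprehensive(alnu, cat0$table$code))
  # duplicated entry -> strictly more comprehensive mass
  alnd <- align_to_catalog(spiked, catd)
  expect_gt(sum(count_comprehensive(alnd, catd$table$code)),
            sum(count_best(alnd, catd$table$code)))
})

test_that("FPKM follows the closed form and its scaling laws", {
  expect_equal(unname(fpkm_x1000(c(e = 10), 1000, 1e6)), 10000)
  expect_equal(unname(fpkm_x1000(c(e = 10), 1000, 2e6)),
               unname(fpkm_x1000(c(e = 10), 1000, 1e6)) / 2)
  expect_equal(unname(fpkm_x1000(c(e = 0), 500, 1e6)), 0)
  # multiplying counts and norm mass by c leaves FPKM unchanged
  expect_equal(fpkm_x1000(c(a = 30, b = 7), c(300, 700), 37),
               fpkm_x1000(c(a = 300, b = 70), c(300, 700), 370))
  expect_error(fpkm_x1000(c(a = 1), 0, 100), "zero-length")
  expect_error(fpkm_x1000(c(a = 1), 100, 0), "norm_mass")
})

test_that("group comparison: identical groups give ratio 1 and p 1; q matches per-domain BH oracle", {
  design <- data.frame(
    specimen_id = c(paste0("d", 1:4), paste0("c", 1:4)),
    group = rep(c("demyelination", "control"), each = 4),
    diagnosis = c(rep("PPMS", 4), rep("normal", 4)))
  tabm <- matrix(5, nrow = 3, ncol = 8,
                 dimnames = list(c("ENV_U1|r|s|1|300", "ENV_U2|r|s|1|300",
                                   "GAG_U1|r|s|1|400"),
                                 design$specimen_id))
  cat_tab <- data.frame(code = rownames(tabm),
                        domain_type = c("ENV", "ENV", "GAG"),
                        recognition_domain = "r")
  res <- group_compare(tabm, cat_tab, design)
  expect_equal(res$ratio, rep(1, 3))
  expect_equal(res$p, rep(1, 3))
  # an all-zero entry is flagged uninformative with p = 1
  tab0 <- tabm; tab0[2, ] <- 0
  res0 <- group_compare(tab0, cat_tab, design)
  expect_true(res0$uninformative[2])
  expect_equal(res0$p[2], 1)
  # per-domain BH: q within a domain is BH of that domain's p-values only
  set.seed(44)
  tabr <- matrix(rexp(24), nrow = 3, dimnames = dimnames(tabm))
  tabr[1, 1:4] <- tabr[1, 1:4] * 20
  resr <- group_compare(tabr, cat_tab, design)
  expect_equal(resr$q[resr$domain_type == "ENV"],
               bh_fdr(resr$p[resr$domain_type == "ENV"]))
  expect_equal(resr$q[resr$domain_type == "GAG"],
               bh_fdr(resr$p[resr$domain_type == "GAG"]))
})

test_that("quantify_expression produces consistent matrices on the fixture study", {
  st <- fixture_study()
  cat0 <- fixture_catalog()
  reads <- lapply(st$reads[1:3], function(r)
    quality_filter(r)$reads)
  expr <- quantify_expression(reads, cat0)
  expect_equal(dim(expr$counts_best), c(nrow(cat0$table), 3))
  expect_true(all(expr$counts_comprehensive >= expr$counts_best))
  expect_equal(unname(colSums(expr$counts_best)),
               unname(expr$aligned_reads))
  # library norm mass: denominator is the specimen's supplied read count
  sid <- colnames(expr$fpkm_best)[1]
  expect_equal(expr$fpkm_best[, sid],
               1000 * expr$counts_best[, sid] /
                 ((cat0$table$length / 1000) * (nrow(reads[[sid]]) / 1e6)))
  # aligned norm mass: denominator is the scheme's catalog total
  expr_a <- quantify_expression(reads, cat0, norm_mass = "aligned")
  nm <- sum(expr_a$counts_best[, sid])
  expect_equal(expr_a$fpkm_best[, sid],
               1000 * expr_a$counts_best[, sid] /
                 ((cat0$table$length / 1000) * (nm / 1e6)))
  expect_equal(expr_a$counts_best, expr$counts_best)
})
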