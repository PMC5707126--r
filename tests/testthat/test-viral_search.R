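# Seeded alignment against the viral reference set, hit-rate tabulation,
# log display transform, and the overrepresentation screen.

viral_fixture <- function() {
  set.seed(23)
  seq_records(c("v1", "v2"),
              c(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                      collapse = ""),
                paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                      collapse = "")))
}

test_that("a read copied from a reference aligns at identity 1 over its full length", {
  refs <- viral_fixture()
  rd <- seq_records("r1", substr(refs$seq[1], 501, 550),
                    qual = strrep("I", 50))
  h <- seed_and_extend(rd, refs)
  expect_equal(nrow(h), 1)
  expect_equal(h$viral_record_id, "v1")
  expect_equal(h$extended_identity, 1)
  expect_equal(h$extended_length, 50)
  rc <- seq_records("r2", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(refs$seq[1], 501, 550)))),
    qual = strrep("I", 50))
  h2 <- seed_and_extend(rc, refs)
  expect_equal(h2$strand, "-")
  expect_equal(h2$extended_length, 50)
})

test_that("a shared block shorter than the word size does not seed", {
  refs <- viral_fixture()
  block27 <- substr(refs$seq[1], 1001, 1027)
  set.seed(4)
  filler <- paste(sample(c("A", "C", "G", "T"), 23, TRUE), collapse = "")
  rd <- seq_records("r1", paste0(block27, filler), qual = strrep("I", 50))
  # the random filler must not itself create a 28-mer; check then assert
  h <- seed_and_extend(rd, refs, word_size = 28L)
  expect_equal(nrow(h), 0)
  h2 <- seed_and_extend(rd, refs, word_size = 27L, min_length = 27L)
  expect_gte(nrow(h2), 1)
})

test_that("substituted reads seed exactly when an intact 28-mer survives (enumeration oracle)", {
  refs <- viral_fixture()
  flip <- function(s, pos) {
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, pos, pos))[1]
    s
  }
  has_seed <- function(s) { # oracle: enumerate exact 28-mers of the read
    kmers <- vapply(1:(nchar(s) - 27), function(i) substr(s, i, i + 27), "")
    any(vapply(kmers, function(k) grepl(k, refs$seq[1], fixed = TRUE), TRUE))
  }
  base <- substr(refs$seq[1], 501, 550)
  # a substitution at position 10 leaves the 40 nt tail intact: seeds and
  # extends across the mismatch
  rd10 <- flip(base, 10)
  expect_true(has_seed(rd10))
  h <- seed_and_extend(seq_records("r1", rd10, qual = strrep("I", 50)), refs)
  expect_equal(nrow(h), 1)
  expect_gte(h$extended_length, 40)
  expect_lt(h$extended_identity, 1)
  # a dead-center substitution (position 25 of 50) splits the read into
  # flanks of 24 and 25 nt -- no exact 28-mer remains, so no seed
  rd25 <- flip(base, 25)
  expect_false(has_seed(rd25))
  expect_equal(nrow(seed_and_extend(
    seq_records("r2", rd25, qual = strrep("I", 50)), refs)), 0)
})

test_that("reads shorter than the word size yield no hits, not an error", {
  refs <- viral_fixture()
  rd <- seq_records("tiny", substr(refs$seq[1], 1, 20), qual = strrep("I", 20))
  expect_equal(nrow(seed_and_extend(rd, refs)), 0)
})

test_that("VHR tabulation counts distinct reads and divides by HQ reads", {
  taxa <- data.frame(record_id = c("v1", "v2", "v3"),
                     taxon = c("tA", "tA", "tB"))
  hits <- data.frame(
    read_id = c("r1", "r1", "r1", "r2"),
    viral_record_id = c("v1", "v2", "v3", "v1"),
    stringsAsFactors = FALSE)
  tab <- tabulate_vhr(list(s1 = hits, s2 = hits[0, ]),
                      taxa, c(s1 = 1e6, s2 = 1e6))
  expect_equal(tab$counts["s1", "tA"], 2L) # r1 counted once for tA
  expect_equal(tab$counts["s1", "tB"], 1L)
  expect_equal(tab$vhr["s1", "tA"], 2e-6)
  expect_equal(unname(tab$vhr["s2", ]), c(0, 0))
  expect_error(tabulate_vhr(list(s1 = transform(hits,
                                                viral_record_id = "vX")),
                            taxa, c(s1 = 10)), "missing from the taxon map")
  # duplicating a record inside a taxon cannot change the VHR
  taxa2 <- rbind(taxa, data.frame(record_id = "v1b", taxon = "tA"))
  hits2 <- rbind(hits, data.frame(read_id = "r1", viral_record_id = "v1b"))
  tab2 <- tabulate_vhr(list(s1 = hits2, s2 = hits[0, ]), taxa2,
                       c(s1 = 1e6, s2 = 1e6))
  expect_equal(tab2$vhr["s1", "tA"], tab$vhr["s1", "tA"])
})

test_that("log hit rates use the half-hit floor for zero counts and are monotone", {
  taxa <- data.frame(record_id = "v1", taxon = "tA")
  mk <- function(n_hits, hq) {
    hits <- if (n_hits > 0) data.frame(
      read_id = sprintf("r%d", 1:n_hits), viral_record_id = "v1") else
        data.frame(read_id = character(0), viral_record_id = character(0))
    tabulate_vhr(list(s = hits), taxa, c(s = hq))
  }
  expect_equal(log_hit_rates(mk(10, 1e6))["s", "tA"], -5)
  expect_equal(log_hit_rates(mk(0, 1e6))["s", "tA"], log10(0.5e-6),
               tolerance = 1e-12)
  expect_equal(round(log_hit_rates(mk(0, 1e6))["s", "tA"], 2), -6.3)
  vals <- vapply(c(0, 1, 5, 50), function(k)
    log_hit_rates(mk(k, 1e6))["s", "tA"], 0)
  expect_true(all(diff(vals) > 0))
})

test_that("the overrepresentation screen retains only the spiked taxon on synthetic data", {
  st <- fixture_study()
  screened <- list(); hq <- c()
  for (sid in names(st$reads)) {
    sc <- screen_reads(st$reads[[sid]], st$genome, st$host_transcripts)
    screened[[sid]] <- sc$screened_reads
    hq[sid] <- sc$summary$hq_reads
  }
  hits <- lapply(screened, seed_and_extend,
                 viral_refs = st$viral_refs$records)
  tab <- tabulate_vhr(hits, st$viral_refs$taxa, hq)
  scr <- screen_overrepresented_taxa(tab, st$design)
  expect_true(scr$retained[scr$taxon == st$viral_refs$exogenous_taxon])
  expect_false(any(scr$retained[scr$taxon != st$viral_refs$exogenous_taxon]))
  # permuting specimen order permutes rows identically
  perm <- rev(names(hits))
  tab2 <- tabulate_vhr(hits[perm], st$viral_refs$taxa, hq)
  expect_equal(tab2$vhr, tab$vhr[perm, ])
})

test_that("z-screen edge cases: equality with control mean never retains; extreme case does", {
  taxa <- data.frame(record_id = "v1", taxon = "tA")
  vhr <- matrix(c(rep(1e-6, 4), 1e-6, 1e-4), ncol = 1,
                dimnames = list(c(paste0("c", 1:4), "d1", "d2"), "tA"))
  tab <- structure(list(vhr = vhr, counts = (vhr > 0) * 1L,
                        hq = setNames(rep(1e6, 6), rownames(vhr))),
                   class = "hervex_vhr")
  design <- data.frame(specimen_id = rownames(vhr),
                       group = c(rep("control", 4), "demyelination",
                                 "demyelination"))
  scr <- screen_overrepresented_taxa(tab, design)
  expect_true(scr$retained[1])
  expect_true(scr$degenerate[1]) # sd over controls is 0 here, case deviates
  vhr2 <- vhr; vhr2["d2", ] <- 1e-6
  tab2 <- structure(list(vhr = vhr2, counts = (vhr2 > 0) * 1L,
                         hq = tab$hq), class = "hervex_vhr")
  scr2 <- screen_overrepresented_taxa(tab2, design)
  expect_false(scr2$retained[1])
})
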