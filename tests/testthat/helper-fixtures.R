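# Shared fixtures, built once per test run. Scales are desk-sized: a 30 kb
# genome, 3 domain types, 10 specimens, a few thousand reads each.

.fixture_cache <- new.env(parent = emptyenv())

fixture_config <- function() {
  simulation_config(
    seed = 42L,
    n_per_group = c(demyelination = 4L, control = 4L, OND = 2L),
    reads_per_specimen = 3000L,
    host_genome_length = 30000L,
    n_loci_per_domain = 2L,
    domain_types = c("GAG", "ENV", "RT"),
    effect_ratios = c(GAG = 2.5, ENV = 1.7, RT = 1.7),
    proteins_per_domain = 1L,
    exogenous_viral_fraction_ond = 0.01)
}

fixture_study <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- simulate_study(fixture_config())
  }
  .fixture_cache$study
}

fixture_catalog <- function() {
  if (is.null(.fixture_cache$catalog)) {
    st <- fixture_study()
    .fixture_cache$catalog <- build_catalog_from_genome(
      seq_records("host_genome", st$genome), st$proteins)
  }
  .fixture_cache$catalog
}

# random read set helper for counting-scheme property tests
random_reads <- function(n, len = 50L, seed = 1L) {
  set.seed(seed)
  seq_records(sprintf("r%04d", seq_len(n)),
              vapply(seq_len(n), function(i)
                paste(sample(c("A", "C", "G", "T"), len, TRUE),
                      collapse = ""), ""),
              qual = strrep("I", len))
}

# brute-force end-to-end alignment oracle: every offset, both strands
oracle_align <- function(reads, entries, max_mm) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    for (j in seq_len(nrow(entries))) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") reads$seq[i] else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(reads$seq[i])))
        L <- nchar(q); S <- entries$seq[j]
        if (nchar(S) < L) next
        for (off in 0:(nchar(S) - L)) {
          mm <- sum(strsplit(q, "")[[1]] !=
                      strsplit(substr(S, off + 1, off + L), "")[[1]])
          if (mm <= max_mm) {
            out[[length(out) + 1L]] <- data.frame(
              read_id = reads$id[i], entry_code = entries$id[j],
              pos = off, strand = strand, mismatches = mm,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0L) return(data.frame())
  do.call(rbind, out)
}
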