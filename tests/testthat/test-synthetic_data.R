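# Synthetic-data generator: determinism, construction invariants,
# provenance completeness, and parameter recovery against ground truth.

small_cfg <- function(seed = 1L, ...) {
  simulation_config(seed = seed,
                    n_per_group = c(demyelination = 2L, control = 2L,
                                    OND = 1L),
                    reads_per_specimen = 1000L,
                    host_genome_length = 12000L,
                    n_loci_per_domain = 1L,
                    domain_types = c("GAG", "ENV"),
                    effect_ratios = c(GAG = 2.0, ENV = 1.7),
                    proteins_per_domain = 1L, ...)
}

test_that("config validation rejects degenerate values", {
  expect_error(simulation_config(reads_per_specimen = 0), "> 0")
  expect_error(simulation_config(base_error_rate = 1.5), "probabilities")
  expect_error(simulation_config(effect_ratios = c(GAG = 1)),
               "effect_ratios missing")
  expect_error(simulation_config(domain_types = character(0)),
               "at least one")
})

test_that("host genome simulation is deterministic, seed-sensitive, and bounded", {
  cfg <- small_cfg()
  g1 <- simulate_host_genome(cfg)
  g2 <- simulate_host_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), cfg$host_genome_length)
  expect_true(all(strsplit(substr(g1, 1, 1000), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g3 <- simulate_host_genome(small_cfg(seed = 2L))
  expect_false(identical(g1, g3))
  expect_error(simulate_host_genome(
    simulation_config(host_genome_length = 500)), ">= 1000")
})

test_that("domain proteins: counts, labels, alphabet, determinism", {
  cfg <- simulation_config(domain_types = c("GAG", "ENV", "RT"),
                           proteins_per_domain = 2L)
  pr <- simulate_domain_proteins(cfg)
  expect_equal(nrow(pr), 6)
  expect_equal(sort(unique(pr$domain_type)), c("ENV", "GAG", "RT"))
  aa <- strsplit(paste(pr$seq, collapse = ""), "")[[1]]
  expect_true(all(aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  lens <- nchar(pr$seq)
  expect_true(all(lens >= 80 & lens <= 400))
  expect_identical(pr, simulate_domain_proteins(cfg))
})

test_that("planted loci are non-overlapping, recorded, and translate back at zero divergence", {
  cfg <- small_cfg()
  g <- simulate_host_genome(cfg)
  pr <- simulate_domain_proteins(cfg)
  pl <- plant_erv_loci(g, pr, cfg)
  loci <- pl$loci[order(pl$loci$start), ]
  expect_equal(nrow(loci), 2)
  expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
  expect_true(all(loci$end <= nchar(pl$genome)))
  expect_equal(nchar(pl$genome), nchar(g))

  cfg0 <- small_cfg(aa_divergence = 0)
  pl0 <- plant_erv_loci(simulate_host_genome(cfg0),
                        simulate_domain_proteins(cfg0), cfg0)
  for (i in seq_len(nrow(pl0$loci))) {
    lo <- pl0$loci[i, ]
    nt <- substr(pl0$genome, lo$start, lo$end)
    if (lo$strand == "-") {
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    }
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    src <- simulate_domain_proteins(cfg0)
    expect_equal(aa, src$seq[src$protein_id == lo$protein_id])
  }
})

test_that("planting fails loudly when the genome is too small", {
  cfg <- simulation_config(host_genome_length = 1000L,
                           n_loci_per_domain = 3L)
  g <- simulate_host_genome(cfg)
  pr <- simulate_domain_proteins(cfg)
  expect_error(plant_erv_loci(g, pr, cfg), "insufficient genome space")
})

test_that("read simulation conserves counts and records complete provenance", {
  st <- simulate_study(small_cfg())
  for (r in st$reads) expect_equal(nrow(r), 1000)
  expect_equal(nrow(st$provenance), 5 * 1000)
  expect_equal(anyDuplicated(st$provenance$read_id), 0L)
  all_ids <- unlist(lapply(st$reads, `[[`, "id"), use.names = FALSE)
  expect_setequal(st$provenance$read_id, all_ids)
  expect_true(all(nchar(st$reads[[1]]$seq) == 50))
})

test_that("identical config and seed reproduce the study byte-for-byte", {
  s1 <- simulate_study(small_cfg(seed = 5L))
  s2 <- simulate_study(small_cfg(seed = 5L))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$provenance, s2$provenance)
  s3 <- simulate_study(small_cfg(seed = 6L))
  expect_false(identical(s1$reads, s3$reads))
})

test_that("zero exogenous fraction yields zero exogenous OND reads", {
  st <- simulate_study(small_cfg(exogenous_viral_fraction_ond = 0))
  expect_equal(sum(st$provenance$source == "exogenous"), 0L)
  st2 <- simulate_study(small_cfg(exogenous_viral_fraction_ond = 0.05))
  exo <- st2$provenance[st2$provenance$source == "exogenous", ]
  expect_gt(nrow(exo), 0)
  ond_ids <- st2$design$specimen_id[st2$design$group == "OND"]
  expect_true(all(exo$specimen_id %in% ond_ids))
})

test_that("unknown group labels in the design are rejected", {
  cfg <- small_cfg()
  st <- simulate_study(cfg)
  bad_design <- st$design
  bad_design$group[1] <- "mystery"
  expect_error(simulate_reads(st$genome, st$loci, bad_design, cfg,
                              st$viral_refs), "unknown group")
})

test_that("per-domain group expression ratios are recovered within 3 SE", {
  cfg <- simulation_config(
    seed = 31L, n_per_group = c(demyelination = 1L, control = 1L, OND = 1L),
    reads_per_specimen = 50000L, host_genome_length = 15000L,
    n_loci_per_domain = 1L, domain_types = c("GAG", "ENV"),
    effect_ratios = c(GAG = 2.0, ENV = 1.7), proteins_per_domain = 1L)
  st <- simulate_study(cfg)
  prov <- merge(st$provenance, st$design[c("specimen_id", "group")])
  loc_dom <- setNames(st$loci$domain_type, st$loci$locus_id)
  n <- cfg$reads_per_specimen
  for (dom in c("GAG", "ENV")) {
    frac <- function(grp) {
      sum(prov$group == grp & prov$source %in%
            names(loc_dom)[loc_dom == dom]) / n
    }
    p_ctrl_true <- st$expected_fractions$control[
      st$expected_fractions$domain_type == dom]
    ratio_true <- unname(cfg$effect_ratios[dom])
    p_case_true <- p_ctrl_true * ratio_true
    fd <- frac("demyelination"); fc <- frac("control")
    ratio_hat <- fd / fc
    # delta-method SE of the ratio of two binomial proportions
    se <- ratio_true * sqrt(p_case_true * (1 - p_case_true) /
                              (n * p_case_true^2) +
                            p_ctrl_true * (1 - p_ctrl_true) /
                              (n * p_ctrl_true^2))
    expect_lt(abs(ratio_hat - ratio_true), 3 * se)
  }
})

test_that("written simulation files load back consistently", {
  st <- simulate_study(small_cfg())
  dir <- withr::local_tempdir()
  write_simulation(st, dir)
  genome <- read_fasta(file.path(dir, "host_genome.fasta"))
  expect_equal(genome$seq, st$genome)
  reads <- read_fastq(file.path(dir, sprintf("%s.fastq",
                                             st$design$specimen_id[1])))
  expect_equal(reads$seq, st$reads[[1]]$seq)
  loci <- read_tsv_table(file.path(dir, "loci.tsv"))
  expect_equal(loci$start, st$loci$start)
})
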