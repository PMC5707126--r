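# Synthetic study generator. Emulates the structure of the sequencing study
# the pipeline targets: three specimen groups (demyelination-like, normal
# control, other-neurologic-disease), 50 nt single-end reads drawn from a
# host genome background, endogenous-retrovirus-like loci planted into the
# host genome and expressed with small multiplicative group effects, and an
# exogenous virus spiked into the OND-like group. Every read carries a
# recorded provenance label so downstream stages can be tested against
# ground truth.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Defaults state the simulated world: group sizes 14/14/7, 50 nt single-end
#' reads, a 200 kb host genome at human-like 41% GC, nine retroviral domain
#' types, and demyelination-group expression ratios in the 1.5-2.8 range.
#' `reads_per_specimen` defaults to a desk-scale 100,000 (the study it
#' emulates sequenced tens of millions); tests and examples scale it down
#' further via this argument.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   byte-identical outputs.
#' @param n_per_group named integer vector: specimens per group.
#' @param read_length read length in nt.
#' @param reads_per_specimen reads simulated per specimen.
#' @param host_genome_length host genome length in nt.
#' @param n_loci_per_domain ERV-like loci planted per domain type.
#' @param domain_types retroviral domain-type labels.
#' @param effect_ratios named multiplicative expression ratios applied to
#'   ERV loci in the demyelination group (one per domain type).
#' @param base_error_rate per-base substitution error probability.
#' @param exogenous_viral_fraction_ond fraction of OND-group reads drawn
#'   from the spiked exogenous virus.
#' @param aa_divergence amino-acid divergence of planted loci from their
#'   source domain proteins.
#' @param proteins_per_domain domain proteins simulated per type.
#' @param protein_length_range min/max protein length (aa).
#' @param host_gc host genome GC content.
#' @param erv_base_fraction total fraction of a control specimen's reads
#'   drawn from ERV loci (split evenly across loci).
#' @param low_quality_fraction fraction of reads emitted with uniformly low
#'   (Phred 5) quality, exercising the HQ filter.
#' @param low_quality_phred Phred score assigned to low-quality reads.
#' @param n_decoy_taxa additional random viral taxa in the reference set.
#' @param viral_genome_length length of each simulated viral genome (nt).
#' @return list with class `hervex_sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_per_group = c(demyelination = 14L, control = 14L, OND = 7L),
    read_length = 50L,
    reads_per_specimen = 100000L,
    host_genome_length = 200000L,
    n_loci_per_domain = 3L,
    domain_types = c("GAG", "POL", "RT", "INT", "ENV", "PRO", "CHR",
                     "KRAB", "SCAN"),
    effect_ratios = c(GAG = 2.5, POL = 1.5, RT = 1.7, INT = 1.7, ENV = 1.7,
                      PRO = 1.5, CHR = 1.5, KRAB = 1.8, SCAN = 1.5),
    base_error_rate = 0.005,
    exogenous_viral_fraction_ond = 1e-4,
    aa_divergence = 0.2,
    proteins_per_domain = 2L,
    protein_length_range = c(80L, 400L),
    host_gc = 0.41,
    erv_base_fraction = 0.02,
    low_quality_fraction = 0.02,
    low_quality_phred = 5L,
    n_decoy_taxa = 4L,
    viral_genome_length = 10000L) {
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              read_length = as.integer(read_length),
              reads_per_specimen = as.integer(reads_per_specimen),
              host_genome_length = as.integer(host_genome_length),
              n_loci_per_domain = as.integer(n_loci_per_domain),
              domain_types = domain_types, effect_ratios = effect_ratios,
              base_error_rate = base_error_rate,
              exogenous_viral_fraction_ond = exogenous_viral_fraction_ond,
              aa_divergence = aa_divergence,
              proteins_per_domain = as.integer(proteins_per_domain),
              protein_length_range = as.integer(protein_length_range),
              host_gc = host_gc, erv_base_fraction = erv_base_fraction,
              low_quality_fraction = low_quality_fraction,
              low_quality_phred = as.integer(low_quality_phred),
              n_decoy_taxa = as.integer(n_decoy_taxa),
              viral_genome_length = as.integer(viral_genome_length))
  class(cfg) <- "hervex_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_per_group, cfg$read_length, cfg$reads_per_specimen,
              cfg$host_genome_length, cfg$n_loci_per_domain,
              cfg$proteins_per_domain, cfg$viral_genome_length)
  if (any(counts <= 0)) stop("all counts in the simulation config must be > 0")
  if (length(cfg$domain_types) < 1L) stop("at least one domain type required")
  missing_ratio <- setdiff(cfg$domain_types, names(cfg$effect_ratios))
  if (length(missing_ratio)) {
    stop("effect_ratios missing for domain type(s): ",
         paste(missing_ratio, collapse = ", "))
  }
  if (any(cfg$effect_ratios <= 0)) stop("effect ratios must be > 0")
  probs <- c(cfg$base_error_rate, cfg$exogenous_viral_fraction_ond,
             cfg$aa_divergence, cfg$host_gc, cfg$erv_base_fraction,
             cfg$low_quality_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!all(names(cfg$n_per_group) %in% c("demyelination", "control", "OND"))) {
    stop("group names must be demyelination, control, OND")
  }
  invisible(cfg)
}

random_dna <- function(n, gc = 0.41) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Simulate the host genome
#'
#' A random nucleotide sequence over A/C/G/T at the configured GC content.
#'
#' @param config a [simulation_config()].
#' @return single character string.
#' @export
simulate_host_genome <- function(config) {
  validate_sim_config(config)
  if (config$host_genome_length < 1000L) {
    stop("host genome length must be >= 1000 nt (too small to host loci)")
  }
  set.seed(derive_seed(config$seed, "host_genome"))
  random_dna(config$host_genome_length, config$host_gc)
}

#' Simulate the retroviral domain-protein set
#'
#' One or more random amino-acid sequences (80-400 aa) per domain type, each
#' labeled with its domain type and a stand-in recognition-domain name.
#'
#' @param config a [simulation_config()].
#' @return data.frame: `protein_id`, `domain_type`, `recognition_domain`,
#'   `seq`.
#' @export
simulate_domain_proteins <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "domain_proteins"))
  rng <- config$protein_length_range
  rows <- list()
  for (dt in config$domain_types) {
    for (j in seq_len(config$proteins_per_domain)) {
      len <- sample(rng[1]:rng[2], 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = sprintf("%s_p%d", dt, j),
        domain_type = dt,
        recognition_domain = sprintf("RD-%s-%d", dt, j),
        seq = paste(sample(AA_LETTERS, len, replace = TRUE), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Uniform-codon back-translation of an amino-acid sequence.
back_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(gc), unname(gc))
  letters <- strsplit(aa, "")[[1]]
  paste(vapply(letters, function(a) {
    cands <- codons_by_aa[[a]]
    if (is.null(cands)) stop("cannot back-translate letter: ", a)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, ""), collapse = "")
}

mutate_protein <- function(aa, divergence) {
  letters <- strsplit(aa, "")[[1]]
  hit <- stats::runif(length(letters)) < divergence
  for (i in which(hit)) {
    letters[i] <- sample(setdiff(AA_LETTERS, letters[i]), 1L)
  }
  paste(letters, collapse = "")
}

#' Plant ERV-like loci into the host genome
#'
#' Each locus is a back-translation of a (mutated) domain protein, written
#' over a non-overlapping stretch of the genome on a random strand. Locus
#' coordinates, domain type, strand and source protein are recorded as
#' ground truth.
#'
#' @param genome host genome string from [simulate_host_genome()].
#' @param proteins protein set from [simulate_domain_proteins()].
#' @param config a [simulation_config()].
#' @param margin minimum spacing (nt) between loci and from genome ends.
#' @return list: `genome` (modified string), `loci` (data.frame with
#'   `locus_id`, `domain_type`, `protein_id`, `start`, `end` (1-based,
#'   inclusive), `strand`, `length`).
#' @export
plant_erv_loci <- function(genome, proteins, config, margin = 150L) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "plant_loci"))
  plan <- list()
  for (dt in config$domain_types) {
    cand <- proteins[proteins$domain_type == dt, , drop = FALSE]
    if (nrow(cand) == 0L) stop("no proteins for domain type ", dt)
    for (j in seq_len(config$n_loci_per_domain)) {
      prot <- cand[((j - 1L) %% nrow(cand)) + 1L, ]
      aa <- mutate_protein(prot$seq, config$aa_divergence)
      nt <- back_translate(aa)
      plan[[length(plan) + 1L]] <- list(
        locus_id = sprintf("%s_L%d", dt, j), domain_type = dt,
        protein_id = prot$protein_id, nt = nt)
    }
  }
  lens <- vapply(plan, function(p) nchar(p$nt), 0L)
  n <- length(plan)
  L <- nchar(genome)
  need <- sum(lens) + (n + 1L) * margin
  if (need > L) {
    stop(sprintf("insufficient genome space for loci: need %d nt, have %d nt",
                 need, L))
  }
  # distribute the slack randomly over the n+1 gaps, preserving order
  extra <- L - sum(lens) - (n + 1L) * margin
  cuts <- sort(sample.int(extra + 1L, n + 1L, replace = TRUE) - 1L)
  gaps <- c(margin + cuts[1], margin + diff(cuts))
  ord <- sample.int(n) # random genomic order of loci
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[ord[i]] <- pos + 1L
    pos <- pos + lens[ord[i]]
  }
  strands <- sample(c("+", "-"), n, replace = TRUE)
  for (i in seq_len(n)) {
    insert <- if (strands[i] == "+") plan[[i]]$nt else
      reverse_complement(plan[[i]]$nt)
    substr(genome, starts[i], starts[i] + lens[i] - 1L) <- insert
  }
  loci <- data.frame(
    locus_id = vapply(plan, `[[`, "", "locus_id"),
    domain_type = vapply(plan, `[[`, "", "domain_type"),
    protein_id = vapply(plan, `[[`, "", "protein_id"),
    start = starts, end = starts + lens - 1L, strand = strands,
    length = lens, stringsAsFactors = FALSE)
  if (any(loci$start[order(loci$start)][-1] <=
          loci$end[order(loci$start)][-nrow(loci)])) {
    stop("internal error: overlapping loci") # defensive; should not happen
  }
  list(genome = genome, loci = loci)
}

#' Simulate the viral reference set
#'
#' One random exogenous "viral genome" (the OND spike-in) plus a handful of
#' decoy taxa, with a record-to-taxon map. Entirely synthetic: no real
#' pathogen sequence is embedded.
#'
#' @param config a [simulation_config()].
#' @return list: `records` ([seq_records]), `taxa` (data.frame `record_id`,
#'   `taxon`), `exogenous_taxon` (label of the spiked taxon).
#' @export
simulate_viral_refs <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "viral_refs"))
  ids <- c("exo_virus_1",
           sprintf("decoy_virus_%d", seq_len(config$n_decoy_taxa)))
  taxa <- c("Exogenous synthetic virus",
            sprintf("Decoy taxon %d", seq_len(config$n_decoy_taxa)))
  seqs <- vapply(seq_along(ids), function(i)
    random_dna(config$viral_genome_length, 0.45), "")
  list(records = seq_records(ids, seqs, desc = taxa),
       taxa = data.frame(record_id = ids, taxon = taxa,
                         stringsAsFactors = FALSE),
       exogenous_taxon = taxa[1])
}

#' Simulate the specimen design table
#'
#' Specimen ids, group labels and demographic stand-ins (diagnosis, age,
#' sex, post-mortem interval, collection year) mirroring the structure of
#' the study's specimen table.
#'
#' @param config a [simulation_config()].
#' @return data.frame with one row per specimen.
#' @export
simulate_design <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "design"))
  n <- config$n_per_group
  mk <- function(prefix, k) sprintf("%s%02d", prefix, seq_len(k))
  ids <- c(mk("D", n[["demyelination"]]), mk("C", n[["control"]]),
           mk("O", n[["OND"]]))
  group <- rep(names(n), n)
  diagnosis <- character(length(ids))
  nd <- n[["demyelination"]]
  dx <- rep("PPMS", nd)            # 11 PPMS / 1 SPMS / 2 NMO at nd = 14
  if (nd >= 2L) dx[nd] <- "NMO"
  if (nd >= 3L) dx[nd - 1L] <- "NMO"
  if (nd >= 4L) dx[nd - 2L] <- "SPMS"
  diagnosis[group == "demyelination"] <- dx
  diagnosis[group == "control"] <- "normal"
  diagnosis[group == "OND"] <- "encephalitis"
  age_mean <- c(demyelination = 58, control = 71, OND = 70)
  age <- round(stats::rnorm(length(ids), age_mean[group], 12))
  age <- pmin(pmax(age, 30), 95)
  sex <- sample(c("F", "M"), length(ids), replace = TRUE)
  pmi <- round(stats::runif(length(ids), 2, 26))
  year <- sample(1981:2010, length(ids), replace = TRUE)
  data.frame(specimen_id = ids, group = group, diagnosis = diagnosis,
             age = age, sex = sex, pmi = pmi, collection_year = year,
             stringsAsFactors = FALSE)
}

#' Simulate per-specimen sequencing reads
#'
#' Reads are drawn per specimen from three sources: host background, planted
#' ERV loci (each locus expressed at `erv_base_fraction / n_loci`, scaled by
#' the domain's effect ratio in the demyelination group), and -- for OND
#' specimens -- the exogenous virus. Substitution errors are applied at
#' `base_error_rate`; a `low_quality_fraction` of reads receive uniformly
#' low Phred scores to exercise the quality filter.
#'
#' @param genome (modified) host genome string.
#' @param loci locus ground truth from [plant_erv_loci()].
#' @param design design table from [simulate_design()].
#' @param config a [simulation_config()].
#' @param viral_refs viral reference list from [simulate_viral_refs()].
#' @return list: `reads` (named list of [seq_records], one per specimen),
#'   `provenance` (data.frame `read_id`, `specimen_id`, `source` where
#'   source is `host`, a locus id, or `exogenous`).
#' @export
simulate_reads <- function(genome, loci, design, config, viral_refs) {
  validate_sim_config(config)
  bad <- setdiff(unique(design$group), c("demyelination", "control", "OND"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  rl <- config$read_length
  exo_seq <- viral_refs$records$seq[1]
  n_loci <- nrow(loci)
  base_w <- config$erv_base_fraction / n_loci
  reads_out <- list()
  prov_out <- list()
  for (si in seq_len(nrow(design))) {
    sid <- design$specimen_id[si]
    grp <- design$group[si]
    set.seed(derive_seed(config$seed, paste0("reads_", sid)))
    w_loci <- rep(base_w, n_loci)
    if (grp == "demyelination") {
      w_loci <- w_loci * unname(config$effect_ratios[loci$domain_type])
    }
    w_exo <- if (grp == "OND") config$exogenous_viral_fraction_ond else 0
    w_host <- 1 - sum(w_loci) - w_exo
    if (w_host <= 0) stop("source fractions exceed 1; lower erv_base_fraction")
    n <- config$reads_per_specimen
    src_idx <- sample.int(n_loci + 2L, n, replace = TRUE,
                          prob = c(w_host, w_loci, w_exo))
    # 1 = host, 2..n_loci+1 = locus, n_loci+2 = exogenous
    starts <- integer(n)
    is_host <- src_idx == 1L
    is_exo <- src_idx == n_loci + 2L
    is_locus <- !is_host & !is_exo
    # host background reads come from non-locus regions: locus coverage is
    # modeled by the locus expression process alone, so that per-locus
    # counts reflect the configured group effects
    allowed <- rep(TRUE, nchar(genome) - rl + 1L)
    for (k in seq_len(n_loci)) {
      lo <- max(1L, loci$start[k] - rl + 1L)
      hi <- min(length(allowed), loci$end[k])
      allowed[lo:hi] <- FALSE
    }
    allowed_pos <- which(allowed)
    starts[is_host] <- allowed_pos[sample.int(length(allowed_pos),
                                              sum(is_host), replace = TRUE)]
    if (any(is_exo)) {
      starts[is_exo] <- sample.int(nchar(exo_seq) - rl + 1L, sum(is_exo),
                                   replace = TRUE)
    }
    if (any(is_locus)) {
      li <- src_idx[is_locus] - 1L
      span <- loci$length[li] - rl
      if (any(span < 0)) stop("locus shorter than read length")
      offs <- floor(stats::runif(sum(is_locus)) * (span + 1L))
      starts[is_locus] <- loci$start[li] + as.integer(offs)
    }
    seqs <- character(n)
    if (any(!is_exo)) {
      seqs[!is_exo] <- substring(genome, starts[!is_exo],
                                 starts[!is_exo] + rl - 1L)
    }
    if (any(is_exo)) {
      seqs[is_exo] <- substring(exo_seq, starts[is_exo],
                                starts[is_exo] + rl - 1L)
    }
    minus <- stats::runif(n) < 0.5
    if (any(minus)) seqs[minus] <- reverse_complement(seqs[minus])
    # substitution errors
    err <- which(stats::runif(n * rl) < config$base_error_rate)
    if (length(err)) {
      ri <- (err - 1L) %/% rl + 1L
      pp <- (err - 1L) %% rl + 1L
      for (k in seq_along(err)) {
        old <- substr(seqs[ri[k]], pp[k], pp[k])
        substr(seqs[ri[k]], pp[k], pp[k]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
    lowq <- stats::runif(n) < config$low_quality_fraction
    hi_char <- rawToChar(as.raw(37L + 33L))
    lo_char <- rawToChar(as.raw(config$low_quality_phred + 33L))
    qual <- ifelse(lowq, strrep(lo_char, rl), strrep(hi_char, rl))
    ids <- sprintf("%s_r%06d", sid, seq_len(n))
    reads_out[[sid]] <- seq_records(ids, seqs, qual = qual)
    src_lab <- c("host", loci$locus_id, "exogenous")[src_idx]
    prov_out[[sid]] <- data.frame(read_id = ids, specimen_id = sid,
                                  source = src_lab, stringsAsFactors = FALSE)
  }
  list(reads = reads_out, provenance = do.call(rbind, prov_out))
}

#' Simulate the complete study
#'
#' Orchestrates all generators: host genome, domain proteins, planted loci,
#' viral references, design table, host transcript stand-ins and reads.
#'
#' @param config a [simulation_config()].
#' @return list with components `config`, `genome` (modified), `proteins`,
#'   `loci`, `viral_refs`, `design`, `host_transcripts`, `reads`,
#'   `provenance`, and `expected_fractions` (per locus and group, the
#'   expected read fraction -- the recovery target for ratio tests).
#' @export
simulate_study <- function(config = simulation_config()) {
  genome0 <- simulate_host_genome(config)
  proteins <- simulate_domain_proteins(config)
  planted <- plant_erv_loci(genome0, proteins, config)
  viral_refs <- simulate_viral_refs(config)
  design <- simulate_design(config)
  set.seed(derive_seed(config$seed, "transcripts"))
  # transcript stand-ins: genome slices (the screen treats them like cDNA)
  tx_start <- sample.int(nchar(planted$genome) - 2000L, 5L)
  tx <- seq_records(sprintf("tx_%d", seq_len(5L)),
                    substring(planted$genome, tx_start, tx_start + 1999L))
  sim <- simulate_reads(planted$genome, planted$loci, design, config,
                        viral_refs)
  base_w <- config$erv_base_fraction / nrow(planted$loci)
  ratios <- unname(config$effect_ratios[planted$loci$domain_type])
  expected <- data.frame(
    locus_id = planted$loci$locus_id,
    domain_type = planted$loci$domain_type,
    control = base_w, OND = base_w,
    demyelination = base_w * ratios, stringsAsFactors = FALSE)
  list(config = config, genome = planted$genome, proteins = proteins,
       loci = planted$loci, viral_refs = viral_refs, design = design,
       host_transcripts = tx, reads = sim$reads,
       provenance = sim$provenance, expected_fractions = expected)
}

#' Write a simulated study to disk
#'
#' Standard formats only: FASTA (genome, proteins, transcripts, viral refs),
#' FASTQ per specimen, TSV (design, taxa, locus ground truth) and a JSON
#' ground-truth summary.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  p <- file.path(dir, "host_genome.fasta")
  write_fasta(seq_records("host_genome", study$genome), p); paths <- c(paths, p)
  p <- file.path(dir, "domain_proteins.fasta")
  write_fasta(seq_records(study$proteins$protein_id, study$proteins$seq,
                          desc = sprintf("domain_type=%s recognition=%s",
                                         study$proteins$domain_type,
                                         study$proteins$recognition_domain)),
              p); paths <- c(paths, p)
  p <- file.path(dir, "host_transcripts.fasta")
  write_fasta(study$host_transcripts, p); paths <- c(paths, p)
  p <- file.path(dir, "viral_refs.fasta")
  write_fasta(study$viral_refs$records, p); paths <- c(paths, p)
  p <- file.path(dir, "viral_taxa.tsv")
  write_tsv_table(study$viral_refs$taxa, p); paths <- c(paths, p)
  p <- file.path(dir, "design.tsv")
  write_tsv_table(study$design, p); paths <- c(paths, p)
  p <- file.path(dir, "loci.tsv")
  write_tsv_table(study$loci, p); paths <- c(paths, p)
  p <- file.path(dir, "provenance.tsv")
  write_tsv_table(study$provenance, p); paths <- c(paths, p)
  for (sid in names(study$reads)) {
    p <- file.path(dir, sprintf("%s.fastq", sid))
    write_fastq(study$reads[[sid]], p); paths <- c(paths, p)
  }
  p <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(seed = study$config$seed,
         loci = study$loci, expected_fractions = study$expected_fractions),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
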