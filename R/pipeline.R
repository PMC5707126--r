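# End-to-end orchestration: simulate (or load) inputs, screen reads, run
# the viral hit-rate screen, build the catalog, quantify catalog expression
# under both counting schemes, run the domain discrimination analysis and
# the group statistics, and emit a manifest plus a human-readable report.
#
# Stage wiring note: the viral screen consumes *screened* reads (host
# subtraction removes everything of host origin before the viral database
# is searched), while catalog quantification consumes *HQ* reads -- catalog
# entries are host-genome loci, so host subtraction would remove exactly
# the reads being quantified.

#' Pipeline configuration
#'
#' @param sim a [simulation_config()] for the synthetic study.
#' @param screening a [screening_config()].
#' @param expect_cutoff,min_coverage catalog builder settings.
#' @param word_size,min_identity,min_length viral search settings.
#' @param max_mismatches,kmer catalog alignment settings.
#' @param grouping `"demyelination"` or `"ppms"` for the expression
#'   comparison.
#' @param run_viral_search,run_catalog stage toggles.
#' @param out_dir optional output directory; when given, all stage outputs
#'   are written as TSV/FASTA/JSON with an md5 manifest.
#' @return list with class `hervex_pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            screening = screening_config(),
                            expect_cutoff = 0.1, min_coverage = 0.5,
                            word_size = 28L, min_identity = 0.9,
                            min_length = 40L, max_mismatches = 3L,
                            kmer = 12L,
                            grouping = "demyelination",
                            run_viral_search = TRUE, run_catalog = TRUE,
                            out_dir = NULL) {
  structure(list(sim = sim, screening = screening,
                 expect_cutoff = expect_cutoff, min_coverage = min_coverage,
                 word_size = word_size, min_identity = min_identity,
                 min_length = min_length, max_mismatches = max_mismatches,
                 kmer = kmer, grouping = grouping,
                 run_viral_search = run_viral_search,
                 run_catalog = run_catalog, out_dir = out_dir),
            class = "hervex_pipeline_config")
}

#' Run the full pipeline on a synthetic study
#'
#' Executes: synthetic data generation, per-specimen screening, the viral
#' hit-rate screen (optional), catalog construction (optional -- a
#' pre-built catalog may be supplied), dual-scheme catalog quantification
#' with group comparison, and the domain discrimination analysis.
#'
#' @param config a [pipeline_config()].
#' @param study optional pre-generated [simulate_study()] output (the
#'   config's `sim` is ignored then).
#' @param catalog optional pre-built catalog (used when
#'   `run_catalog = FALSE`).
#' @param verbose emit one structured log line per stage.
#' @return list with class `hervex_run`: `study`, `screening` (summary
#'   data.frame), `vhr`, `taxa_screen`, `catalog`, `expression`,
#'   `comparison_best`, `comparison_comprehensive`, `profile`, `split`,
#'   `report` (character vector), `manifest` (data.frame or NULL).
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         catalog = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(study)) {
    say("stage=simulate seed=%d", config$sim$seed)
    study <- simulate_study(config$sim)
  }
  specimens <- names(study$reads)

  say("stage=screen specimens=%d", length(specimens))
  hq_reads <- list(); screened <- list(); summaries <- list()
  for (sid in specimens) {
    sc <- screen_reads(study$reads[[sid]], study$genome,
                       study$host_transcripts, config$screening)
    hq_reads[[sid]] <- sc$hq_reads
    screened[[sid]] <- sc$screened_reads
    summaries[[sid]] <- cbind(specimen_id = sid, sc$summary)
  }
  screening_summary <- do.call(rbind, summaries)
  rownames(screening_summary) <- NULL
  hq_counts <- stats::setNames(screening_summary$hq_reads,
                               screening_summary$specimen_id)

  vhr <- NULL; taxa_screen <- NULL
  if (isTRUE(config$run_viral_search)) {
    say("stage=viral_search refs=%d", nrow(study$viral_refs$records))
    hits <- lapply(screened, seed_and_extend,
                   viral_refs = study$viral_refs$records,
                   word_size = config$word_size,
                   min_identity = config$min_identity,
                   min_length = config$min_length)
    vhr <- tabulate_vhr(hits, study$viral_refs$taxa, hq_counts)
    taxa_screen <- screen_overrepresented_taxa(vhr, study$design)
  }

  if (isTRUE(config$run_catalog) || is.null(catalog)) {
    say("stage=build_catalog genome_nt=%d", nchar(study$genome))
    catalog <- build_catalog_from_genome(
      seq_records("host_genome", study$genome), study$proteins,
      expect_cutoff = config$expect_cutoff,
      min_coverage = config$min_coverage)
  }
  if (nrow(catalog$table) == 0L) stop("catalog construction produced no entries")

  say("stage=quantify entries=%d", nrow(catalog$table))
  expr <- quantify_expression(hq_reads, catalog,
                              max_mismatches = config$max_mismatches,
                              kmer = config$kmer)
  cmp_best <- group_compare(expr$fpkm_best, catalog$table, study$design,
                            grouping = config$grouping)
  cmp_comp <- group_compare(expr$fpkm_comprehensive, catalog$table,
                            study$design, grouping = config$grouping)

  say("stage=discriminate")
  rates <- domain_hit_rates(expr$counts_comprehensive, catalog$table,
                            hq_counts)
  pc <- 0.5 / stats::median(as.numeric(hq_counts))
  profile <- log2_center(rates, pc)
  hc <- cluster_specimens(profile)
  split <- split_and_test(hc, study$design,
                          c("demyelination", "control"))

  report <- build_report(study, screening_summary, taxa_screen, cmp_best,
                         cmp_comp, split)
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_run_outputs(config$out_dir, study, screening_summary,
                                  vhr, taxa_screen, catalog, expr,
                                  cmp_best, cmp_comp, profile, split,
                                  report)
  }
  structure(list(study = study, screening = screening_summary, vhr = vhr,
                 taxa_screen = taxa_screen, catalog = catalog,
                 expression = expr, comparison_best = cmp_best,
                 comparison_comprehensive = cmp_comp, profile = profile,
                 split = split, report = report, manifest = manifest),
            class = "hervex_run")
}

build_report <- function(study, screening_summary, taxa_screen, cmp_best,
                         cmp_comp, split) {
  lines <- c("== Specimen groups ==")
  tab <- table(study$design$group)
  lines <- c(lines, sprintf("  %s: n=%d", names(tab), as.integer(tab)),
             sprintf("  mean HQ reads: %s",
                     paste(sprintf("%s=%.0f", names(tab),
                                   tapply(screening_summary$hq_reads,
                                          study$design$group[
                                            match(screening_summary$specimen_id,
                                                  study$design$specimen_id)],
                                          mean)[names(tab)]),
                           collapse = ", ")))
  lines <- c(lines, "", "== Viral hit-rate screen ==")
  if (is.null(taxa_screen)) {
    lines <- c(lines, "  (stage disabled)")
  } else {
    kept <- taxa_screen$taxon[taxa_screen$retained]
    lines <- c(lines, sprintf("  retained taxa (%d): %s", length(kept),
                              if (length(kept)) paste(kept, collapse = "; ")
                              else "none"))
  }
  fmt_cmp <- function(cmp) {
    sig <- cmp[cmp$significant & !is.na(cmp$ratio) & cmp$ratio > 1, ]
    if (nrow(sig) == 0L) return("  no significantly overexpressed entries")
    sprintf("  %s (%s): ratio=%.2f p=%.2g q=%.3f", sig$entry_code,
            sig$domain_type, sig$ratio, sig$p, sig$q)
  }
  lines <- c(lines, "", "== Expression, best alignment ==",
             fmt_cmp(cmp_best),
             "", "== Expression, comprehensive alignment ==",
             fmt_cmp(cmp_comp),
             "", "== Domain discrimination ==",
             utils::capture.output(print(split)))
  lines
}

write_run_outputs <- function(dir, study, screening_summary, vhr,
                              taxa_screen, catalog, expr, cmp_best,
                              cmp_comp, profile, split, report) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(obj, name, writer = write_tsv_table) {
    p <- file.path(dir, name)
    writer(obj, p)
    paths <<- c(paths, p)
  }
  w(screening_summary, "screening_summary.tsv")
  if (!is.null(vhr)) {
    w(data.frame(specimen_id = rownames(vhr$vhr), vhr$vhr,
                 check.names = FALSE), "vhr.tsv")
    w(data.frame(specimen_id = rownames(vhr$vhr), log_hit_rates(vhr),
                 check.names = FALSE), "log_hit_rates.tsv")
    w(taxa_screen, "taxa_screen.tsv")
  }
  w(catalog$records, "catalog.fasta", write_fasta)
  w(catalog$table, "catalog.tsv")
  w(data.frame(entry_code = rownames(expr$fpkm_best), expr$fpkm_best,
               check.names = FALSE), "fpkm_best.tsv")
  w(data.frame(entry_code = rownames(expr$fpkm_comprehensive),
               expr$fpkm_comprehensive, check.names = FALSE),
    "fpkm_comprehensive.tsv")
  w(cmp_best, "comparison_best.tsv")
  w(cmp_comp, "comparison_comprehensive.tsv")
  w(data.frame(domain_type = rownames(profile), profile,
               check.names = FALSE), "domain_profile.tsv")
  p <- file.path(dir, "cluster_split.json")
  jsonlite::write_json(
    list(left = split$left_members, right = split$right_members,
         contingency = split$contingency, fisher_p = split$fisher_p,
         merge = split$dendrogram$merge,
         height = split$dendrogram$height,
         labels = split$dendrogram$labels),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  p <- file.path(dir, "report.txt")
  writeLines(report, p)
  paths <- c(paths, p)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  write_tsv_table(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

#' @export
print.hervex_run <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
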