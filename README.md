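# hervex

Screening for endogenous retrovirus (HERV) and exogenous viral expression
in short single-end RNA-seq reads from post-mortem brain tissue.

Studies of demyelinating disease repeatedly implicate endogenous
retroviral sequences, but the effects are small (under 3-fold) and spread
across many highly similar loci, which makes them easy to lose in standard
gene-level pipelines. `hervex` implements the complete analysis as a
tested, self-contained R package:

1. **Read screening** — quality filtering to high-quality (HQ) reads
   (mean Phred ≥ 20, ≤ 2 N bases), then host subtraction: reads with an
   end-to-end alignment (≤ 2 substitutions, either strand) to the host
   genome or transcript set are removed, yielding *screened* reads.
2. **Viral hit-rate screen** — screened reads are aligned to a viral
   reference set by exact 28-nt word seeding with ungapped extension
   (identity ≥ 0.9, length ≥ 40 nt). Distinct hit reads per taxon are
   divided by the specimen's HQ count to give the viral hit rate
   `VHR = hits / HQ`; per-specimen overrepresentation against the control
   group is screened with a Bonferroni-corrected Z-test.
3. **Retroviral gene catalog (RVGC)** — the genome is translated in six
   frames, stop-free segments are locally aligned (BLOSUM62, affine gaps)
   against a retroviral protein-domain set, hits with E ≤ 0.1 whose
   alignment length is ≥ 50% of the subject domain are kept, and
   overlapping same-domain hits are union-merged into named nucleotide
   entries (`GAG_U21|K-HERV|src|1200|450`).
4. **Dual-scheme quantification** — reads are aligned end-to-end to the
   catalog (≤ 3 substitutions, all placements reported). *Best Alignment*
   credits each read once, to its best match (ties broken
   lexicographically); *Comprehensive Alignment* credits every reported
   alignment. Expression is reported as
   `FPKM × 1000 = 1000 · count / ((L/1000)(M/10⁶))` with a library-wide
   norm mass `M`. Case/control ratios are tested per entry with the
   Mann-Whitney U test and Benjamini–Hochberg FDR within each domain type.
5. **Domain discrimination** — catalog counts are binned by domain type
   (GAG, RT, INT, ENV, PRO, CHR, KRAB, SCAN, …), normalized by HQ reads,
   log₂-transformed, mean-centered along the domain axis, and the
   specimens are hierarchically clustered (distance `1 − Pearson r`,
   average linkage). The dendrogram's root split is tested for group
   separation with the two-tailed Fisher exact test.

A synthetic-data module generates the whole study — host genome (41% GC),
domain proteins, ERV-like loci planted at 20% amino-acid divergence,
group-structured reads (14 demyelination-like / 14 control / 7 OND-like
specimens by default) with multiplicative domain effects of 1.5–2.8×, and
an exogenous virus spiked into the OND group — with full per-read
provenance, so every stage is tested against known ground truth.

## Worked example

```r
library(hervex)

cfg <- pipeline_config(
  sim = simulation_config(
    seed = 7, n_per_group = c(demyelination = 4, control = 4, OND = 2),
    reads_per_specimen = 2000, host_genome_length = 30000,
    n_loci_per_domain = 2, domain_types = c("GAG", "ENV", "RT"),
    effect_ratios = c(GAG = 2.5, ENV = 1.7, RT = 1.7),
    proteins_per_domain = 1, exogenous_viral_fraction_ond = 0.01))
run <- run_pipeline(cfg)
print(run)
```

prints (abridged):

```
== Specimen groups ==
  control: n=4
  demyelination: n=4
  OND: n=2
  mean HQ reads: control=1958, demyelination=1965, OND=1964

== Viral hit-rate screen ==
  retained taxa (1): Exogenous synthetic virus

== Domain discrimination ==
Cluster split at dendrogram root
              left right
demyelination    3     1
control          2     2
Two-tailed Fisher exact p = 1
```

All six planted loci are recovered as catalog entries
(`run$catalog$table`), and the only taxon passing the overrepresentation
screen is the virus that was actually spiked into the OND specimens. At
this toy depth (2,000 reads, 4 vs 4 specimens) the discrimination split is
not significant — at the acceptance-scale world (5,000 reads, 14 vs 14,
six domains) it separates the groups with Fisher p < 10⁻⁶ and recovers
the configured expression ratios to within a few percent (see
`tests/testthat/test-acceptance.R`).

## Command line

`inst/cli/hervex.R` exposes the stages as subcommands
(`simulate | screen | build-catalog | viral-screen | quantify | run`)
over plain FASTA/FASTQ/TSV files.
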