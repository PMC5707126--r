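---
title: "Methods: retroviral expression screening with hervex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroviral expression screening with hervex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models and
procedures each stage implements, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The analysis problem

Endogenous retroviruses (HERVs) are ancient proviral remnants fixed in the
host germ line. Claims that their expression is elevated in demyelinating
brain disease involve small effects (ratios well under 3) distributed over
many near-identical loci, so an analysis must (a) quantify a bespoke
catalog of retroviral-homology loci rather than annotated genes, (b) deal
explicitly with multi-mapping reads, and (c) aggregate weak per-locus
signals into domain-level statistics. `hervex` implements that analysis
end-to-end for 50 nt single-end reads, plus the accompanying exogenous
virus screen.

## Read screening

Quality filtering retains reads with mean Phred ≥ `min_mean_phred`
(default 20) and at most `max_n_bases` (default 2) ambiguous bases. The
source study does not state its quality thresholds; these defaults are
conventional for 50 nt Illumina reads and are exposed in
`screening_config()`. The surviving set are the *HQ reads*; their count is
the normalization denominator for all hit rates downstream.

Host subtraction removes a read when a `host_kmer_size`-mer seed (default
14) extends to a *full-length* alignment with at most
`max_mismatches_host` (default 2) substitutions against the host genome
or transcript set, on either strand. Alignment is end-to-end with
substitutions only: for 50 nt reads an indel-free model loses almost
nothing and keeps the matcher exact (the seed sizes satisfy the pigeonhole
bound, so no alignment within the budget can be missed). A read matching
both host and viral sequence is removed — host subtraction precedes the
viral search by construction.

## Viral hit-rate screen

The viral aligner emulates a large-word-size nucleotide BLAST with an
exact 28-nt word seed followed by ungapped extension in both directions;
a base is appended only while cumulative identity stays ≥ `min_identity`
(0.9), and extensions shorter than `min_length` (40 nt) are discarded. At
most one hit — the best-scoring — is kept per (read, reference) pair.
Full gapped dynamic programming and E-value theory add little for 50 nt
queries and would pull in an external aligner; the word size is the
parameter that matters and it is faithful. One consequence is exact: a
single substitution can only be seeded if an intact 28-mer remains, so a
dead-center mismatch in a 50 nt read (flanks of 24 and 25 nt) is
undetectable by design.

The hit count for a specimen and taxon is the number of *distinct* reads
with at least one alignment to any reference record of that taxon, so
duplicating a record inside a taxon cannot inflate the count. The viral
hit rate is `VHR = hits / HQ`. For display, zero counts are rendered at a
half-hit floor `log10(0.5 / HQ)` — the study's figure does not state its
zero handling, and half a hit is the usual detection-limit convention.

Overrepresentation screening compares each case (demyelination or OND)
specimen against the control set per taxon with a Z-test (sample SD,
two-sided normal p). The Bonferroni family is conservatively taken as
(case specimens) × (taxa), since the source text does not pin the family
down. A taxon is retained when at least one case specimen lies above the
control mean with corrected p < 0.05. Zero control variance with a
deviating case is flagged `degenerate` and retained for manual review
rather than silently passed or dropped.

## Catalog construction

The retroviral gene catalog (RVGC) is built by translated homology: the
genome is translated in all six frames (stops as `*`, ambiguous codons as
`X`), translations are split at stop codons — a local alignment through a
stop is biologically meaningless here — and segments of ≥ 20 aa are
locally aligned (BLOSUM62, gap open 11 / extend 1) against the domain
protein set. Raw scores are converted to E-values with the ungapped
Karlin–Altschul parameters λ = 0.318, K = 0.13 over a search space of
(total translated residues) × (protein length); the cutoff is E ≤ 0.1.
This is a deliberate approximation: gapped-statistics refinement is out
of scope and the cutoff is configurable to compensate.

Hits whose alignment length (residues, gaps included) is at least 50% of
the subject domain length — inclusive boundary — enter the catalog.
Overlapping retained hits of the same domain type on the same strand are
union-merged into one entry; merging is not described in the source
methods, but without it duplicated overlapping entries would double-count
reads in quantification. Entries are numbered sequentially within each
domain type in genomic order and named
`<DOMAIN>_U<k>|<recognition domain>|<source id>|<start>|<length>` with a
1-based inclusive start (0-based half-open coordinates are used
internally; the codec is the only place the shift occurs). The normative
code form uses underscores (`GAG_U21`); a rendering layer may display
hyphens. The pipe-delimited suffix syntax is this package's choice — the
record-keeping fields are specified, their syntax is not.

## Quantification

Reads are aligned to catalog entries end-to-end with at most
`max_mismatches` (default 3 for 50 nt) substitutions, both strands, *all*
placements reported, each scored `-(mismatches)`. "Every reported
alignment" in the comprehensive scheme is operationalized as every
end-to-end alignment within the budget, since the original aligner's
report set depends on internals that are not pinned down.

* **Best Alignment**: each read contributes 1 to its best-scoring entry;
  ties break to the lexicographically smallest entry code, so counting is
  deterministic.
* **Comprehensive Alignment**: every (read, entry) alignment contributes
  1; a multi-mapping read may be credited to many entries.

Best counts conserve the number of aligned reads exactly, and
comprehensive counts dominate best counts cell-wise; both are tested as
invariants.

Expression is `FPKM × 1000` with
`FPKM = count / ((L/1000)(M/10⁶))`. The norm mass `M` defaults to the
specimen's supplied (HQ) read count — a stand-in for a library-wide
mapped-fragment total. The alternative, normalizing by the catalog-wide
aligned total, is available (`norm_mass = "aligned"`) but is *not* the
default for a measurable reason: when an entire compartment is elevated in
one group, a catalog-wide denominator rises with it and biases every
entry's between-group FPKM ratio toward (and past) 1, defeating
parameter recovery even at infinite depth. A library-wide denominator
leaves ratios unbiased because the retroviral compartment is a negligible
share of it.

Group comparison per entry: ratio of case to control group means, a
two-sided Mann-Whitney U p-value, and Benjamini–Hochberg q computed
*within each domain type separately*. Entries all-zero in both groups get
p = 1 and an `uninformative` flag. The case group is either the full
demyelination group or its PPMS-only subset (via the design table's
diagnosis column). Mann-Whitney is the default test; Tukey HSD is
available in the stats module — the source text names both without saying
which produced which table entry.

## Domain discrimination

Comprehensive catalog counts are binned by domain type and divided by HQ
reads. The rates are transformed `log2(rate + pseudocount)` with a
default pseudocount of `0.5 / median(HQ)` (half a hit — zeros must stay
finite; the source is silent on this), then each *domain row* is
mean-centered across specimens. "Centered in the domain-type axis" is
read as centering along the domain axis, because the downstream contrast
is between specimens; centering specimens instead would erase exactly the
signal being tested.

Specimens are clustered agglomeratively with distance `1 − Pearson r`
over domain values and average linkage (UPGMA) — the common configuration
of the classic clustering tools. The implementation is in-package with a
deterministic tie rule (smallest pair index in input order); `stats::hclust`
serves as an independent oracle in the tests. Zero-variance specimen
columns get correlation 0 (distance 1) with a warning. The root split
(the final merge's two children) defines the two dominant clusters; a
2×2 group-by-side table restricted to the two groups under test is
evaluated with the two-tailed Fisher exact test, summing hypergeometric
probabilities ≤ that of the observed table (the probability-mass
convention). "Left" is the side with more members of the first test
group — presentation only; the p-value is label-invariant.

## Statistics module

All procedures are implemented in-package and oracle-tested: Z-test,
Bonferroni, BH step-up (sort, `p·m/rank`, tail cummin, cap at 1),
Mann-Whitney U with midranks (exact enumeration of label permutations up
to combined n = 16, then normal approximation with tie and continuity
correction; the two-sided exact p sums both symmetric tails), Fisher
exact (probability-mass summation, relative tolerance 1e-7), Yates
chi-square with the corrected `|ad − bc| − N/2` floored at 0, one-way
unweighted ANOVA, and Tukey HSD (pooled within-group variance,
studentized-range q). One distribution primitive is taken from base R:
`stats::ptukey`, the studentized-range CDF — re-implementing a numerical
quadrature for a standard distribution function would add risk without
information.

## The synthetic world

The generator states one world and the tests measure against it:

* three groups sized 14/14/7, 50 nt single-end reads;
* a host genome at 41% GC (human-like composition without external data);
* random domain proteins (80–400 aa) per domain type, with the nine
  domain-type labels used in the source analysis;
* ERV-like loci: back-translations (uniform codon choice — the simplest
  neutral model) of proteins mutated at 20% amino-acid divergence,
  planted at recorded, non-overlapping positions and strands;
* per-specimen reads drawn from host background, loci, and (for OND) an
  exogenous 10 kb synthetic virus at fraction 1e-4; substitution errors
  at 0.005/base; 2% of reads uniformly Phred 5 to exercise the HQ filter
  (the source never states its quality-filter loss rate);
* locus expression: a base fraction (default 2% of reads, split evenly
  over loci) multiplied in the demyelination group by the domain's
  configured ratio, defaults drawn from the published 1.5–2.8 range. OND
  specimens express loci at the base level — the source observed an even
  stronger pattern there, but only the demyelination effect sizes are
  printed, so only they are modeled.

Host background reads are drawn from *non-locus* regions of the genome.
In a real-sized genome, background transcription over a given locus is a
negligible, group-independent floor; in a desk-scale genome the loci are
a substantial fraction of the sequence, and a uniform background would
add a large constant to every locus count, attenuating every configured
ratio. Excluding loci from the background keeps per-locus counts a pure
readout of the modeled expression process, which is what the
parameter-recovery criteria measure.

What the generator does **not** model — so what a green test does not
establish: rRNA content and library duplication (the source performed no
rRNA depletion and reports neither), indel sequencing errors, paired
ends, splice structure, real HERV sequence similarity structure (loci are
independent back-translations, so cross-locus multi-mapping is rarer than
in the real genome), and post-mortem RNA degradation. Acceptance
replicates run at a deliberately elevated ERV fraction (10%) and desk
depths (5,000 reads/specimen) so that per-domain counts (~100/specimen)
give the discrimination analysis realistic per-domain precision at a
manageable compute cost; this trades absolute realism of the ERV fraction
for statistical power equivalent to much deeper sequencing of a much
smaller compartment.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  names and tables; converters live only in the codec and writers.
* Deterministic everywhere under a seed: per-stage sub-seeds are derived
  from the global seed, so stages can be re-run in isolation
  byte-identically.
* Empty inputs: an empty FASTA yields an empty record set with a warning;
  zero viral hits is a valid result; an empty catalog is an error at
  quantification (nothing to quantify).
* Reads shorter than the seed word produce no hits, not an error.
* All-zero expression rows get p = 1 and a flag rather than NA
  propagation.

## Known limitations

The translated-search E-values use ungapped statistics with a fixed
(λ, K); absolute E-values are approximate and only the relative ranking
plus the configurable cutoff should be relied on. The catalog does not
deduplicate near-identical loci beyond union-merging of overlaps. The
viral screen's Bonferroni family choice is conservative; with very many
taxa it will be strict. Specimen-level covariates (age, sex, PMI) are
summarized and tested but not modeled as confounders of expression.
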