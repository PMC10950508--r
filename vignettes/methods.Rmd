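---
title: "Methods: pharmacogenomic landscapes, population comparison and binary-vector DDI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenomic landscapes, population comparison and binary-vector DDI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical machinery in `pgxddi`, the
conventions it fixes where several are in common use, and what the
synthetic-data validation does and does not establish about real data.

## 1. Carriage landscape

For each drug the pipeline counts, per individual, the number of
annotated risk variants/alleles carried. Counting is **carrier-based**:
an annotation contributes 1 if the individual carries at least one copy
of the risk allele (SNP: dosage of the risk allele ≥ 1; star/HLA:
either diplotype allele equals the risk allele), regardless of
homo-/heterozygosity. This matches the "carries at least one risk
variant" framing that dominates PGx population reports. Allele-dosage
weighting (homozygous counts 2) is available via `dosage_weighted =
TRUE` but is off by default.

Conventions, chosen once and unit-tested:

* **Missing genotypes** count as non-carrier and are logged; they are
  excluded from allele-frequency denominators (`total_count` is twice
  the number of non-missing diploid individuals).
* **Median** of an even-sized cohort is the midpoint of the two central
  order statistics, so count data yield the familiar half-integer
  medians (e.g. 25.5).
* **Quartiles** use the midpoint-exclusive (Moore–McCabe) rule: the
  sorted sample is split at the median, the middle observation is
  dropped when n is odd, and Q1/Q3 are the medians of the halves. Other
  conventions (R's `quantile` types 6/7) interpolate differently; for
  integer counts the exclusive rule keeps quartiles at observed values
  or midpoints, which is what box/violin summaries of carriage counts
  typically display.
* **Evidence-level filter**: whether a landscape covers all PharmGKB-style
  levels (1A–4) or only actionable ones (1A–2B) materially changes the
  counts, and no universal default exists. The filter is therefore a
  mandatory explicit parameter of the pipeline configuration (`NULL`
  meaning "all levels" must be stated, not implied), and the analysis
  scripts compute both.
* **Annotation deduplication**: exact duplicate records are dropped,
  and each `(allele_id, drug)` pair keeps a single record — the one
  with the strongest evidence level (1A < 1B < 2A < 2B < 3 < 4), ties
  broken by input order. This also resolves multi-level re-curations of
  the same association.

## 2. Cross-population comparison

**Fisher exact tests.** Per shared variant, the 2×2 table of
(alt, ref) allele counts × population is tested two-sided using the
minimum-likelihood rule: the p-value sums hypergeometric point
probabilities no larger than that of the observed table, with a 1e-7
relative tolerance for floating-point ties — the dominant convention in
scientific software (`stats::fisher.test`). Tables with a zero margin
carry no information and get p = 1 by convention, logged. Significance
is a bare p < α (default α = 0.05) with no multiplicity correction, as
population-comparison figures of this kind conventionally flag; a
Benjamini–Hochberg flag is available behind `p_adjust = TRUE`.

**Weir–Cockerham Fst.** The two-population variance components of Weir &
Cockerham (1984) are computed per site from the observed (non-missing)
sample sizes, allele frequencies and heterozygosities — missingness is
handled per site per population, as PLINK does. The headline statistic
is the ratio-of-sums ("weighted") aggregate Σa / Σ(a+b+c); the mean of
per-site ratios is reported alongside. Sites monomorphic across both
populations are excluded (their components are identically zero and the
per-site ratio undefined); sites with fewer than one observed genotype
per population or a pooled observed size ≤ 2 individuals are likewise
excluded, with counts logged. Negative per-site components are retained
as computed — clamping would bias the aggregate upward. The estimator is
exactly symmetric in the pair and invariant to ref/alt label swaps.

No site filters beyond the monomorphic-pair exclusion are applied
(no MAF or missingness thresholds); variant subsetting is explicit via
rsID lists.

## 3. Candidate-variant filter

A variant is retained iff all of:

1. functional class is nonsynonymous exonic;
2. its gene is a CTET gene of the active drug list (no genome-wide
   scan — the discovery question is scoped to genes encoding the drugs'
   carrier/transporter/enzyme/target proteins);
3. at least 2 of 3 predictors call it damaging — SIFT `damaging`,
   PolyPhen-2 `damaging` or `probably_damaging`, MutationTaster
   `disease_causing`; a `missing` call abstains rather than voting
   either way;
4. cohort allele frequency is **strictly** greater than the threshold
   (default 0.01). "AF > 1%" is read literally; the boundary af = 0.01
   fails and is unit-tested.

The ≥ 2 reading of the vote rule was chosen over "exactly 2" (both
phrasings circulate in methods descriptions of this filter); a variant
damaging by all three tools obviously should not be excluded. Every
input variant yields a decision row recording each sub-flag and their
conjunction, so the funnel is fully auditable; variants missing from
the AF table are flagged (`passed_af = NA`) and never retained. The
three predictors are consumed as categorical annotations — running them
is out of scope.

## 4. The DDI model

Five binary vectors per drug: one per CTET role and a hybrid over all
roles. The universe (vector length *d*) is the union of elements across
the **analysed drug set**, deduplicated and lexicographically ordered —
so S values are universe-relative and comparable only within one
analysis. This is stated prominently because adding unrelated drugs to
the analysis rescales every S; it provably never flips the S > 0 call,
which is the quantity that matters.

* **Hybrid keying**: the hybrid universe is keyed by `(role, gene)` —
  a gene serving two roles contributes two elements, and hybrid
  positive matches decompose exactly as the sum of role-wise matches.
  The alternative gene-only keying (a gene shared through *different*
  roles still matches) is implemented behind `hybrid_keying = "gene"`;
  under role-gene keying such a pair scores hybrid S = 0. Which
  convention a given catalog extraction used is often undocumented, so
  both are provided and the default is the decomposable one.
* **Gating**: the DDI flag is driven by the hybrid vector (S > 0),
  since only the all-roles vector covers every sharing mode; per-role
  similarities are reported for interpretation.
* **Zero vectors**: drugs with no catalogued elements are eliminated
  before scoring and their names reported — they carry no information
  under this model, not evidence of safety.
* **Regimen counting**: counts are over distinct unordered pairs in the
  union of the regimens' drug sets (a drug in both regimens is counted
  once). A pair is within-A if both drugs are in A, within-B if both
  are in B and not both in A, cross otherwise, so
  `union = within_a + within_b + cross` holds identically — the
  decomposition a combined-regimen table relies on.
* Similarity is **not** a severity measure; outputs deliberately carry
  no severity field.

The drug–gene network collapses roles onto edges: gene degree = number
of distinct drugs linked, drug degree = number of distinct genes, the
quantities network views scale their labels by.

## 5. Synthetic data and what validation shows

The generator emulates the inputs of a real study with exact ground
truth:

* **Genotypes**: Balding–Nichols — ancestral AF per variant (default
  uniform on [0.05, 0.95], bounded away from 0/1 so monomorphic sites
  do not dominate; degenerate draws are resampled and logged),
  population AFs Beta(mean p, variance p(1−p)F), genotypes
  Binomial(2, ·). F may be per-population, in which case a pair's
  expected Fst is approximately the mean of its two F values. Expected
  weighted Fst ≈ F gives the estimator a closed-form recovery target.
* **CTET catalogs**: independent role-typed drug–gene links at a given
  density plus planted shared elements for named pairs; the DDI truth
  is recomputed from the emitted catalog by brute-force intersection,
  never assumed from the planting.
* **Annotations**: risk SNPs assigned to real cohort variants, with
  per-sample carrier counts recounted directly from the genotype
  matrix.
* **Diplotypes**: two independent draws per sample from a given allele
  frequency law.

All randomness flows from one explicit integer seed through a local
generator; the caller's RNG state is untouched, and identical
parameters + seed give byte-identical outputs.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
(variants are independent), realistic site-frequency spectra (the
ancestral law is uniform, so rare variants are under-represented and
the AF > 1% filter bites less than it would in sequencing data),
haplotype structure behind star alleles, genotyping error and
population-structured missingness, and curation noise in annotation and
catalog extracts. The validation establishes the *estimators and
counting rules* are implemented correctly, not that real cohorts will
match any particular published value.

## 6. Problem sizes and determinism

The test suite and acceptance script use sizes chosen to put each check
in its informative regime while keeping a full run in tens of seconds:
Fst recovery at 500 diploids/population × 5000 variants (Monte-Carlo
standard error well under the ±0.02 acceptance band), self-comparison
at 2000 variants, landscape truth at 1008–1000 samples × 200
annotations, Fisher enumeration on 200 random tables with margins ≤ 50,
DDI oracles on 1000+ random pairs, and regimen counting across 50
generator seeds. The analysis scripts use a 1008-sample focal cohort
with four 200-sample comparison panels at graded divergence
(F = 0.01–0.30), 2000 variants and an 18-drug list.

End-to-end runs are deterministic at byte level given a configuration:
tables are written with fixed formatting, the run log carries no
timestamps, and the serialized configuration excludes the output path.

## 7. Known limitations

* Biallelic SNVs only; multiallelic records and indels are skipped at
  VCF load (annotation tables are keyed per rsID/alt pair, and
  splitting multiallelics introduces ambiguity the downstream joins
  cannot resolve). Sex chromosomes are treated as diploid; mtDNA is
  excluded at load.
* Star-allele and HLA calls are consumed, not inferred; there is no
  phasing or imputation.
* The per-site Fst components assume the island-model sampling theory
  of the estimator; no significance is attached to per-site values.
* No gene-symbol alias resolution: symbols are upper-cased and matched
  literally, keeping the pipeline deterministic and offline.
* The DDI model is structural (shared CTET elements); it neither
  classifies mechanisms nor validates against adverse-event data.
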