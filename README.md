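# pgxddi

Population-scale pharmacogenomic (PGx) profiling of drug lists, with a
binary-vector model for predicting drug–drug interactions (DDIs).

The package is aimed at analysts characterising how a genotyped cohort is
likely to respond to a set of therapies — for example the drugs used to
treat COVID-19, its post-acute sequelae, and common comorbidities — when
the questions are:

* **Landscape** — how many curated risk variants/alleles (SNPs, star
  alleles such as `CYP2C19*2`, HLA alleles such as `HLA-B*15:02`) does
  each individual carry per drug, and what fraction of the cohort carries
  at least one?
* **Population differentiation** — how different is the cohort from
  reference panels at those pharmacogenomic loci, measured by pairwise
  weighted Fst and per-variant Fisher exact tests on allele counts?
* **Novel candidates** — which cohort variants in the genes encoding a
  drug's carrier/transporter/enzyme/target (CTET) proteins are
  nonsynonymous, predicted deleterious by at least two of SIFT,
  PolyPhen-2 and MutationTaster, and common (AF > 1%)?
* **DDI risk** — which drug pairs share CTET elements, and how many
  potential interactions does a treatment regimen entail, alone or
  combined with a comorbidity regimen?

## The models

**Russell–Rao DDI score.** Each drug is encoded as binary vectors over
ordered element universes built from the analysed drug set: one vector
per CTET role plus a hybrid vector over all roles, keyed by
`(role, gene)`. For two drugs with vectors *x*, *y* of length *d*, the
similarity is

> S = xᵀy / d

the number of shared elements over the universe size. Drugs with
all-zero hybrid vectors are eliminated; a surviving pair is a potential
DDI iff its hybrid S > 0, i.e. iff the drugs share at least one
catalogued element. S is universe-relative (d is recomputed per
analysis) but the S > 0 call is not.

**Weighted Weir–Cockerham Fst.** Per biallelic site the Weir & Cockerham
(1984) variance components *a* (among populations), *b* (among
individuals within populations) and *c* (within individuals) are
computed from observed sample sizes, allele frequencies and
heterozygosities; the weighted estimate aggregates as a ratio of sums,

> Fst = Σᵢ aᵢ / Σᵢ (aᵢ + bᵢ + cᵢ)

the estimator behind PLINK's `--fst`. Sites monomorphic across both
populations are excluded; negative components are kept as computed.

**Synthetic cohorts.** The generator uses the Balding–Nichols model:
ancestral frequency *p* per variant, population frequencies Beta
distributed with mean *p* and variance *p(1−p)F*, genotypes
Binomial(2, ·). Its expected weighted Fst is approximately *F*, which
gives the estimator a closed-form recovery target; CTET catalogs are
emitted with planted drug-pair overlaps and a brute-force intersection
truth, and annotation tables carry exact per-sample planted carrier
counts.

## Worked example

```r
library(pgxddi)

drugs <- as_drug_list(data.frame(
  name   = c("ritonavir", "warfarin", "dexamethasone"),
  groups = c("cause_treatment", "antithrombotic", "corticoid")))
catalog <- as_ctet_catalog(data.frame(
  drug = c("ritonavir", "ritonavir", "warfarin", "warfarin", "dexamethasone"),
  role = c("enzyme", "transporter", "enzyme", "enzyme", "target"),
  gene = c("CYP3A4", "ABCB1", "CYP3A4", "CYP2C9", "NR3C1")), drugs)

detect_ddis(drugs, catalog)[, c("drug_a", "drug_b", "S_enzyme",
                                "S_hybrid", "is_ddi")]
#>          drug_a    drug_b S_enzyme S_hybrid is_ddi
#> 1 dexamethasone ritonavir      0.0     0.00  FALSE
#> 2 dexamethasone  warfarin      0.0     0.00  FALSE
#> 3     ritonavir  warfarin      0.5     0.25   TRUE
```

Ritonavir and warfarin share one element (the enzyme CYP3A4) out of an
enzyme universe of 2 genes (S = 1/2) and a hybrid universe of 4
`(role, gene)` elements (S = 1/4); sharing any element flags the pair as
a potential DDI. Dexamethasone shares nothing and is flagged with
neither.

```r
sim <- simulate_populations(5000, c(viet = 500, eur = 500), F = 0.1,
                            seed = 7)
weighted_fst(sim$cohorts$viet, sim$cohorts$eur)
#> fst_result: viet vs eur, 5000 variants, weighted Fst = 0.0991 (mean 0.0836)
```

Two populations simulated at divergence F = 0.1 are estimated at
weighted Fst 0.099 — the estimator recovers the generative parameter.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
inputs with known ground truth, writing tables under `results/`:

| script | output |
|---|---|
| `01_simulate_inputs.R` | cohort VCFs (focal n = 1008 + 4 panels), drug list, CTET catalog, annotations, diplotypes, deleteriousness table, `truth.json` |
| `02_landscape.R` | per-drug carriage summaries (all levels and actionable 1A–2B), star/HLA allele frequencies |
| `03_population_comparison.R` | pairwise Fst matrix, Fisher exact AF comparisons |
| `04_variant_filter.R` | candidate-variant filter decisions and funnel |
| `05_ddi_network.R` | DDI pairs, regimen-level counts, drug–gene network (+ GraphML) |
| `06_report.R` | single-config end-to-end bundle with determinism check and summary report |

Run them in order from the repository root:
`Rscript analysis/01_simulate_inputs.R`, etc.

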