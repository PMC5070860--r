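---
title: "Family-based rare-variant prioritization: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant prioritization: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
```

## Scope and model

`famseg` prioritizes rare deleterious single-nucleotide variants (rdSNVs)
in multiplex-family sequencing cohorts. The underlying disease model is
autosomal dominant transmission with possible incomplete penetrance, plus
compound heterozygosity as a second recessive-like mechanism in
parent-parent-proband constellations. Pedigrees are trusted as given (no
kinship inference), sites are diploid and biallelic, and X-linked,
recessive-homozygous and de novo models are out of scope.

The pipeline's logic is a composition of filters and tests rather than a
joint likelihood: this mirrors how such cohorts are analysed in practice
when sample sizes preclude formal family-based association, and it makes
every stage auditable through the funnel of per-stage variant counts.

## Tunable parameters

| Parameter | Default | Units / domain | Rationale |
|---|---|---|---|
| `maf_threshold` | 0.001 | reference-population allele frequency | "rare" cutoff of 0.1%, strict `<`; a variant exactly at the threshold fails |
| `min_damaging_predictors` | 2 | count of 4 predictor calls | consensus of at least two algorithms; missing calls count as not damaging so missingness cannot promote a variant |
| `lof_classes` | stop-gain, frameshift, splice | — | loss-of-function variants bypass the predictor consensus because missense predictors do not score them |
| `strict_controls` | `FALSE` | — | unaffected in-family carriers are tolerated but flagged (incomplete penetrance); strict mode disqualifies them |
| `min_affected` | 2 | genotyped affecteds | dominant co-segregation is undefined with a single affected; such families contribute only compound-het candidates |
| `z` threshold | 2 | standard deviations | candidate gate on the per-gene rdSNV count z-score, strict `>` |
| intolerant decile | RVIS percentile ≤ 10 | percentile | right-closed decile bins `((b−1)·10, b·10]`; the most intolerant decile is bin 1 |
| `weight` (GSEA) | 1 | exponent on \|score\| | the standard weighted running-sum statistic |
| `n_perm` | 1000 | permutations | permutation null for the enrichment score; the smallest attainable nominal p is 1/1001 |
| `count_per_family` | `"index"` | — | one affected per family enters burden counts, avoiding pseudo-replication of a single transmitted allele; `"all"` is available |
| high-CADD threshold | 20 | scaled CADD | "top 1% most deleterious" convention, strict `>` |
| `cadd_rank_floor` | 15 | scaled CADD | floor for the ranked variant report, strict `>` |

## The synthetic cohort

The generator is a first-class module, not a fixture: it defines the study
conditions under which the pipeline is validated.

**Pedigrees.** Three templates — trio (3 members), three-generation (6),
extended two-branch (8) — mixed by default as 42/8/1, giving 51 families
and 182 individuals with 2 affected members per family along a single
descent lineage, plus 193 unrelated singleton controls. These sizes are the
scale of a typical multiplex exome cohort with an external control panel.

**Background variation.** A universe of 1200 genes with Poisson(3) sites
per gene; reference-MAF spectrum novel 5%, rare (<0.1%) 25%, low-frequency
30%, common 40%; background scaled CADD a 95:5 mixture of Exponential(mean
6) and Uniform(15, 35), so a realistic minority of benign variation looks
pathogenic. Predictor calls are drawn conditionally on CADD tier
(P(damaging) = 0.10 below 10, 0.35 between 10 and 20, 0.70 above 20, 5%
missing), so predictors and CADD agree only imperfectly, as in real
annotation. Genotypes come from Mendelian gene dropping: founders are
Hardy–Weinberg draws at the site's cohort frequency, children receive one
uniformly chosen allele per parent; novel sites (which have no reference
frequency) segregate at 0.0013 — singleton scale for ~375 diploid
individuals, since novel variants are predominantly singletons.

**Planted architecture.** By default 12 of 51 families receive a fully
penetrant dominant causal variant in one of 6 designated genes (2 families
per gene), novel, scaled CADD Uniform(25, 35) — matching the observation
that causal alleles in such studies print scaled CADD scores in the
high 20s to 30s — with at least two damaging predictor calls. Causal genes
are forced into the bottom RVIS decile and collected in one designated
25-gene set among 50; other sets are random and may overlap it by chance.
A truth table records every planted carrier.

**Penetrance semantics.** Each affected draws carrier status independently
with probability `penetrance`; ancestors on the descent path from the
founder origin are then forced to carriers so transmission stays
Mendelian-consistent. Unaffected on-path individuals become flagged
unaffected carriers; an affected drawn non-carrier but required as an
ancestor is overridden and flagged `forced_carrier`. With transmission-
independent affecteds (siblings) the affected-carrier fraction is exactly
binomial in the penetrance; in chained lineages forcing can exceed the
nominal rate, which the truth table makes visible. Unaffected off-path
children of carriers inherit with probability 1/2.

**What the generator does not emulate.** No linkage disequilibrium between
background sites, no sequencing error or genotype missingness, no
population stratification, no de novo mutations, no locus length variation
(every gene is equally mutable). Passing parameter-recovery tests therefore
demonstrates correctness of the pipeline's logic under a clean Mendelian
signal, not robustness to the artefacts of real exome data.

## Numerical and procedural choices

- **Fisher exact test**: conditional hypergeometric (not mid-p); tail sums
  accumulate in log space so p-values never truncate to 0. The two-sided
  p sums tables no more probable than the observed one (with a 1e-7
  relative slack on the equality comparison, the ecosystem convention).
- **Wilcoxon**: midranks for ties; exact mode enumerates all
  `choose(n+m, n)` rank splits and is guarded to `n + m ≤ 16`; the normal
  approximation applies the tie-corrected variance and a 0.5 continuity
  correction. Default mode is the normal approximation.
- **Chi-square**: closed-form 2×2 statistic without Yates correction; in
  the high-CADD test a pair in which every variant falls on one side of
  the threshold short-circuits to statistic 0, p 1 rather than an error.
- **GSEA**: gene-set permutation (phenotype permutation is impossible for
  a preranked statistic); permutation nulls are cached per set size within
  a call, so same-size sets share one null; `p = (1 + #{|ES*| ≥ |ES|}) /
  (1 + n_perm)`; NES normalises by the sign-pooled mean |ES*| rather than
  signed-side means — simpler, and adequate for a one-sided enrichment
  question; FDR across sets is BH on nominal p rather than an NES-based
  FDR. Ranking ties break lexicographically by gene symbol, so results are
  order-independent.
- **z-scores** use the population (denominator n) standard deviation over
  the full universe including zero-count genes; an all-equal count vector
  is an error rather than a silent all-zero.
- **Coordinates** are 1-based throughout; multiallelic VCF records are
  split into biallelic rows and alleles normalised by trimming shared
  suffix then prefix; variant keys `chrom:pos:ref:alt` are the only join
  handle, and annotation joins are exact (unannotated variants are dropped
  with a logged count).
- **Degenerate inputs**: a family with no genotyped affected is "not
  evaluable" (NA), distinct from non-co-segregating (FALSE); a gene with
  no qualifying variants gets burden p = 1 with 0/0 carriers; an empty
  filter input yields an empty table with a zeroed funnel.

## Open design decisions

Several behaviours were genuinely underdetermined and are settled here as
package policy, each exposed as an option where both readings are useful:

- Whether loss-of-function variants must also pass the predictor
  consensus: they are exempt (predictors mostly score missense), which is
  why the cascade applies consensus to missense only.
- Whether unaffected in-cohort relatives disqualify a candidate: both
  modes exist (`strict_controls`); the default tolerates and flags them,
  because incomplete penetrance is expected in dominant cardiac disease,
  while phenotype-confirmed population controls always disqualify.
- Whether the extreme-bin excess test compares per-gene counts or per-bin
  sums: per-gene counts, the only variant that yields a well-defined rank
  test.
- Whether burden counts alleles or carrier individuals, and how many per
  family: binary carrier collapsing with one index case per family
  (configurable to all affecteds). With counts of 3 carriers among 106
  cases versus 0 among 193 controls the one-tailed hypergeometric tail is
  0.04374 — the package documents this computation and does not force any
  alternative counting convention.
- RVIS decile boundaries are right-closed and "intolerant" means
  percentile ≤ 10, fixing the boundary inconsistency inherent in "below
  the 10th percentile" versus "top 10%".

## Problem sizes

The shipped validation uses cohorts of 51 families (182 members) plus 193
controls over 1200 genes (~3600 sites), 1000 GSEA permutations, and 50
simulation seeds for the parameter-recovery study; enumeration oracles run
over all 2×2 tables with total ≤ 40 and all rank splits with n + m ≤ 12.
These sizes were chosen so that a full validation cycle completes in a few
minutes on one CPU while keeping every test at the scale where its
statistical behaviour is meaningful.

## Limitations

Binary carrier collapsing ignores allele dosage and within-gene variant
counts; the burden test conditions on the margins and has little power at
2–3 carriers per gene (single-cohort candidate confirmation, not
genome-wide discovery). The GSEA null permutes gene sets, not phenotypes,
so correlated gene scores inflate neither ES nor NES but are also not
modelled. The simulator's clean Mendelian signal means recovery rates
reported by `recovery_study()` are upper bounds on what identical settings
would achieve on real exomes.
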