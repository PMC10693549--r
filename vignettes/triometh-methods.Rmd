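---
title: "Methods: trio-based discovery of heritable DNA methylation sites"
author: "triometh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trio-based discovery of heritable DNA methylation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triometh)
```

## The model

`triometh` asks a narrow question of trio WGBS data: which CpG sites behave
like a Mendelian trait across families while being statistically
independent of every SNP? The answer is built from three components.

**State categorization.** A per-sample methylation percentage is collapsed
to unmethylated (U, at or below 20 %), intermediate (I, strictly between 20
and 80 %) or methylated (M, at or above 80 %). The boundaries belong to U
and M; I is the open interval. This coarse-graining is what makes a
transmission model possible at all: a quantitative 0–100 % signal becomes a
three-level genotype-like variable.

**Epiallele transmission.** The three states are modelled as the three
genotypes of a diploid, biallelic *epiallele*: M = *mm*, I = *mu*, U =
*uu*. A child draws one epiallele from each parent, so the reachable child
states are the distinct sums of one gamete per parent. This is the unique
two-allele model consistent with the three-state categorization, and
brute-force enumeration of all gamete combinations is the package's single
source of truth for compatibility: `compatibilityTable()` is generated from
it, and the test suite re-derives it with an independent enumeration.
Exactly 15 of the 27 ordered (father, mother, child) triples are
compatible. The identical algebra, under the mapping 0 = U, 1 = I, 2 = M,
gives the dosage-transmission rule used for the SNP-side Mendelian filter.

**mQTL exclusion.** Sites surviving the Mendelian selection are tested
against every SNP by simple linear regression of methylation percent on
additive dosage (no covariates; trios are treated as independent samples,
since with 12 exchangeable subjects no relatedness correction is
identifiable and none is attempted). Significance uses a Bonferroni
threshold of alpha over the full test count — deliberately extreme, so that
only near-perfect fits at n = 12 can remove a site, and every removal is
defensible as "explained by genotype". A significant SNP within 1 Mb on
the same chromosome labels the CpG `cis_explained`; cis takes precedence
over trans when both occur. What remains is the heritable candidate set.

## Assumptions

* Methylation calls are binomial draws over reads: at coverage *c*
  the observed percent has standard deviation up to
  $100\sqrt{0.25/c}$ (≈ 14 points at 10×). States near the 20/80 boundaries
  are therefore unstable at low coverage, which is why the coverage floor
  and the completeness rule exist, and why parameter-recovery guarantees
  are only claimed under high-coverage conditions.
* Compatibility is evaluated only in families where all three members are
  observed at the CpG; a family with a missing member neither passes nor
  fails. The upstream filter guarantees at least 3 complete families, and
  `selectMendelian()` treats a violation of that contract as an error
  rather than silently tolerating it.
* The genotype input is assumed post-QC apart from missingness (> 2 %
  missing drops a SNP) and Mendelian-consistency checks; Hardy–Weinberg and
  imputation-quality filtering belong to array QC, not this pipeline.

## Tunable parameters

All cutoffs live in `methThresholds()`:

| parameter | default | meaning |
|---|---|---|
| `state_low`, `state_high` | 20, 80 % | U/I/M boundaries |
| `parental_delta` | 20 points | strict parental difference for variability |
| `min_mean_cov` | 10× | total reads ≥ `min_mean_cov` × n samples |
| `min_complete_families` | 3 | families with all three members observed |
| `cis_window` | 1 Mb | cis/trans boundary for mQTL labelling |
| `alpha` | 0.05 | family-wise error for the Bonferroni threshold |
| `flank_width` | 1000 bp | flanking window per side |
| `flank_purity` | 0.80 | strict side-purity for scenario calls |
| `min_flank_cpgs` | 3 | observed CpGs per side below which a site is unclassified |

The defaults are the conventional choices for this analysis; the filter
cascade attributes each removal to the *first* failing stage in a fixed
order (non-autosome, SNP overlap, incomplete families, imprinted region,
low coverage), which makes the `FilterLedger` deterministic and auditable —
permuting input rows never changes the counts.

## The synthetic generator

`simulateTrioDataset()` emulates the study design the pipeline targets:
4 trios (12 samples), Poisson coverage with mean 12× (matching a
median-coverage-≈11× design; an optional negative-binomial dispersion is
available but off by default), Gaussian noise of 5 points on the true
methylation level, 1 % missing calls, and a genome of two 2 Mb autosomes
carrying CpG islands, gene models, a 15-state chromatin segmentation,
imprinted regions and a SNP panel. Planted CpG classes:

* `stable` — constant level in everyone: 0 % inside CpG islands, 100 %
  outside. This choice both reflects the canonical island/open-sea
  methylation landscape and gives the methylome the boundary structure that
  the transition (scenario E) analysis needs.
* `cis_mqtl` / `trans_mqtl` — 50 points per dosage unit of a driver SNP
  (trimodal 0/50/100 pattern), the driver within 1 Mb for cis and on
  another chromosome for trans. The 50-point effect guarantees that, with
  low noise and 12 samples, driver associations clear even an extreme
  Bonferroni threshold.
* `heritable_epiallele` — founder epialleles drawn independently of all
  genotypes (Bernoulli 1/2 per epiallele), child inheriting one per
  parent; level = 50 × (methylated epialleles). Mendelian by construction,
  genotype-independent by construction.
* `non_mendelian` — independent per-individual levels from {0, 50, 100};
  this class exists to stress the compatibility filter, and the expected
  fraction that survives selection is computable exactly from the
  enumeration ((15/27)⁴ − (5/27)⁴ ≈ 0.094 for four families), which the
  tests verify empirically.
* `imprinted` — 50 % in everyone, placed inside imprinted regions, removed
  up front because parent-of-origin methylation is expected and confounded
  there.

Island sequence is generated at ~63 % GC versus 40 % background, with a CG
dinucleotide forced at every planted CpG.

What the generator does **not** emulate: read-level artefacts (bisulphite
conversion errors, mapping bias), linkage disequilibrium between SNPs,
cell-composition heterogeneity, X inactivation, and polymorphic repeat
elements. Passing tests therefore demonstrate the correctness of the
*procedure* under its stated statistical model, not robustness to every
failure mode of real WGBS.

## Numerical choices

* The mQTL scan is computed blockwise with an indicator-matrix formulation
  of pairwise-complete sums, so missing cells are handled without a
  per-pair loop; the tests assert equality with per-pair OLS and with an
  independent closed-form r-to-t oracle to 12 significant digits.
* Centered sums of squares below a scale-aware tolerance
  (10⁻¹⁰ · n · (scale + 1)²) mark a vector as constant; such pairs are
  untestable and never significant. Perfect fits give t = ∞ and p = 0,
  which *does* count as significant — with n = 12 an exact tie at zero is
  precisely the "explained by genotype" case.
* Distances to annotation tracks follow the GenomicRanges
  `distanceToNearest` convention (gap width; containment and adjacency are
  0). Island banding assigns distance 0 to `island`, (0, 2 kb) to `shore`,
  [2 kb, 4 kb] to `shelf` (both boundaries, so the verbal rules form a
  partition with boundaries assigned outward once) and > 4 kb to
  `open_sea`.
* Flank scenarios are evaluated per side — the only reading that makes the
  transition scenario E well-defined — with A–D requiring both sides to
  qualify; purity is strict (> 0.8) over all observed flanking CpGs, so
  intermediates dilute it. An intermediate index CpG inside concordant
  flanks is left `unclassified`. Flank GC content uses the union of both
  1 kb flanks with the index base excluded, truncated and renormalized at
  chromosome ends.
* Hierarchical clustering defaults to complete linkage on Euclidean
  distances over complete-case CpGs; linkage is configurable and stated so
  results are reproducible either way.
* BED input/output is delegated to `rtracklayer` (0-based half-open
  handled at the boundary); CpG and SNP coordinates are 1-based
  throughout the in-memory model.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
simulated datasets of roughly 300–600 CpGs × 12 samples against panels of
~100–300 SNPs, with recovery checks at 150× coverage and noise sd 1 (50
CpGs per class). These sizes exercise every code path, including the
blockwise scan, while keeping a full run in seconds; the scan design
scales linearly in CpG blocks for larger inputs.

## Limitations

With 4 trios the scan has power only for near-deterministic effects, so a
"heritable" verdict means "no detectable SNP association at an extreme
threshold", not proof of epigenetic inheritance; rare family-private
variants, structural variation and LD partners outside the panel can all
masquerade as heritable signal. The deterministic compatibility rule has no
error model: a single miscategorized state in one family removes a site,
which is why state boundaries and coverage interact strongly with
sensitivity at realistic depth.
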