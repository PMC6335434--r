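---
title: "Prioritizing exosome-surface tumor antigens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing exosome-surface tumor antigens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoprio)
```

## The scientific problem

Tumor cells shed exosomes — extracellular vesicles of roughly 30–150 nm —
that display a subset of cellular proteins on their outer membrane.
Circulating immunoglobulins in cancer patients bind some of these
exosome-surface proteins, which makes the immunoglobulin-bound (Ig-bound)
fraction of plasma a window into the tumor antigens that actually elicit a
humoral response. `exoprio` implements the integrative analysis that turns
several label-free proteomic experiments into a ranked, provenance-tracked
list of candidate exosome-surface tumor antigens, and the companion
serological and functional readouts: autoantibody microarrays merged
across cohorts, and the "decoy" effect by which antigen-bearing exosomes
sequester cytotoxic antibodies and attenuate complement-dependent
cytotoxicity (CDC) against tumor cells.

Because the raw mass-spectrometry and cohort data of such a study cannot
be reproduced at desk scale, the package carries a first-class synthetic
study generator with planted ground truth. Every selection rule is
therefore testable: the planted antigens are known, so precision and
recall of the full cascade are measurable quantities, not anecdotes.

## The data model

Three proteomic experiments feed the cascade:

* **Ig-bound spectral counts** — proteins × pooled plasma samples (case
  and control pools), MS2 spectral counts as a semi-quantitative
  abundance proxy.
* **Cell line × compartment spectral counts** — six cancer cell lines
  fractionated into five compartments: total cell extract (TCE), cell
  surface, total exosome extract (TEE), exosome surfaceome, and exosome
  cargo.
* **Plasma exosome MS1 intensities** — proteins × individual plasma
  exosome preparations (six cases, six controls), with per-sample
  nanoparticle-tracking diameter tables used to normalize intensities to
  the number of exosome-sized (30–200 nm) particles.

## The selection cascade

All count matrices are quantile-normalized first (see *Numerical
choices*). The Ig-bound cascade then applies, in order:

1. **Detection** — at least 5 normalized MS2 counts in at least one pool.
   The rule is inclusive (`>= 5`), whereas the cell-line detection rule is
   strict (`> 5` in at least 2 of 6 lines); both boundary semantics are
   covered by tests.
2. **Case/control ratio** — arithmetic mean ratio of at least 1.5.
   Proteins observed only in cases have an infinite ratio and pass; this
   is deliberate — a protein unique to cases is maximally elevated — and
   no pseudocount is applied by default (a pseudocount option exists).
   Proteins absent from both groups are undefined and dropped.
3. **Expression confirmation** — the corresponding gene must show
   FPKM ≥ 1 in at least one of 11 cell lines *and* a TCGA log2 expression
   summary ≥ 1. The source study confirms expression without stating its
   rule; these thresholds are explicit arguments and are echoed in every
   report.
4. **Exclusion lists** — immunoglobulin chains (gene-symbol prefixes IGH,
   IGK, IGL, IGJ), acute-phase response proteins, and classical
   high-abundance plasma proteins (editable text lists shipped under
   `inst/extdata/`).

Survivors are annotated — not filtered — with an overexpression flag
(how many of eight external expression datasets report tumor
overexpression; flagged at ≥ 2), since that evidence grades candidates
rather than defining them.

Orthogonal filters then intersect with the Ig-bound survivors:

* **Exosome-surface enrichment**: mean normalized counts in the exosome
  surfaceome must exceed 1.25 × the mean in *both* the cargo and the TEE
  compartment (a conjunction, and strict `>`), intersected with the
  strict detection rule. The same operation with TCE as reference yields
  the cell-surface analogue.
* **Plasma elevation**: particle-normalized case/control MS1 intensity
  ratio > 2.5 in plasma exosomes, detected in at least two samples; for
  immunoglobulin chains themselves the pipeline applies the stricter
  3.5-fold rule.

Overlaps between lists are scored with the inclusive upper-tail
hypergeometric test in a universe of *N* = 17,611 genes (overridable),
with the representation factor *k·N/(K·n)* as the effect size. Marker QC
compares the canonical exosome panel (CD81, CD9, FLOT1, FLOT2, PDCD6IP,
SDCBP, TSG101) against compartments with a one-sided rank test, and a
depleted panel (CANX, CYC1, GOLGA2, HSP90B1) as the negative control.

## What the generator emulates — and what it does not

`sim_config()` fixes the synthetic study's conditions:

* **Counts** are negative-binomial with mean/dispersion parameterization
  (variance = μ + φμ²; `nb_dispersion` φ = 0.2 by default, i.e. ~47%
  CV per observation — typical for spectral counts across biological
  replicates). φ = 0 is the deterministic limit: counts equal their
  integer planted means, intensities their planted means, so every
  realized ratio equals its planted fold exactly and cascade recovery is
  exact. Per-protein baselines are integers drawn log-normally
  (median ≈ 30 counts, sdlog 1) so the noise-free ratios are exact.
* **Planted antigens** (default 25 of 2000 proteins) carry a 2.0-fold
  surfaceome enrichment and a 3.0-fold case/control ratio in both the
  Ig-bound counts and plasma intensities. A small configurable set of
  *unique-to-case* proteins has control means of zero, exercising the
  infinite-ratio path, and planted contaminants (Ig chains, an
  acute-phase and an abundant plasma protein) exercise the exclusion
  stage. Marker and depleted-panel proteins are planted with
  compartment-appropriate enrichment so marker QC is meaningful.
* **Pools and samples**: 6 case and 6 control Ig-bound pools (the
  emulated study pooled ~60 case and ~76 control subjects at ~10 per
  pool), 6 + 6 plasma exosome preparations.
* **MS1 intensities** are log-normal with `intensity_sigma` = 0.1
  (natural-log SD, ~10% CV) — technical label-free variation. Each
  plasma sample has a latent exosome-yield factor that scales both its
  intensities and its particle counts; particle normalization is exactly
  the operation that divides this factor out, so the generator gives the
  normalization something real to do.
* **Particles**: diameters are normal, 110 ± 16 nm for plasma exosomes
  and 82 ± 3 nm for cell-line exosomes, ~300 tracks per sample scaled by
  the yield factor.
* **Serology**: three sample sets sized 10/10/10, 13/13 and 42/50/50
  (case/healthy/pancreatitis) with set-specific location and scale
  shifts; planted antigens carry a 2-SD case effect on the standardized
  scale; a set of null antigens carries none.
* **CDC**: cytotoxicity follows the saturating decoy model
  c(dose) = c₀ / (1 + λ·dose) with c₀ = 0.6, λ = `decoy_strength`
  (default 1), doses 0/1/2.5 µg in triplicate, 5% multiplicative noise,
  read out both as plate absorbance and as dead-cell counts with matched
  spontaneous-lysis wells.

One master seed drives everything; each generator stage derives a child
seed from the master seed and its stage name, so adding a stage never
perturbs the streams of earlier stages, and the same planted antigen
identifiers appear in the proteomic, serologic and epitope outputs.

**Limitations.** The generator models technical, not biological,
variation in plasma intensities: between-patient heterogeneity of exosome
cargo is far larger than 10% and would erode the plasma-elevation filter;
passing tests therefore demonstrate correctness of the machinery, not
expected performance on real cohorts. Compartment counts are independent
across compartments, whereas real TEE abundance partially contains the
surfaceome signal. Peptide-level identification, isoform collapsing and
raw spectra are out of scope.

## Statistical components

* `hypergeometric_overlap()` computes the inclusive upper tail
  P(X ≥ k) through `phyper(..., lower.tail = FALSE)`, which accumulates
  the tail directly in C and does not underflow at p ~ 1e-100; it is
  cross-checked against exhaustive enumeration for every configuration in
  universes up to N = 12 at 1e-12.
* `mann_whitney()` computes U from midranks; AUC = U/(n₁n₂). With both
  groups of at most 8 values the p-value is exact by enumeration of all
  group assignments (correct under ties — the reason this is authored
  rather than delegated); otherwise the normal approximation with tie and
  continuity correction is used, and it matches `wilcox.test` where both
  are defined.
* `roc_analysis()` reports the trapezoidal ROC area (equal to the
  Mann-Whitney AUC to machine precision, which the tests assert), a
  DeLong 95% CI (seeded stratified bootstrap optional) and the rank-test
  p-value against AUC = 0.5.
* `fisher_exact()` is two-sided by the point-probability criterion;
  `bh_fdr()` is Benjamini-Hochberg, used in place of the proprietary FDR
  procedure of commercial annotation tools; `correlation_cluster()` is
  complete-linkage on 1 − Pearson distance.
* The CDC decoy analysis reports both the classical pairwise unpaired
  t-tests against dose 0 and a seeded permutation trend test (Spearman of
  dose versus replicate-level cytotoxicity, one-sided for inhibition),
  because pairwise tests alone cannot establish dose-dependence.

## Numerical choices

* **Quantile normalization** maps each column to the reference
  distribution (row-wise means of the column-sorted matrix). Within-column
  ties receive the mean of the reference values their rank positions span
  (`ties = "average"`, the convention of expression preprocessing);
  `ties = "first"` instead assigns reference order statistics exactly, so
  every column's multiset equals the reference even under ties. With tied
  inputs these two goals — tie symmetry and exact multiset equality — are
  mutually exclusive; the default favors tie symmetry, which preserves
  rank correlation exactly. Normalization happens once per experiment
  (Ig-bound, cell line, plasma are distinct experiments) and before any
  detection or ratio rule; this ordering is recorded in the cascade name.
* **Boundary semantics** are implemented exactly as printed for each
  rule: detection "at least 5" is inclusive, cell-line detection
  "more than 5" is strict, ratio "1.5 or greater" is inclusive, fold
  thresholds 1.25/2.5/3.5 are strict, the 30–200 nm particle window is a
  closed interval, and the IC50 rule is strict (< 500 nM).
* **Degenerate inputs**: zero-variance control sets abort serology
  standardization naming antigen and set; constant rows abort clustering
  naming the row; spontaneous absorbance ≤ 0 and empty groups are errors;
  equal constant groups give t-test p = 1 by convention; negative
  background-subtracted dead-cell counts are floored at 0 with an ε =
  1e-9 denominator guard and a warning.
* **Epitope coordinates** are 0-based half-open internally (string
  offsets) and 1-based inclusive in all reports; the slice-back identity
  (reported range reproduces the peptide) is a tested invariant.
  Leucine/isoleucine are distinguished unless `collapse_il = TRUE`.

## Open design decisions, resolved

* *Ig-bound detection per pool or summed?* Per pool, any pool — summing
  would let many shallow observations mimic one confident one.
* *Best-allele or per-allele IC50?* Best over provided alleles by
  default (`per_allele = TRUE` restricts), since presentation by any
  allele suffices for antigenicity.
* *Luminex double normalization:* the published score normalizes to the
  anti-Ig bead yet is written as log2(exosome/uncoated); both statements
  are honored by computing the anti-Ig-normalized intermediates (kept as
  QC columns) whose ratio algebraically cancels the anti-Ig factor.
* *CDC averaging:* per-experiment cytotoxicity is computed
  replicate-matched before any averaging across replicates.
* *Serology sidedness:* two-sided by default, one-sided available.

## Problem sizes

The shipped tests and the acceptance script run the generator at the
study's native scale (2000 proteins, 42 proteomic samples) for 20–50
seeds, 100–200 seeds for the CDC power and calibration studies at 199
permutations each, and 50 seeds for the serology null calibration —
sizes chosen so the whole suite completes in about a minute while keeping
Monte-Carlo standard errors below a percentage point. At the default
dispersion the cascade's planted-antigen recall is ~0.90 with precision
~0.99; the binding step is the surface-enrichment conjunction, whose
per-antigen pass probability at 47% count CV is ~0.91 — an honest
property of the prescribed noise level, not a tunable constant.
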