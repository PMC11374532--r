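---
title: "Methods: the VDEG screen and its supporting machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the VDEG screen and its supporting machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdegscreen)
```

This vignette explains what the package computes, the assumptions behind
each stage, the defaults and why they were chosen, and what the synthetic
data generator does and does not emulate. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The design and the VDEG classification

The experimental layout is a two-arm time course with a shared baseline:
one control cell at day 0 (C0) and control/treatment cells (C, T) at days
1, 2, 4 and 8, with at least two (by default three) replicates per cell.
Because both arms are referenced to the same C0, the natural-course (NS:
C0 vs Cd) and treatment-course (TS: C0 vs Td) DEG sets are directly
comparable, and the same-day contrast (TC: Cd vs Td) decides whether an
apparent difference between courses is real at that day.

For each day the classifier takes the three DEG sets `A` (NS), `B` (TS),
`X` (TC) and assigns

| class | region | reading |
|---|---|---|
| g | `A ∩ B ∩ X` | responds in both courses, levels differ |
| f | `(B ∩ X) \ A` | treatment-only response |
| e | `(A ∩ X) \ B` | natural response suppressed by treatment |

The VDEG set is the disjoint union `e ∪ f ∪ g`, which algebraically
equals `X ∩ (A ∪ B)`; the test suite checks both routes against a
per-gene membership-pattern enumeration. Genes in `(A ∩ B) \ X` are
deliberately excluded: both courses moved them, but the arms do not
differ at that day. Direction (up/down) is the sign of the same-day
`log2(T/C)`; every VDEG belongs to `X`, so this sign is always defined
and its magnitude is at least the DEG threshold. Cross-period sharing
counts up- and down-memberships independently per day (a
direction-flipping gene can in principle enter both shared lists); the
shared-in-≥3-periods sets are the default enrichment study sets, using
the union `e ∪ f ∪ g` rather than any single class.

## Differential expression engine

The DE stage is an implemented, deliberately simple negative-binomial
Wald test (`Var = μ + αμ²`), not a wrapper around an external DE
package:

* **Normalization** — median-of-ratios size factors over genes nonzero
  in all samples; an informative error suggests a pseudo-reference when
  no such gene exists.
* **Dispersion** — gene-wise method of moments on normalized counts,
  residual contributions pooled within replicate cells, with the
  plug-in bias of `m²` as an estimate of `μ²` removed (denominator
  `m² − s²/n`). The shrinkage target is the same moment ratio pooled
  across all genes, which is nearly unbiased. Shrinkage strength is
  empirical-Bayes: the between-gene dispersion variance τ² is estimated
  by moments against each raw estimate's delta-method sampling variance
  (negative-binomial cumulants to fourth order, evaluated at the pooled
  dispersion), and each gene's prior weight is
  `max(n_prior/(n_prior + n_reps), V_g/(V_g + τ²))`. With only 2–4
  residual degrees of freedom per gene, a fixed-weight linear shrinkage
  of the zero-truncated raw estimates leaves genes with underestimated
  dispersion carrying inflated Wald statistics; the adaptive weight
  collapses to the pooled estimate when genes genuinely share one
  dispersion and retains gene-wise signal otherwise, with the fixed
  `n_prior` weight (default 5) as a floor.
* **Test** — group means on normalized counts; log2 fold change with a
  pseudo-count of 0.5 per group mean; the standard error from the
  delta method including the second-order term
  `V/m² + V²/(2m⁴)` (at three replicates the first-order term alone
  underestimates `Var(log m)` enough to visibly inflate the null tail);
  two-sided normal p; BH across all genes tested in the contrast. Genes
  all-zero in both groups are excluded and flagged.
* **Calling** — `|log2FC| ≥ lfc_min` (boundary inclusive, default 1.0)
  and `padj < padj_max` (strict, default 0.05).

Known limitations: no fold-change shrinkage, no covariates, no outlier
handling, no independent filtering; the pseudo-count biases low-count
fold changes toward zero. The all-null calibration of the pipeline as
built is itself an acceptance check in the test suite.

## Quantification

TPM divides counts by the annotated gene length and rescales each sample
to one million; per-period expression is the arithmetic replicate mean;
a gene is *not expressed* in a period when its mean TPM is below 1 (the
boundary value counts as expressed), and the globally expressed set
(expressed in ≥1 period) is the default enrichment background. PCA runs
on per-gene-centered `log2(TPM+1)` of the expressed genes — the
transform is a package choice (configurable), made for variance
stabilization since nothing in the source design fixes it.

## Profile clustering

Trajectories are `(0, log2FC_d1, …, log2FC_d4)` per gene, taken from a
single strategy's tables whether or not each day is significant.
Candidate templates start at 0 and change by an integer in `−c..c` per
step (81 candidates at `c = 1`); `m = 26` profiles are selected by
greedy max–min under distance `1 − r`, seeded with the flat profile,
whose correlation is defined as 0 against everything (it must survive as
the catch-all for flat trajectories). Genes go to the
highest-correlation profile, ties to the lowest id. Significance uses
the exhaustive within-gene permutation of the four post-baseline values
(4! = 24 orderings): the expected size of profile *m* is the summed
per-gene assignment probability, the p-value is the binomial upper tail
of the observed size, Bonferroni-corrected across profiles. This is a
simplified, deterministic variant of the classic short-time-series
permutation logic, not claimed to reproduce any specific tool's output;
`c` and `m` are configurable and their defaults follow the 0–25 profile
numbering convention common in such analyses.

## Enrichment

Over-representation is the hypergeometric upper tail `P(X ≥ k)` with BH
across terms — by default within namespace, mirroring grouped GO
reporting — or raw p (the convention used for BIN-style functional
categories, threshold 0.05). The background is the globally expressed
set by default and configurable, since study designs differ on this
point. TF-family enrichment is the same machinery with families as
pseudo-terms over the TF universe. Annotations are taken as given
(no ontology-graph propagation).

## Network, motifs, tiers and ranking

Each target's expression (`log2(TPM+1)`, standardized) is regressed on
all TFs with a 1000-tree random forest (`mtry = √K`, seeded per
target); variance-reduction importances are normalized to sum 1 per
target and edges kept at weight > 0.1, the published convention for
this estimator family. The input transform and estimator settings are
configurable because the source design leaves them open.

The scanner reports ATG-relative, inclusive coordinates: −1 is the base
immediately 5′ of the ATG, so a forward-strand match at 1-based string
position p in a promoter of length L starts at `p − 1 − L`, and a 6-mer
planted at −1594 spans −1594..−1589. Consensus motifs match exactly
(IUPAC codes; `N` in a promoter never matches); PWMs are scored by
log-odds against a 0-order background, with the score-tail probability
computed exactly by dynamic programming over the discretized score
distribution (granularity 1e-3 bits) — deterministic at desk scale, no
sampling. Evidence tiers: 1 = expression edge only; 2 = plus a hit of
the TF's motif in the target promoter in exactly one library; 3 = hits
in both libraries. Candidates are ranked by the mean of the eight
per-day TC and TS log2 fold changes, ties by the maximum single-day
value, missing genes flagged and ranked last.

## The synthetic generator

`simulate_counts` draws gene base means lognormally, assigns each gene
one class (`null`, `ns_equal`, `cppu_only`, `both_diff`,
`ns_suppressed`) multinomially, and builds per-cell log2 means so that
the noise-free membership pattern of each class matches its intended
Venn region with margin: `cppu_only` plants `±effect_lfc` in the T arm
only, `ns_suppressed` in the C arm only, `ns_equal` identically in
both, and `both_diff` plants `±effect_lfc` in C and `±2·effect_lfc` in
T. The both-arm magnitudes keep each constituent contrast comfortably
above the DEG threshold while the arm difference equals `effect_lfc`;
placing the weaker arm exactly at the calling threshold would leave
class-g genes falling out of set A half the time by sampling noise
alone. Counts are negative binomial (default dispersion 0.1, the
common order for bulk RNA-seq biological replicates) with lognormal
library factors (sdlog 0.15) recorded in the truth, which exercises the
median-of-ratios step.

Regulator (TF) genes carry a day-only temporal pattern shared by both
arms — they never enter the same-day T-vs-C contrast, so planted edges
cannot contaminate the VDEG class-recovery metrics. Planted TF→target
edges set the target's per-sample log2 mean to
`intercept + coefficient × z + noise`, where `z` is the TF's *realized*
per-sample expression (replicate noise included), standardized; the
dependency therefore lives at sample level, where expression-based
network inference can see it. Promoters are uniform ACGT backgrounds
with motifs written at recorded ATG-relative coordinates; any chance
background occurrence of a library consensus is scrubbed by local
resampling, and library consensi are rejection-sampled to avoid
equal/reverse-complement collisions, so planted-hit counts are exact.
Promoters are generated for the planted-edge targets (plus any genes
explicitly requested): the scan stage only ever consumes promoters of
candidate targets. One annotation term (`CK_PROCESS`) is planted
enriched among `cppu_only` genes (80% membership vs 2% background).

What the generator does **not** emulate: read-level artifacts (FASTQ,
mapping, GC or length bias within a gene), splice isoforms, batch
effects, dispersion–mean trends, correlated gene modules beyond the
planted edges, and non-uniform promoter composition. Passing tests
therefore demonstrate the *algebra and statistics* of the pipeline under
its stated model, not robustness to the full messiness of real
sequencing data.

## Numerical and degenerate-input choices

* All randomness flows from one root seed through deterministic
  per-stage substreams; two runs with the same configuration are
  byte-identical including the summary JSON (fixed serialization
  precision).
* Zero-variance cases: flat trajectories go to the flat profile;
  zero-variance network targets are skipped with a warning;
  zero-variance vectors yield missing correlations.
* Ties: profile assignment breaks toward the lowest profile id;
  candidate ranking breaks by maximum single-day fold change, then gene
  id.
* Degenerate inputs error early with the offending name: all-zero
  sample columns, missing design cells, study genes outside the
  population, promoters with non-ACGTN characters, motifs longer than
  the promoter.
* Problem sizes used by the tests and the acceptance script — 2000-gene
  default simulations, a 5000-gene all-null calibration (three
  replicates of it in the script), 100-promoter scan round-trips,
  five-seed network recovery — were chosen as the smallest sizes at
  which the binomial noise of the reported rates is well inside the
  margins being checked.

## Known limitations

The DE engine trades power and robustness for transparency (no shrunken
fold changes, normal rather than exact small-sample reference). The
profile significance scheme is exact only under exchangeability of the
four post-baseline values per gene. Motif evidence requires a curated
TF→motif mapping; motif–motif clustering and de novo discovery are out
of scope. Real-data headline counts from any particular study are not
reproduction targets: they depend on the underlying sequencing data,
which this package replaces with its generator.
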