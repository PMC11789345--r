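---
title: "Fiber-type scoring and subpopulation profiling: methods"
author: "fiberfa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fiber-type scoring and subpopulation profiling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skeletal muscle mixes fast-twitch and slow-twitch fibers, plus hybrid
fibers expressing both myosin programs and non-myofiber cells expressing
neither. Given a gene-by-cell count matrix from probe-based fixed-cell
single-cell RNA-seq of muscle, `fiberfa` quantifies each cell's
fast-twitch and slow-twitch character as two latent factor scores,
classifies cells into four classes (fast, slow, double-positive,
double-negative), and profiles subpopulations within the fast and slow
classes across experimental conditions.

The pipeline is:

1. **QC**: remove cells with total counts ≥ 5000 or a mitochondrial
   count share ≥ 10% (both boundaries inclusive on the removal side),
   plus zero-total cells.
2. **Normalization**: `log2(RPM + 1)`, RPM being counts scaled to a
   per-cell library of 10^6 over all genes that survive QC.
3. **Marker panel**: fast seeds (Myh1, Myh2, Myh4) and slow seed (Myh7),
   extended with genes ranked by Jaccard similarity of their GO
   annotation sets against the seeds (Myh7b, Myh11, Myh3 with the
   packaged fixture).
4. **Factor model**: exploratory factor analysis on the z-scored panel —
   KMO adequacy, Horn's parallel analysis for the factor count, minres
   extraction, oblique quartimin rotation, regression factor scores,
   then a data-driven mapping of factors to fiber programs.
5. **Classification**: thresholds on the two factor scores split cells
   into the four classes.
6. **Profiling**: graph clustering inside the fast and slow classes,
   cluster naming from significantly upregulated genes ("sigups"),
   condition-stratified cluster proportions, combination of designated
   slow-typical clusters, and a rank-sum check of the atrophy markers
   Fbxo32 and Trim63 across conditions.

```{r}
library(fiberfa)
sim <- generate_fiber_counts(sim_config(seed = 1))
ann <- generate_go_annotations(seed = 1)
res <- run_fiber_pipeline(sim$counts, ann, seed = 1)
res
write_report(res, "fiberfa_out")
```

## The factor model

Let `Z` be the cells × panel matrix of z-scored `log2(RPM + 1)` values
and `R = cor(Z)`. The model is `R ≈ Λ Φ Λᵀ + diag(u²)` with pattern
matrix `Λ` (genes × 2), factor correlation `Φ`, and uniquenesses `u²`.

* **Adequacy.** KMO compares squared correlations against squared
  anti-image partial correlations,
  `KMO = Σ r²ᵢⱼ / (Σ r²ᵢⱼ + Σ q²ᵢⱼ)`; per-variable MSA is the row-wise
  analogue. A variable with no shared variance is assigned MSA 0 rather
  than 0/0.
* **Factor count.** Horn's parallel analysis: observed eigenvalues of
  `R` are compared with the 95th percentile of eigenvalues from 100
  same-shape standard-normal datasets; the retained count is the run of
  leading eigenvalues above their null quantile. Replicates, quantile
  and the seed are configurable (`pa_reps`, `pa_quantile`).
* **Extraction.** Minres: uniquenesses are chosen to minimize the sum of
  squared off-diagonal residuals of `R − ΛΛᵀ − diag(u²)` (L-BFGS-B over
  `u² ∈ [10⁻⁷, 1]`; the near-zero floor lets exact low-rank structure
  reach communality 1, at the cost of admitting Heywood-adjacent
  solutions, which the tests monitor through the `|loading| ≤ 1`
  invariant). An iterated principal-axis alternative (`method = "pa"`)
  is provided and doubles as an optimization oracle in the tests.
* **Rotation.** Quartimin (oblimin with γ = 0) by oblique gradient
  projection over unit-column rotation matrices `T`, minimizing
  `Q(Λ) = Σᵢ Σ_{k≠l} λ²ᵢₖ λ²ᵢₗ` with `Λ = A(Tᵀ)⁻¹`, `Φ = TᵀT`. Ten
  seeded random restarts guard against local minima. Convergence is a
  projected-gradient norm below 10⁻⁶; a line-search stall with gradient
  norm below 10⁻⁵ (criterion differences at float precision) also counts
  as converged. `ΛΦΛᵀ = AAᵀ` holds exactly by construction, so
  communalities are rotation invariants.
* **Scores.** Regression (Thurstone) scores `F = Z R⁻¹ (ΛΦ)`; Bartlett
  weighted-least-squares scores are available by configuration. A
  singular `R` is an error unless a ridge is supplied.
* **Fiber mapping.** The factor with the largest mean |loading| over the
  fast seeds is "fast", likewise "slow"; both programs winning the same
  factor is an error rather than a silent guess. Output factors are
  reordered fast-first and sign-aligned so seed genes load positively.

Extraction method, score estimator, parallel-analysis operationalization
and the z-scoring of expression are all package decisions — the workflow
this package implements names only the rotation and the use of parallel
analysis — chosen as the most common defaults in psychometric practice
and recorded in the run report.

## Classification

A cell is positive for a program when its score reaches the threshold
(boundary inclusive, so a score exactly at τ counts as positive — a
deterministic tie rule). The reference analysis set thresholds manually
from score histograms; `propose_thresholds()` automates that reading:
per factor, the minimum of a kernel density estimate between the two
largest modes, accepted only if the valley dips below 0.8× the lower of
the two modes (this rejects sampling wiggles on a single hump); if the
density is effectively unimodal it falls back to the midpoint of two
1-D k-means centers, with a warning. Manual `tau_fast`/`tau_slow` in the
configuration always take precedence, and the report records which
provenance was used. Fewer than 20 cells is an error advising manual
thresholds.

## Subpopulation profiling

Within each of the fast and slow classes: principal components (up to
30) of the subpopulation's expression feed a k-nearest-neighbour graph
(k = 15, clamped with a warning for small subpopulations) whose
communities are found by Louvain modularity optimization at resolution
1.0 under a fixed seed. The method is a package decision — the reference
workflow reports only cluster counts — and matches the standard
graph-clustering recipe of single-cell practice.

Sigups are genes with one-vs-rest Wilcoxon rank-sum (one-sided,
"greater") BH-adjusted p < 0.05 and log2 fold-change ≥ 1 in the cluster;
both knobs are configurable. Cluster names follow the grammar: the
sigup with the largest fold-change names the cluster as `G+`; clusters
sharing a name — in particular clusters with identical sigup sets — are
indexed `G+(1)`, `G+(2)`, … by descending size; clusters without sigups
are `Unknown`, indexed likewise. "Sharing" is resolved at the level of
the display name so that names are always unique, which subsumes the
identical-set case.

Proportions are tallied per condition over all classified cells, with
subpopulation-qualified cluster labels (`fast:Ckm+(1)`, `slow:Unknown(2)`,
…) for cells in a clustered subpopulation and the class label otherwise;
each condition row of the fraction matrix sums to 1.
`combine_clusters()` sums designated columns — by default the pipeline
combines all slow-subpopulation clusters, the slow-typical population
whose depletion across conditions is the analysis' headline contrast;
`combine_names` overrides the selection.

## The synthetic generator

`generate_fiber_counts()` emulates the statistical structure the
analysis assumes, with full ground truth:

* Four true classes per condition (default mix fast 0.5, slow 0.2,
  hybrid 0.1, negative 0.2) with a multiplicative depletion of the slow
  class (default 0.5) in designated diseased conditions, renormalized.
* Program genes elevated `2^program_mean_lfc`-fold (default 4) in their
  class. Elevation scales expected counts directly, without library
  renormalization, so the fast/negative mean-count ratio of fast program
  genes equals `2^program_mean_lfc` exactly by construction and
  program-positive cells carry correspondingly more RNA.
* Counts are gamma-Poisson: negative binomial with dispersion 0.5
  (variance `μ + 0.5μ²`) around library-size-scaled means; library
  sizes are log-normal (median 1100 for a program-negative cell,
  σ_log = 0.3), far enough below the 5000-count QC line that only
  planted outliers cross it.
* Mitochondrial expression lives in dedicated `mt-` genes whose
  expected share of the cell's total is an exactly realized per-cell
  fraction, normal (0.04, 0.01) truncated to [0.002, 0.07] — the upper
  truncation keeps count noise from pushing regular cells over the 10%
  QC line.
* 10% of cells are planted QC outliers (half high-total, half
  mitochondrial fraction uniform on [0.18, 0.35], both chosen with
  enough margin that the realized values cross the cutoffs essentially
  always).
* Baseline weights put background genes (60 filler, 2 neutral myosins,
  2 atrophy markers) at weight 4 and resting program genes at 1 (slow
  program 3 — the slow factor has only two indicator genes, and a
  slightly higher resting expression keeps their correlation, and hence
  the two-indicator factor, well conditioned).
* All randomness flows from one seed through a counter-based per-cell
  substream: outputs are byte-identical across runs and independent of
  generation order.

The generator does **not** emulate ambient RNA, doublets beyond the
hybrid class, batch effects, probe chemistry, gene-length effects, or
the near-total dominance of myosin transcripts in real myofibers.
Passing recovery tests on this data therefore show that the estimators
are correct and calibrated for well-separated programs under negative
binomial noise — not that real muscle data will separate as cleanly.

`generate_go_annotations()` builds the companion GO fixture: seed genes
receive disjoint term blocks; designated similar genes share an exactly
realized fraction of one seed's terms (defaults: Myh7b 0.6 of Myh7,
Myh11 0.5 of Myh7, Myh3 0.4 of Myh1, ten terms per gene), so every
pairwise Jaccard index is known in closed form and the packaged ranking
reproduces the published panel.

## Numerical choices and degenerate inputs

* Ties in the similarity ranking break lexicographically; cluster
  renumbering and name indexing order by descending size with
  first-appearance tie-break — all outputs are total orders.
* The correlation matrix is inverted directly; singularity is an error
  with an explicit `ridge` escape hatch in `kmo()` and
  `score_factors()`.
* Constant panel variables are an error naming the variable.
* Zero-total cells are removed at QC with reason `zero_total`; one
  reaching normalization is a contract violation error.
* Empty simulations (0 cells) are valid and produce empty, well-formed
  containers.
* Cluster counts below 3 cells are an error; `n_neighbors` clamps with
  a warning.

## Problem sizes used by the test-suite and acceptance script

The default simulated study is 667 cells × 3 conditions (≈ 2000 cells,
~1800 after QC) over a 78-gene panel; calibration loops use 100 seeded
replicates (parallel-analysis null, depletion-direction recovery at 300
cells per condition) and 200 label permutations for sigup calibration;
the loading-stability reference fit uses ≈ 9000 cells after QC. These
sizes were chosen to give the binomial and Monte-Carlo tolerances quoted
in the tests comfortable margins.

## Known limitations

* The two-indicator slow factor is intrinsically fragile; with weaker
  slow-program correlation than the defaults produce, minres can drift
  toward Heywood-type solutions (one communality near 1).
* Automatic thresholds assume the score distributions are bimodal;
  strongly imbalanced class mixes can defeat the valley detector and
  trigger the k-means fallback.
* Proportions are descriptive tabulations; the package deliberately
  performs no inferential test on composition differences between
  conditions.
* The TOML reader covers the subset the configuration uses (tables,
  scalars, flat arrays); it is not a general TOML parser.
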