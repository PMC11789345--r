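# fiberfa

Fiber-type scoring and subpopulation profiling for single-cell muscle
transcriptomics.

Skeletal muscle mixes fast-twitch and slow-twitch fibers, hybrid fibers
expressing both myosin programs, and non-myofiber cells expressing
neither. `fiberfa` takes a gene-by-cell count matrix (Matrix Market
triplets with features/barcodes/metadata sidecars) and GO annotations,
and turns them into per-cell fiber-type calls and condition-stratified
composition tables. It is written for transcriptomics analysts studying
muscle remodelling — for example the selective loss of slow-typical
fiber populations under systemic disease — who want every stage of the
analysis reproducible and testable without access to the original
sequencing run.

## What it computes

1. **QC and normalization** — cells with total counts ≥ 5000 or a
   mitochondrial share ≥ 10% are removed; retained counts become
   log2(RPM + 1), RPM = counts / cell total × 10⁶.
2. **Marker panel** — fast seeds (*Myh1*, *Myh2*, *Myh4*) and slow seed
   (*Myh7*) are extended with genes ranked by the Jaccard index
   J(A, B) = |A ∩ B| / |A ∪ B| of their GO term sets against the seeds
   (*Myh7b*, *Myh11*, *Myh3* with the packaged fixture).
3. **Factor model** — exploratory factor analysis on the z-scored panel:
   R ≈ ΛΦΛᵀ + diag(u²), with KMO sampling adequacy, Horn's parallel
   analysis for the factor count, minres extraction, oblique quartimin
   rotation (minimizing Q(Λ) = Σᵢ Σ_{k≠l} λ²ᵢₖλ²ᵢₗ by gradient
   projection), and regression factor scores F = Z R⁻¹(ΛΦ). The factor
   loading on the fast seeds identifies the fast factor, likewise slow.
4. **Four-class fiber typing** — thresholds τ_fast, τ_slow on the two
   scores (automatic valley detection on the score histograms, or
   manual) split cells into fast, slow, double-positive and
   double-negative.
5. **Subpopulation profiling** — PCA + kNN-graph Louvain clustering
   within the fast and slow classes; clusters named after their
   significantly upregulated genes ("sigups": one-vs-rest Wilcoxon,
   BH-adjusted p < 0.05, log2 fold-change ≥ 1) as `G+`, indexed
   `G+(1)`, `G+(2)` when shared, `Unknown` when empty; per-condition
   cluster proportions; combined fractions of designated slow-typical
   clusters; a rank-sum check of the atrophy markers *Fbxo32* and
   *Trim63* across conditions.

A negative-binomial synthetic generator with complete ground truth
(`generate_fiber_counts()`, `generate_go_annotations()`) emulates the
assumed data structure — two expression programs, hybrids, QC outliers,
condition-dependent slow-class depletion — so the whole pipeline runs
and is validated offline.

## Worked example

```r
library(fiberfa)

sim <- generate_fiber_counts(sim_config(seed = 1))   # ~2000 cells, 3 conditions
ann <- generate_go_annotations(seed = 1)             # designed GO fixture
res <- run_fiber_pipeline(sim$counts, ann, seed = 1)
res
```

```
<fiber_pipeline>
  QC: 1810 / 2001 cells kept
  panel (7 genes): Myh1, Myh2, Myh4, Myh7, Myh7b, Myh11, Myh3
  factors: m = 2, KMO = 0.709
  thresholds: tau_fast = -0.110, tau_slow = 0.557 (auto)
  classes:

double_negative            fast            slow double_positive 
            346             995             310             159 
  combined slow-typical fraction (slow:Myh1+ + slow:Unknown(1) + ... + slow:Unknown(7)):
  Ctrl      P   P_PG 
0.2030 0.1860 0.1248 
```

Reading the output: QC removed the planted outliers (~10% of cells);
parallel analysis retained m = 2 factors on the 7-gene myosin panel;
the automatic thresholds split the cells into the four fiber classes;
and the combined slow-typical fraction drops from 0.203 in the control
condition to 0.125 in the depleted condition — the generator planted a
0.5 depletion of the slow class in `P_PG`, and the pipeline recovers
its direction. The factor loadings behind the calls:

```r
round(res$factors$loadings, 2)
#>       F_fast F_slow
#> Myh1    0.63  -0.02
#> Myh2    0.69   0.03
#> Myh4    0.69  -0.02
#> Myh7   -0.02   0.65
#> Myh7b   0.02   0.70
#> Myh11  -0.16  -0.09
#> Myh3   -0.13  -0.13
```

Fast seeds load on the fast factor, slow genes on the slow factor, and
the neutral myosins on neither. `write_report(res, "out/")` writes
loadings, scores, classes, clusters, sigups, proportions and a JSON run
report (seeds, configuration, thresholds used, stage tallies);
identical inputs and seed give byte-identical files.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/fiberfa simulate --out simdir --seed 4
Rscript inst/scripts/fiberfa run --counts simdir/matrix.mtx \
    --features simdir/features.tsv --barcodes simdir/barcodes.tsv \
    --meta simdir/meta.tsv --gaf ann.gaf --config cfg.toml --out rundir
```

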