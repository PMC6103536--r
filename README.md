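# prism

Cell-to-cell chromatin accessibility variability from single-cell ATAC-seq.

## What it is for

Single-cell ATAC-seq yields a sparse, near-binary peaks-by-cells matrix.
Given a set of peaks sharing an annotation — a transcription factor's
ChIP-seq binding sites, motif matches — `prism` quantifies how differently
individual cells use those regions, while cancelling the technical
covariates (GC content, mean accessibility) that otherwise dominate such
comparisons. It is written for regulatory genomicists asking which chromatin
features suppress cell-to-cell variability (insulators, lineage-determining
factors) and which amplify it.

## The statistic

Each cell is a binary vector over the peak subset. Pairs of cells are
compared with the angular cosine distance

    d(A, B) = arccos( A·B / (‖A‖‖B‖) ) / (π/2)  ∈ [0, 1],

so cells accessible at the same sites score 0 and cells accessible at
disjoint sites score 1. The distance matrix is embedded by classical
multidimensional scaling (Gower double-centering of squared distances,
spectral decomposition), and the **raw variability** is the mean distance of
cells to their centroid. Technical bias is removed in two resampling stages:

    bias-corrected = raw / mean(raw of GC- and accessibility-matched background sets)
    final          = bias-corrected / mean(bias-corrected of random negative-control sets)

Final variation is measured in units of background noise: **1 means no more
variable than chance**; the negative controls also provide a Z-score and an
empirical p-value. A titration benchmark (mixing an original and a
GC-matched peak block across cells in 50 steps) verifies that the estimator
traces the expected inverse-U over the mixture proportion, scored by a
concavity U statistic (Spearman correlation of successive differences with
the sequence 49…1) and the mean squared error around a LOESS fit.

## Worked example

Everything below runs on synthetic data; no downloads are needed.

```r
library(prism)

# A null universe: 200 cells x 2,000 peaks, independent Bernoulli entries,
# annotated with GC and per-peak mean accessibility.
probs <- withr::with_seed(11, pmin(0.5, pmax(0.05, rnorm(2000, 0.45, 0.008))))
u <- generate_null_universe(fixture_spec(acc_probs = probs, seed = 11))

# Pick a 200-peak "feature" and inject two-population heterogeneity at it:
# half the cells become accessible at one sub-block, half at the other.
blk <- withr::with_seed(12, sort(sample(2000, 200)))
fs  <- feature_set(blk, "example_tf", 2000)
u2  <- inject_block_heterogeneity(u, blk, h = 1, seed = 13)

final_variation(u2$binary, fs, u2$peaks, background_config(seed = 14))
#> <prism_variability> 'example_tf'
#>   raw 0.5205 | bias-corrected 1.036 | final 1.043
#>   z 33.7, empirical p 0.0323 (30 backgrounds, 30 controls)
```

The feature's cells-to-centroid dispersion is 3.6% above its matched
backgrounds and 4.3% above random negative controls — far outside the
control spread (z = 33.7) and above *all* 30 controls (the minimal empirical
p, 1/31 ≈ 0.032). On the unmodified null universe the same pipeline returns
final ≈ 1.

The titration benchmark, on the packaged two-block fixture:

```r
tt_u <- generate_null_universe(fixture_spec(acc_profile = "bimodal", seed = 1))
tt   <- run_titration(tt_u$binary, tt_u$peaks, simulation_config(seed = 1))
tt
#> <prism_titration> model 1 subtype A: 50 steps, U = 0.987, LOESS MSE = 4.02e-07
glance(tt)$argmax_proportion
#> [1] 0.52
autoplot(tt)   # inverse-U curve with its LOESS smooth
```

Variability peaks at a near 50–50 mixture (0.52), the curve is almost
perfectly concave (U = 0.987 of a possible 1), and the scatter around the
smooth trend is of order 10⁻⁷ — the estimator adds essentially no noise of
its own. Results carry `tidy()`/`glance()` methods, and the file-level
wrappers (`prism_annotate()`, `prism_variability()`, `prism_simulate()`) or
the CLI (`inst/cli/prism.R`) run the same pipeline on a Matrix-Market + BED +
barcode bundle with reproducibility manifests in every output.

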