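# mosaicclust

Consensus clustering for ensembles of clustering runs with **unequal sample
coverage** ("missing labels").

## The problem

Integrative subtyping of a clinical cohort often produces many clustering
runs of the *same* samples — one per combination of omics platforms fed into
a fusion + clustering pipeline. Because each subject is missing some
platforms, each run covers a different subset of the cohort: a label matrix
with rows = samples, columns = runs, and many `NA` cells.

Classical consensus clustering summarises such an ensemble by the
co-association (consensus weight):

CW(i, j) = (# runs where i and j share a cluster) / (# runs where both i and j are observed)

CW alone is misleading when coverage varies. A pair co-observed in two runs
that happened to agree gets CW = 1, the same as a pair co-clustered in
thirty informative runs — and a pair co-observed only in runs that put
*everyone* in one cluster gets CW = 1 from no evidence at all.

## The method

`mosaicclust` normalizes CW against a permutation null built from the
ensemble itself. Each column of the label matrix is permuted among its
*observed* positions (missing cells stay fixed), the permuted CW is
recomputed, and the one-sided empirical p-value of the observed CW is
estimated per pair with add-one smoothing over N permutations:

P(i, j) = (1 + #\{permutations with CW\* ≥ CW\}) / (N + 1),  NCW(i, j) = 1 − P(i, j)

Uninformative co-clustering is thereby zeroed out (the constant-run pair
above gets NCW = 0 exactly), and equal CWs backed by different amounts of
evidence separate. Convergence in N is monitored by the squared Euclidean
distance between cumulative NCW estimates every 1000 permutations.

The NCW matrix is then consensus-clustered in the usual Monti resampling
style (subsample items, cluster `1 − NCW` with hierarchical / spectral /
k-medoids engines, accumulate a consensus matrix per k = 2..maxK), with
CDF/delta-area model selection and item-/cluster-consensus diagnostics.

## Worked example

```r
library(mosaicclust)

# a synthetic 60-sample cohort: 3 true clusters, 30 runs whose coverage
# ranges from 40% to 100%, 10% label noise
coh <- generate_cohort(n_samples = 60, k_true = 3, n_runs = 30,
                       coverage_range = c(0.4, 1), noise_rate = 0.1, seed = 1)

ncw <- compute_ncw(coh$matrix, nperm_blocks = 10, seed = 1)
#> <ncw_result> 60 samples; 10000 permutations (10 blocks x 1000); seed 1
#>   stability sum of squared changes, last block: 0.000367

head(tidy(ncw), 4)
#> # A tibble: 4 x 6
#>   sample_a sample_b     cw     ncw observed exceed
#> 1 s01      s02      0.25   0.185         16   8147
#> 2 s01      s03      0.0714 0.00470       14   9953
#> 3 s02      s03      0.118  0.00930       17   9907
#> 4 s01      s04      0.0667 0.00310       15   9969

fit <- consensus_cluster_ncw(ncw, maxK = 6, seed = 1)
fit$areas
#>       k  area delta_area
#>       2 0.451     0.451
#>       3 0.680     0.506     <- delta-area elbow: chosen_k = 3
#>       4 0.701     0.0310
#>       5 0.722     0.0301
#>       6 0.737     0.0208

nmi(consensus_classes(fit, 3), coh$truth)
#> [1] 1
```

Reading the output: pair s01/s02 was co-observed in 16 of 30 runs and
co-clustered in a quarter of them; 81% of permutations did at least as well,
so its NCW (0.185) is *lower* than its CW — that similarity is mostly
chance. The delta-area curve jumps at k = 3 and the partition at k = 3
matches the generating truth exactly (NMI = 1) despite 10% label noise and
runs covering as little as 40% of the cohort.

Diagnostics: `plot_compare_cw(ncw)` (NCW vs CW, colored by co-observation
count), `plot_stability(ncw)` (per-block convergence), `plot_consensus(fit)`
(heatmap, CDF, delta-area). Results tidy into tibbles via `tidy()` /
`glance()`.

## Command line

```sh
inst/cli/mosaicclust ncw     --input labels.tsv --min-coverage 0.4 --nperm 10 --seed 1 --out-dir out/
inst/cli/mosaicclust cluster --input labels.tsv --maxk 6 --alg hc --seed 1 --out-dir out/ --plots
```

Every run writes a `manifest.json` sufficient to reproduce its numeric
outputs bit-identically.

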