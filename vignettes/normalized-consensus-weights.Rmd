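---
title: "Normalized consensus weights for label ensembles with unequal coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized consensus weights for label ensembles with unequal coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicclust)
```

## The model

The input is a label matrix: `n` samples by `R` clustering runs, each cell
an integer cluster label or `NA` where the run did not cover the sample.
Labels are meaningful only within a column; `mosaicclust` never recodes
them across columns, and all downstream computation depends only on
within-column equality (so any bijective per-column renaming leaves every
result unchanged — a property the test suite checks).

**Step 1 — consensus weights.** For a pair (i, j), `cocluster_counts()`
tallies `observed`, the number of runs covering both samples, and
`together`, the number of those in which they share a label. The consensus
weight is `CW = together / observed`. The denominator is deliberately
restricted to co-observed runs (pairwise-available-case): dividing by the
total number of runs would convert missingness itself into apparent
dissimilarity. Pairs with `observed = 0` have no defined CW and are carried
as `NA`, never silently imputed.

**Step 2 — permutation normalization.** CW conflates genuine co-clustering
with what the ensemble would produce by chance. The null keeps everything
about the ensemble fixed except the assignment of labels to samples: each
column's observed labels are shuffled uniformly among that column's
observed positions (missing cells immobile). Over `N` such permutations of
the whole matrix, the one-sided empirical p-value per pair is

    P(i,j) = (1 + #{ permuted CW >= observed CW }) / (N + 1)

and the normalized consensus weight is `NCW = 1 - P`. Because missing
positions never move, `observed` is permutation-invariant and only
`together` needs recomputing — the engine exploits this (a C++ loop over
label groups per column) without changing semantics.

**Step 3 — consensus clustering of NCW.** The NCW matrix is treated as a
similarity and ensembled in the Monti resampling style: for each
k = 2..maxK, repeatedly subsample items, cluster the induced `1 - NCW`
distance (or the NCW affinity, for the spectral engine), and accumulate the
fraction of co-sampled iterations in which each pair co-clusters. The per-k
consensus matrix is hierarchically clustered to give the consensus tree and
the cut at k; the CDF of consensus values per k, the area under it, and the
relative area gain from k-1 to k (delta-area) drive model selection.

## Why the normalization matters

Three consequences, each encoded as a test:

- a pair co-observed **only in constant-label runs** has CW = 1, but every
  permutation reproduces CW = 1, so `P = 1` and `NCW = 0` exactly —
  uninformative co-clustering carries no weight;
- two pairs with **identical CW but unequal support** (say 2 vs 10
  informative runs) separate: more informative runs give the null more
  chances to fall short, so the better-supported pair earns the higher NCW;
- with **complete data** all pairs face exchangeable nulls, so NCW is a
  non-decreasing function of CW — normalization can reorder pairs only
  when coverage differs.

## Parameters

| parameter | where | default | notes |
|---|---|---|---|
| `nperm_blocks` | `compute_ncw` | 10 | total permutations = blocks × `block_size`; judge sufficiency from the stability trace |
| `block_size` | `compute_ncw` | 1000 | the snapshot interval of the stability trace |
| `unobserved_policy` | `compute_ncw` | `"error"` | never-co-observed pairs abort with a pointer to `filter_by_coverage()`; `"zero"` for exploratory use |
| `min_rate` | `filter_by_coverage` | — | existing-sample-rate threshold; the comparison is inclusive (0.40 keeps runs covering exactly 40%), the conservative reading |
| `mode`, `n` | `select_runs` | — | EQUAL keeps runs built from exactly n platforms, LARGER from n or more |
| `maxK` | `consensus_cluster_ncw` | 6 | must not exceed n − 1 |
| `reps`, `p_item` | `consensus_cluster_ncw` | 100, 0.8 | common consensus-clustering practice; `p_item = 1` with a deterministic engine makes the whole step deterministic and reps-invariant |
| `inner_alg` | `consensus_cluster_ncw` | hierarchical | spectral consumes NCW directly as an affinity (normalized-Laplacian embedding + seeded k-means); k-medoids partitions `1 − NCW` |
| `linkage` | `consensus_cluster_ncw` | average | also used for the consensus tree; `"ward"` maps to `ward.D2` |

## Numerical and design choices

- **Add-one p-value estimator.** `P = (exceed + 1)/(N + 1)` rather than
  `exceed/N`: a finite sample can never certify impossibility, so `P > 0`
  and `NCW < 1` strictly. The degenerate all-exceed case still gives
  `NCW = 0` exactly.
- **Per-pair null.** Each pair's observed CW is compared against that same
  pair's permuted distribution. Pooling all pairs into one ECDF is a
  coherent alternative (it would tie each pair's NCW to the global mixture
  of coverages); per-pair is implemented because the quantity being
  normalized — the chance a *specific* pair co-clusters given its own
  co-observation pattern — is pair-specific.
- **Weak inequality** (`>=`) in the exceedance count: the conservative
  one-sided convention; equality mass counts against significance.
- **Seeding.** One master seed; per-block child seeds are drawn up-front
  with `sample.int(.Machine$integer.max, nperm_blocks)`, so any block can
  be reproduced in isolation and block-level parallelism would not change
  results. Identical (matrix, seed, blocks) gives bit-identical exceedance
  counts.
- **k selection.** Delta-area elbow: `chosen_k` is the k ≥ 3 maximising
  delta-area (ties resolved toward the smaller k by the argmax scan order),
  since delta-area at k = 2 is the raw area and not comparable; an explicit
  `elbow_threshold` switches to "largest k exceeding the threshold".
- **Degenerate inputs.** Columns observed for fewer than two samples are
  rejected at validation by name; all-missing columns likewise. Singleton
  clusters get cluster-consensus 0 by convention. Consensus entries for
  never-co-sampled pairs (possible at small `reps` × `p_item`) are 0 with a
  warning.
- **NMI.** Normalized by the square root of the entropy product
  (`variant = "max"` available for sensitivity checks). When either
  partition has zero entropy, conventions in the wild disagree; here NMI is
  1 if the two partitions are identical as set-partitions and 0 otherwise.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the method consumes:
a fixed true partition (largest-remainder allocation of the requested
proportions, so no cluster is empty), per-run coverage drawn uniformly from
`coverage_range` with independent per-sample observation, true labels for
observed cells, and a `noise_rate` fraction of observed cells flipped to a
uniformly different cluster. Defaults (60 samples, 3 clusters, 30 runs,
coverage 0.35–1) mirror a deeply multi-omic cohort in which combination
networks cover from roughly a third to all of the samples. The optional
`tiers` argument assigns each run an `n_omics` value and shrinks its
coverage interval as platforms accumulate — more required platforms, fewer
complete cases — which exercises the EQUAL/LARGER selection strategies.

What the generator does **not** emulate: correlated missingness across runs
(subjects missing one platform are missing it in every combination
containing it, so real coverage patterns are nested, not independent);
run-to-run correlation beyond the shared truth; runs whose label count
differs from the true k; and any structure of the omics features
themselves. Passing recovery tests on these cohorts therefore demonstrates
the ensembling machinery, not the upstream fusion or clustering quality on
real data.

## Problem sizes used by the test suite

Recovery experiments run at 60 samples × 30 runs with 10 permutation blocks
(the package's documented study conditions), averaged over 10 seeds for the
partial- vs complete-coverage comparison and the noise curve; oracle
equivalence uses 200 random 8 × 5 matrices with 30% missingness; exhaustive
permutation enumeration uses grids whose arrangement space is ≤ 10⁴;
stability and monotonicity properties use 20 seeded cohorts each. These
sizes make every check exact or tightly bounded while keeping the suite
desk-scale.

## Limitations

- NCW is a resolution-limited Monte-Carlo quantity: with `N` permutations,
  p-values below `1/(N + 1)` saturate, so ranking among very strong pairs
  requires more blocks.
- There is no analytic null; highly structured ensembles (few, large label
  groups) make the permutation distribution coarse, and the weak-inequality
  convention then pulls NCW down.
- Never-co-observed pairs are a modelling gap, not a nuisance: no
  permutation scheme can manufacture evidence for them. The default is to
  refuse; the `"zero"` policy is a declared assumption that absence of
  evidence is dissimilarity.
- The delta-area elbow, like all internal k-selection rules, can prefer a
  coarser k when clusters are strongly nested; the per-k outputs are all
  retained so the choice can be overridden.
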