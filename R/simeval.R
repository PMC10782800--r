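#' Generate a synthetic missing-label cohort with known ground truth
#'
#' Emulates the statistical structure of a cohort clustered many times from
#' different omics combinations: a true partition of the samples; one column
#' per clustering run, each covering only a random subset of samples (as
#' when the omics combination behind a run lacks data for some subjects);
#' and label noise flipping a fraction of observed labels to a different
#' cluster. Only the label-matrix structure is simulated — no omics
#' features, affinity matrices or network fusion.
#'
#' Per run, a coverage is drawn uniformly from `coverage_range` and each
#' sample is observed independently with that probability; observed samples
#' receive their true label, then `round(noise_rate * n_observed)` observed
#' cells, chosen uniformly, are flipped to a uniformly random *different*
#' cluster (per-run label alphabets therefore stay within `1..k_true`).
#' Runs with fewer than two observed samples are redrawn (bounded retries).
#'
#' With `tiers`, each run gets an `n_omics` value and its coverage interval
#' shrinks toward `coverage_range[1]` as `n_omics` grows — mimicking how
#' combinations of more platforms cover fewer complete cases — and the
#' cohort's label matrix carries the corresponding `run_meta`.
#'
#' @param n_samples Number of samples. Default 60.
#' @param k_true Number of true clusters (>= 2). Default 3.
#' @param n_runs Number of clustering runs (columns). Default 30.
#' @param cluster_proportions Simplex vector of length `k_true`; cluster
#'   sizes are fixed by largest-remainder rounding of these proportions (so
#'   every true cluster is non-empty), then shuffled over samples. Default
#'   equal proportions.
#' @param coverage_range `c(lo, hi)` in (0, 1]: per-run coverage interval.
#'   Default `c(0.35, 1)`, the span seen in deep multi-omics combination
#'   sets.
#' @param noise_rate Fraction of observed labels flipped, in \[0, 1).
#'   Default 0.1.
#' @param tiers Optional integer vector of length `n_runs`: `n_omics` per
#'   run (see Details).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_cohort`: list with `matrix` (a [label_matrix]),
#'   `truth` (named integer vector of true clusters) and `spec` (parameter
#'   echo).
#' @examples
#' coh <- generate_cohort(n_samples = 20, k_true = 2, n_runs = 5, seed = 7)
#' table(coh$truth)
#' @export
generate_cohort <- function(n_samples = 60, k_true = 3, n_runs = 30,
                            cluster_proportions = rep(1 / k_true, k_true),
                            coverage_range = c(0.35, 1), noise_rate = 0.1,
                            tiers = NULL, seed = 1) {
  stopifnot(k_true >= 2, length(cluster_proportions) == k_true,
            all(cluster_proportions > 0),
            length(coverage_range) == 2,
            coverage_range[1] > 0, coverage_range[1] <= coverage_range[2],
            coverage_range[2] <= 1,
            noise_rate >= 0, noise_rate < 1,
            n_samples >= k_true, n_runs >= 1)
  if (!is.null(tiers)) stopifnot(length(tiers) == n_runs, all(tiers >= 1))
  props <- cluster_proportions / sum(cluster_proportions)

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)

  # largest-remainder allocation keeps every true cluster non-empty
  sizes <- floor(props * n_samples)
  sizes <- pmax(sizes, 1L)
  while (sum(sizes) > n_samples) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  rem <- props * n_samples - sizes
  while (sum(sizes) < n_samples) {
    i <- which.max(rem)
    sizes[i] <- sizes[i] + 1L
    rem[i] <- -Inf
  }
  truth <- sample(rep.int(seq_len(k_true), sizes))
  names(truth) <- sprintf("s%02d", seq_len(n_samples))

  cov_interval <- function(j) {
    lo <- coverage_range[1]; hi <- coverage_range[2]
    if (is.null(tiers)) return(c(lo, hi))
    # more platforms integrated -> fewer complete cases: shrink hi toward lo
    t_rel <- (tiers[j] - min(tiers)) / max(max(tiers) - min(tiers), 1L)
    c(lo, hi - (hi - lo) * t_rel * 0.8)
  }

  grid <- matrix(NA_integer_, n_samples, n_runs,
                 dimnames = list(names(truth), sprintf("run%03d", seq_len(n_runs))))
  for (j in seq_len(n_runs)) {
    iv <- cov_interval(j)
    for (try in seq_len(100)) {
      cov_j <- stats::runif(1, iv[1], iv[2])
      obs <- which(stats::runif(n_samples) < cov_j)
      if (length(obs) >= 2) break
      if (try == 100) stop("could not draw a run with >= 2 observed samples; ",
                           "raise coverage_range", call. = FALSE)
    }
    col <- rep(NA_integer_, n_samples)
    col[obs] <- truth[obs]
    n_flip <- round(noise_rate * length(obs))
    if (n_flip > 0) {
      flip <- sample(obs, n_flip)
      col[flip] <- vapply(col[flip], function(l) {
        sample(setdiff(seq_len(k_true), l), 1L)
      }, integer(1))
    }
    grid[, j] <- col
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  meta <- if (!is.null(tiers)) {
    tibble::tibble(run_id = colnames(grid), n_omics = as.integer(tiers))
  } else NULL
  structure(list(
    matrix = label_matrix(grid, run_meta = meta),
    truth = truth,
    spec = list(n_samples = n_samples, k_true = k_true, n_runs = n_runs,
                cluster_proportions = props, coverage_range = coverage_range,
                noise_rate = noise_rate, tiers = tiers, seed = seed)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples, %d runs, k_true = %d, noise %.2f, seed %d\n",
              x$spec$n_samples, x$spec$n_runs, x$spec$k_true,
              x$spec$noise_rate, x$spec$seed))
  print(x$matrix)
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes the label matrix TSV (`labels.tsv`), the ground truth
#' (`truth.tsv`: sample_id, true_cluster), the run metadata when present
#' (`run_meta.tsv`), and the generating parameters (`spec.json`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(labels = file.path(dir, "labels.tsv"),
         truth = file.path(dir, "truth.tsv"),
         spec = file.path(dir, "spec.json"))
  write_label_matrix(cohort$matrix, p[["labels"]])
  readr::write_tsv(tibble::tibble(sample_id = names(cohort$truth),
                                  true_cluster = unname(cohort$truth)),
                   p[["truth"]], progress = FALSE)
  if (!is.null(cohort$matrix$run_meta)) {
    pm <- file.path(dir, "run_meta.tsv")
    readr::write_tsv(cohort$matrix$run_meta, pm, progress = FALSE)
    p <- c(p, run_meta = pm)
  }
  jsonlite::write_json(cohort$spec[!vapply(cohort$spec, is.null, logical(1))],
                       p[["spec"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the contingency table, normalized by the square
#' root of the product of the two entropies (or by the larger entropy with
#' `variant = "max"`). 1 means identical partitions up to relabeling; 0
#' means independence. When either partition has zero entropy (a single
#' cluster), returns 1 if the two are identical as set-partitions and 0
#' otherwise — stated explicitly because library conventions disagree on
#' this degenerate case.
#'
#' @param a,b Partitions of the same samples (integer/character/factor
#'   vectors of equal length, no missing values).
#' @param variant Normalization: `"sqrt"` (default) or `"max"`.
#' @return NMI in \[0, 1\].
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, relabeled
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
nmi <- function(a, b, variant = c("sqrt", "max")) {
  variant <- match.arg(variant)
  if (length(a) != length(b)) stop("partition length mismatch", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("partitions must not contain missing values", call. = FALSE)
  fa <- as.integer(factor(a, levels = unique(a)))
  fb <- as.integer(factor(b, levels = unique(b)))
  tab <- table(fa, fb)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  if (ha == 0 || hb == 0) {
    return(as.numeric(identical(fa, fb)))
  }
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  denom <- if (variant == "sqrt") sqrt(ha * hb) else max(ha, hb)
  min(max(mi / denom, 0), 1)
}
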