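#' Permute one column of labels, keeping missing positions fixed
#'
#' The multiset of observed labels is uniformly randomly reassigned among the
#' originally observed positions; missing positions are untouched. This is
#' the elementary move of the permutation null behind the normalized
#' consensus weight. Uses the current R RNG stream (seed with [set.seed()]).
#'
#' @param labels Integer vector (one column of a label grid), `NA` = missing.
#' @return The permuted column.
#' @examples
#' set.seed(1)
#' permute_column(c(1L, NA, 2L, 1L))
#' @export
permute_column <- function(labels) {
  obs <- which(!is.na(labels))
  if (length(obs) > 1L) {
    labels[obs] <- labels[obs][sample.int(length(obs))]
  }
  labels
}

#' Normalized consensus weights by column-wise permutation
#'
#' For every co-observed sample pair, the observed consensus weight (CW) is
#' compared against its own permutation null: in each of
#' `nperm_blocks * block_size` elementary permutations every column of the
#' label grid is independently shuffled among its observed positions (missing
#' positions fixed) and the permuted CW is recomputed. The one-sided
#' empirical p-value is estimated with add-one smoothing,
#' `P = (n_exceed + 1) / (n_perm + 1)`, where `n_exceed` counts permutations
#' with permuted CW `>=` observed CW, and the normalized consensus weight is
#' `NCW = 1 - P`.
#'
#' The correction this buys: a pair co-observed only in runs that assign
#' everyone the same cluster has CW = 1, but every permutation also gives
#' CW = 1, so P = 1 and NCW = 0 — uninformative co-clustering (and, with the
#' pairwise-available-case CW, missingness itself) carries no weight. It also
#' separates pairs with identical CW but different evidence: the same CW
#' supported by many informative runs earns a higher NCW than one supported
#' by two.
#'
#' After every block of `block_size` permutations a cumulative NCW snapshot
#' is taken; the squared differences between consecutive snapshots form the
#' stability trace used to judge whether `nperm_blocks` was large enough
#' (see [stability_distances()] and [plot_stability()]).
#'
#' @param m A validated [label_matrix].
#' @param nperm_blocks Number of permutation blocks (total permutations =
#'   `nperm_blocks * block_size`). Default 10.
#' @param seed Integer master seed. Per-block child seeds are drawn up-front
#'   from this seed, so blocks are independently reproducible.
#' @param block_size Elementary permutations per block (default 1000, the
#'   stability-trace interval).
#' @param unobserved_policy What to do with pairs never co-observed:
#'   `"error"` (default; the message points to [filter_by_coverage()]) or
#'   `"zero"` (NCW set to 0 with a warning).
#' @return An `ncw_result` with elements `ncw` (symmetric matrix in \[0,1\],
#'   diagonal 1), `exceed_counts`, `total_perms`, `stability` (tibble from
#'   [stability_distances()]), `cw` (the observed [consensus_weights()]
#'   matrix), `seed`, `block_size`.
#' @export
compute_ncw <- function(m, nperm_blocks = 10, seed = 1, block_size = 1000,
                        unobserved_policy = c("error", "zero")) {
  stopifnot(inherits(m, "label_matrix"), nperm_blocks >= 1, block_size >= 1)
  unobserved_policy <- match.arg(unobserved_policy)
  counts <- cocluster_counts(m)
  cw <- consensus_weights(counts)
  n <- nrow(counts$observed)
  defined <- counts$observed > 0L
  diag(defined) <- TRUE
  if (!all(defined)) {
    idx <- which(!defined & upper.tri(defined), arr.ind = TRUE)
    pairs <- paste0(rownames(counts$observed)[idx[, 1]], "/",
                    colnames(counts$observed)[idx[, 2]])
    if (unobserved_policy == "error") {
      stop("pair(s) never co-observed: ", paste(head(pairs, 10), collapse = ", "),
           if (length(pairs) > 10) sprintf(" (+%d more)", length(pairs) - 10) else "",
           "; raise coverage with filter_by_coverage() or use ",
           "unobserved_policy = \"zero\"", call. = FALSE)
    }
    warning(length(pairs), " never-co-observed pair(s) set to NCW = 0", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  block_seeds <- sample.int(.Machine$integer.max, nperm_blocks)

  exceed <- matrix(0L, n, n, dimnames = dimnames(counts$observed))
  snapshots <- vector("list", nperm_blocks)
  for (b in seq_len(nperm_blocks)) {
    set.seed(block_seeds[b])
    eb <- perm_exceed_block(m$labels, counts$together, counts$observed, block_size)
    exceed <- exceed + eb + t(eb)
    snapshots[[b]] <- ncw_estimate(exceed, b * block_size, defined)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  total <- nperm_blocks * block_size
  ncw <- ncw_estimate(exceed, total, defined)
  if (unobserved_policy == "zero") ncw[!defined] <- 0

  structure(list(
    ncw = ncw,
    exceed_counts = exceed,
    total_perms = total,
    stability = if (nperm_blocks >= 2) stability_distances(snapshots) else NULL,
    cw = cw,
    seed = seed,
    block_seeds = block_seeds,
    block_size = block_size,
    unobserved_policy = unobserved_policy
  ), class = "ncw_result")
}

# cumulative NCW estimate: 1 - (exceed + 1) / (nperm + 1); diagonal 1,
# undefined pairs NA
ncw_estimate <- function(exceed, nperm, defined) {
  est <- 1 - (exceed + 1) / (nperm + 1)
  est[!defined] <- NA_real_
  diag(est) <- 1
  est
}

#' Stability trace from consecutive NCW snapshots
#'
#' Between consecutive cumulative NCW estimates, computes the per-pair
#' squared differences (over defined pairs of the upper triangle) and their
#' sum — the squared Euclidean distance between successive estimates. A
#' trace whose sums shrink toward 0 indicates the permutation count is
#' sufficient.
#'
#' @param snapshots List of >= 2 cumulative NCW matrices of identical shape
#'   (as taken every block by [compute_ncw()]).
#' @return A tibble with one row per consecutive pair: `block` (index of the
#'   later snapshot), `sum_distance`, quartiles (`q25`, `median`, `q75`) and
#'   extremes of the per-pair squared differences, and the per-pair
#'   differences themselves in the list-column `distances`.
#' @export
stability_distances <- function(snapshots) {
  stopifnot(is.list(snapshots), length(snapshots) >= 2)
  dims <- lapply(snapshots, dim)
  if (length(unique(dims)) != 1) stop("snapshots have mismatched shapes", call. = FALSE)
  purrr::map_dfr(seq(2, length(snapshots)), function(b) {
    a <- snapshots[[b - 1]]
    z <- snapshots[[b]]
    ut <- upper.tri(a) & !is.na(a) & !is.na(z)
    d2 <- (z[ut] - a[ut])^2
    tibble::tibble(
      block = b,
      sum_distance = sum(d2),
      min = min(d2), q25 = stats::quantile(d2, 0.25, names = FALSE),
      median = stats::median(d2),
      q75 = stats::quantile(d2, 0.75, names = FALSE), max = max(d2),
      distances = list(d2)
    )
  })
}

#' @export
print.ncw_result <- function(x, ...) {
  cat(sprintf("<ncw_result> %d samples; %d permutations (%d blocks x %d); seed %d\n",
              nrow(x$ncw), x$total_perms, x$total_perms / x$block_size,
              x$block_size, x$seed))
  if (!is.null(x$stability)) {
    cat(sprintf("  stability sum of squared changes, last block: %.3g\n",
                x$stability$sum_distance[nrow(x$stability)]))
  }
  invisible(x)
}

#' @export
tidy.ncw_result <- function(x, ...) {
  counts <- attr(x$cw, "counts")
  pair_table(x$ncw, value_name = "ncw") |>
    dplyr::mutate(
      cw = unclass(x$cw)[cbind(.data$i, .data$j)],
      observed = counts$observed[cbind(.data$i, .data$j)],
      exceed = x$exceed_counts[cbind(.data$i, .data$j)]
    ) |>
    dplyr::select("sample_a", "sample_b", "cw", "ncw", "observed", "exceed")
}

#' @export
glance.ncw_result <- function(x, ...) {
  ut <- upper.tri(x$ncw)
  tibble::tibble(
    n_samples = nrow(x$ncw),
    total_perms = x$total_perms,
    n_undefined_pairs = sum(is.na(x$ncw[ut])),
    mean_ncw = mean(x$ncw[ut], na.rm = TRUE),
    final_stability = if (is.null(x$stability)) NA_real_ else
      x$stability$sum_distance[nrow(x$stability)],
    seed = x$seed
  )
}

#' Write NCW outputs as TSV
#'
#' Writes `ncw.tsv` and `cw.tsv` (symmetric matrices with sample-id headers)
#' and `stability.tsv` (block, sum_distance, quartiles) into `dir`.
#'
#' @param x An `ncw_result`.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_ncw_outputs <- function(x, dir) {
  stopifnot(inherits(x, "ncw_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ncw = file.path(dir, "ncw.tsv"),
             cw = file.path(dir, "cw.tsv"),
             stability = file.path(dir, "stability.tsv"))
  write_pair_matrix(x$ncw, paths[["ncw"]])
  write_pair_matrix(x$cw, paths[["cw"]])
  if (!is.null(x$stability)) {
    readr::write_tsv(dplyr::select(x$stability, -"distances"), paths[["stability"]],
                     progress = FALSE)
  }
  invisible(paths)
}
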