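#' Consensus clustering of a normalized consensus weight matrix
#'
#' Resampling (Monti-style) consensus clustering of the NCW similarity over
#' `k = 2..maxK`. For each k, `reps` subsamples of `ceiling(p_item * n)`
#' samples (without replacement) are drawn; the inner algorithm clusters
#' each subsample; connectivity and co-sampling indicators are accumulated;
#' and the consensus matrix is their ratio. The per-k consensus tree is an
#' agglomerative clustering of `1 - consensus`, and the class assignment its
#' cut at k. CDF/delta-area model selection and item-/cluster-consensus
#' diagnostics are attached by [consensus_cdf_and_delta()] and
#' [item_and_cluster_consensus()], which this function calls.
#'
#' Inner algorithms: `"hierarchical"` clusters the distance `1 - NCW`
#' (linkage configurable, default average); `"spectral"` uses NCW directly
#' as an affinity (normalized-Laplacian embedding followed by seeded
#' k-means); `"kmedoids"` partitions `1 - NCW` around medoids
#' ([cluster::pam()]).
#'
#' @param ncw An `ncw_result` from [compute_ncw()], or a symmetric
#'   similarity matrix in \[0,1\] with unit diagonal and no `NA`.
#' @param maxK Maximum number of clusters (>= 2, <= n - 1). Default 6.
#' @param reps Resampling iterations per k. Default 100.
#' @param p_item Item-subsampling fraction in (0, 1]. Default 0.8.
#' @param inner_alg `"hierarchical"`, `"spectral"` or `"kmedoids"`.
#' @param linkage Agglomeration method for hierarchical steps: `"average"`
#'   (default), `"complete"` or `"ward"`.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param elbow_threshold Optional delta-area threshold; when supplied,
#'   `chosen_k` is the largest k whose delta-area exceeds it. By default
#'   `chosen_k` is the k >= 3 maximising delta-area (ties to the smaller k).
#' @return A `consensus_result`: per-k list `fcluster` (each with
#'   `consensus_matrix`, `consensus_tree`, `consensus_class`), tibbles
#'   `cluster_consensus` and `item_consensus`, tibbles `cdf` and `areas`
#'   (area under the consensus CDF and delta-area per k), `chosen_k`, and
#'   the configuration echo `config`.
#' @export
consensus_cluster_ncw <- function(ncw, maxK = 6, reps = 100, p_item = 0.8,
                                  inner_alg = c("hierarchical", "spectral", "kmedoids"),
                                  linkage = c("average", "complete", "ward"),
                                  seed = 1, elbow_threshold = NULL) {
  S <- if (inherits(ncw, "ncw_result")) ncw$ncw else as.matrix(ncw)
  inner_alg <- match.arg(inner_alg)
  linkage <- match.arg(linkage)
  hmethod <- if (linkage == "ward") "ward.D2" else linkage
  n <- nrow(S)
  if (any(is.na(S))) {
    stop("NCW matrix contains undefined pairs; filter runs by coverage or use ",
         "unobserved_policy = \"zero\"", call. = FALSE)
  }
  if (maxK < 2 || maxK > n - 1) stop("maxK must be in [2, n_samples - 1]", call. = FALSE)
  stopifnot(p_item > 0, p_item <= 1, reps >= 1)
  if (is.null(rownames(S))) rownames(S) <- colnames(S) <- paste0("s", seq_len(n))
  D <- 1 - S

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  n_sub <- ceiling(p_item * n)
  fcluster <- list()
  for (k in 2:maxK) {
    conn <- matrix(0, n, n)
    ind <- matrix(0, n, n)
    for (r in seq_len(reps)) {
      items <- sort(sample.int(n, n_sub))
      cl <- inner_cluster(S[items, items, drop = FALSE],
                          D[items, items, drop = FALSE],
                          k, inner_alg, hmethod)
      same <- outer(cl, cl, "==") * 1
      conn[items, items] <- conn[items, items] + same
      ind[items, items] <- ind[items, items] + 1
    }
    if (any(ind[upper.tri(ind)] == 0)) {
      warning(sprintf("k=%d: %d pair(s) never co-sampled; consensus set to 0",
                      k, sum(ind[upper.tri(ind)] == 0)), call. = FALSE)
    }
    cons <- ifelse(ind > 0, conn / ind, 0)
    diag(cons) <- 1
    dimnames(cons) <- dimnames(S)
    tree <- hclust(as.dist(1 - cons), method = hmethod)
    cls <- cutree(tree, k = k)
    fcluster[[as.character(k)]] <- list(
      consensus_matrix = cons,
      consensus_tree = tree,
      consensus_class = cls
    )
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  res <- structure(list(
    fcluster = fcluster,
    cdf = NULL, areas = NULL, chosen_k = NULL,
    cluster_consensus = NULL, item_consensus = NULL,
    config = list(maxK = maxK, reps = reps, p_item = p_item,
                  inner_alg = inner_alg, linkage = linkage, seed = seed,
                  elbow_threshold = elbow_threshold)
  ), class = "consensus_result")
  res <- consensus_cdf_and_delta(res)
  item_and_cluster_consensus(res)
}

# one clustering of a subsample; S = similarity, D = 1 - S
inner_cluster <- function(S, D, k, alg, hmethod) {
  switch(alg,
    hierarchical = cutree(hclust(as.dist(D), method = hmethod), k = k),
    kmedoids = cluster::pam(as.dist(D), k = k, cluster.only = TRUE),
    spectral = spectral_partition(S, k)
  )
}

# normalized-Laplacian spectral partition of an affinity matrix; falls back
# to hierarchical average linkage when the embedding has < k distinct rows
spectral_partition <- function(A, k) {
  diag(A) <- 0
  d <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(d)
  M <- A * tcrossprod(Dm)
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nr <- sqrt(rowSums(U^2))
  U <- U / pmax(nr, .Machine$double.eps)
  if (nrow(unique(round(U, 10))) < k) {
    return(cutree(hclust(as.dist(1 - A), method = "average"), k = k))
  }
  kmeans(U, centers = k, nstart = 10, iter.max = 50)$cluster
}

#' Consensus CDF, delta-area and k selection
#'
#' Computes the empirical CDF of upper-triangle consensus values per k, the
#' area under each CDF, and the relative increase in area from k-1 to k
#' (delta-area; for k = 2 the area itself). `chosen_k` is the k >= 3 with
#' maximal delta-area (ties broken toward the smaller k), or, when
#' `elbow_threshold` is set in the config, the largest k whose delta-area
#' exceeds the threshold.
#'
#' @param result A `consensus_result`.
#' @return The result with `cdf`, `areas` and `chosen_k` filled in.
#' @export
consensus_cdf_and_delta <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  grid <- seq(0, 1, by = 0.01)
  cdf <- purrr::map_dfr(names(result$fcluster), function(kk) {
    v <- result$fcluster[[kk]]$consensus_matrix
    v <- v[upper.tri(v)]
    Fn <- stats::ecdf(v)
    tibble::tibble(k = as.integer(kk), consensus = grid, cdf = Fn(grid))
  })
  areas <- cdf |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(area = sum(diff(.data$consensus) *
                                  (utils::head(.data$cdf, -1) + utils::tail(.data$cdf, -1)) / 2),
                     .groups = "drop") |>
    dplyr::arrange(.data$k) |>
    dplyr::mutate(delta_area = dplyr::if_else(
      .data$k == min(.data$k), .data$area,
      (.data$area - dplyr::lag(.data$area)) /
        pmax(dplyr::lag(.data$area), .Machine$double.eps)))

  thr <- result$config$elbow_threshold
  ks <- areas$k
  if (!is.null(thr)) {
    ok <- ks[areas$delta_area > thr]
    chosen <- if (length(ok)) max(ok) else min(ks)
  } else if (max(ks) >= 3) {
    cand <- areas[areas$k >= 3, ]
    chosen <- cand$k[which.max(cand$delta_area)]  # which.max ties to smaller k
  } else {
    chosen <- 2L
  }
  result$cdf <- cdf
  result$areas <- areas
  result$chosen_k <- as.integer(chosen)
  result
}

#' Item- and cluster-consensus diagnostics
#'
#' Cluster consensus of cluster c at level k is the mean consensus over
#' distinct pairs within c (0 for singletons, by convention). Item consensus
#' of sample i toward cluster c is the mean consensus between i and the
#' members of c (excluding i itself when i is in c).
#'
#' @param result A `consensus_result`.
#' @return The result with long tibbles `cluster_consensus`
#'   (k, cluster, cluster_consensus) and `item_consensus`
#'   (k, cluster, sample_id, item_consensus) filled in.
#' @export
item_and_cluster_consensus <- function(result) {
  stopifnot(inherits(result, "consensus_result"))
  per_k <- purrr::map(names(result$fcluster), function(kk) {
    f <- result$fcluster[[kk]]
    M <- f$consensus_matrix
    cl <- f$consensus_class
    ids <- rownames(M)
    k <- as.integer(kk)
    cc <- purrr::map_dfr(sort(unique(cl)), function(c) {
      members <- which(cl == c)
      val <- if (length(members) < 2) 0 else {
        sub <- M[members, members, drop = FALSE]
        mean(sub[upper.tri(sub)])
      }
      tibble::tibble(k = k, cluster = c, cluster_consensus = val)
    })
    ic <- purrr::map_dfr(sort(unique(cl)), function(c) {
      members <- which(cl == c)
      vals <- vapply(seq_along(ids), function(i) {
        others <- setdiff(members, i)
        if (!length(others)) 0 else mean(M[i, others])
      }, numeric(1))
      tibble::tibble(k = k, cluster = c, sample_id = ids,
                     item_consensus = vals, in_cluster = cl == c)
    })
    list(cc = cc, ic = ic)
  })
  result$cluster_consensus <- purrr::map_dfr(per_k, "cc")
  result$item_consensus <- purrr::map_dfr(per_k, "ic")
  result
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = 2..%d; inner = %s; reps = %d; p_item = %.2f\n",
              x$config$maxK, x$config$inner_alg, x$config$reps, x$config$p_item))
  cat(sprintf("  chosen_k = %d\n", x$chosen_k))
  print(x$areas)
  invisible(x)
}

#' @param x A `consensus_result`.
#' @param k Which level's class assignments to return; default all levels.
#' @describeIn consensus_cluster_ncw Tidy per-sample class assignments: a
#'   tibble with `k`, `sample_id`, `class` and the item consensus toward the
#'   sample's own cluster.
#' @export
tidy.consensus_result <- function(x, k = NULL, ...) {
  ks <- if (is.null(k)) as.integer(names(x$fcluster)) else as.integer(k)
  own <- dplyr::filter(x$item_consensus, .data$in_cluster)
  purrr::map_dfr(ks, function(kk) {
    cl <- x$fcluster[[as.character(kk)]]$consensus_class
    tibble::tibble(k = kk, sample_id = names(cl), class = unname(cl))
  }) |>
    dplyr::left_join(
      dplyr::select(own, "k", "sample_id", "item_consensus"),
      by = c("k", "sample_id")
    )
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble::tibble(
    chosen_k = x$chosen_k,
    maxK = x$config$maxK,
    reps = x$config$reps,
    p_item = x$config$p_item,
    inner_alg = x$config$inner_alg,
    mean_cluster_consensus_chosen = mean(
      x$cluster_consensus$cluster_consensus[x$cluster_consensus$k == x$chosen_k])
  )
}

#' Extract class assignments at one k
#'
#' @param result A `consensus_result`.
#' @param k Number of clusters; defaults to `chosen_k`.
#' @return Named integer vector of class assignments.
#' @export
consensus_classes <- function(result, k = result$chosen_k) {
  stopifnot(inherits(result, "consensus_result"))
  kk <- as.character(k)
  if (!kk %in% names(result$fcluster)) stop("no solution at k = ", k, call. = FALSE)
  result$fcluster[[kk]]$consensus_class
}

#' Write consensus outputs to a directory
#'
#' Writes per-k `consensus_matrix.k{K}.tsv` and `consensus_class.k{K}.tsv`,
#' the long-format `itemConsensus.tsv` and `clusterConsensus.tsv`, and
#' `summary.json` (chosen k, per-k areas and delta-areas, configuration
#' echo, seed).
#'
#' @param result A `consensus_result`.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_consensus_outputs <- function(result, dir) {
  stopifnot(inherits(result, "consensus_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (kk in names(result$fcluster)) {
    f <- result$fcluster[[kk]]
    p1 <- file.path(dir, sprintf("consensus_matrix.k%s.tsv", kk))
    write_pair_matrix(f$consensus_matrix, p1)
    p2 <- file.path(dir, sprintf("consensus_class.k%s.tsv", kk))
    readr::write_tsv(tibble::tibble(sample_id = names(f$consensus_class),
                                    class = unname(f$consensus_class)),
                     p2, progress = FALSE)
    paths <- c(paths, p1, p2)
  }
  pic <- file.path(dir, "itemConsensus.tsv")
  readr::write_tsv(result$item_consensus, pic, progress = FALSE)
  pcc <- file.path(dir, "clusterConsensus.tsv")
  readr::write_tsv(result$cluster_consensus, pcc, progress = FALSE)
  psum <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    chosen_k = result$chosen_k,
    areas = result$areas,
    config = result$config[!vapply(result$config, is.null, logical(1))]
  ), psum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, pic, pcc, psum))
}
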