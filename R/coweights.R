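#' Pairwise co-clustering counts under missing labels
#'
#' For every pair of samples, counts (i) the runs in which both samples are
#' observed (`observed`) and (ii) the runs in which both are observed *and*
#' assigned the same cluster (`together`). These two integer matrices are the
#' sufficient statistics for the consensus weight: the denominator is
#' restricted to co-observed runs (pairwise-available-case), because dividing
#' by the total number of runs would let missingness itself masquerade as
#' dissimilarity.
#'
#' Internally the counts are accumulated by one block-indicator crossproduct
#' per matrix (no pair/run triple loop), so cost is one dense matrix multiply.
#'
#' @param m A validated [label_matrix].
#' @return A `cocluster_counts` object: list with symmetric integer matrices
#'   `together` and `observed` (dimnames = sample ids). Diagonals count the
#'   runs in which each single sample is observed.
#' @examples
#' m <- label_matrix(data.frame(id = c("a", "b", "c"),
#'                              r1 = c(1L, 1L, 2L), r2 = c(1L, 1L, NA)))
#' cocluster_counts(m)$together
#' @export
cocluster_counts <- function(m) {
  stopifnot(inherits(m, "label_matrix"))
  grid <- m$labels
  n <- nrow(grid)
  obs_ind <- matrix(as.numeric(!is.na(grid)), n, ncol(grid))
  observed <- obs_ind %*% t(obs_ind)
  # together: one indicator column per (run, label) group
  cols <- lapply(seq_len(ncol(grid)), function(j) {
    v <- grid[, j]
    labs <- unique(v[!is.na(v)])
    vapply(labs, function(l) as.numeric(!is.na(v) & v == l), numeric(n))
  })
  B <- do.call(cbind, cols)
  together <- B %*% t(B)
  storage.mode(together) <- "integer"
  storage.mode(observed) <- "integer"
  dimnames(together) <- dimnames(observed) <- list(rownames(grid), rownames(grid))
  structure(list(together = together, observed = observed),
            class = "cocluster_counts")
}

#' @export
print.cocluster_counts <- function(x, ...) {
  cat(sprintf("<cocluster_counts> %d samples; undefined pairs: %d\n",
              nrow(x$observed),
              sum(x$observed[upper.tri(x$observed)] == 0L)))
  invisible(x)
}

#' Consensus weight (CW) matrix
#'
#' The consensus weight of a sample pair is the fraction of co-observed runs
#' in which the pair shares a cluster, in \[0, 1\]. Pairs never co-observed
#' have no defined weight and are carried as `NA` (never silently imputed;
#' see `unobserved_policy` in [compute_ncw()]). The diagonal is 1.
#'
#' @param counts A `cocluster_counts` object from [cocluster_counts()], or a
#'   [label_matrix] (counts are computed first).
#' @return A `cw_matrix`: symmetric numeric matrix with unit diagonal and
#'   `NA` for never-co-observed pairs, with the `cocluster_counts` attached
#'   as attribute `"counts"`.
#' @export
consensus_weights <- function(counts) {
  if (inherits(counts, "label_matrix")) counts <- cocluster_counts(counts)
  stopifnot(inherits(counts, "cocluster_counts"))
  vals <- ifelse(counts$observed > 0L, counts$together / counts$observed, NA_real_)
  diag(vals) <- 1
  dimnames(vals) <- dimnames(counts$observed)
  structure(vals, class = c("cw_matrix", "matrix"), counts = counts)
}

#' @export
print.cw_matrix <- function(x, ...) {
  ut <- x[upper.tri(x)]
  cat(sprintf("<cw_matrix> %d samples; CW range %.3f-%.3f; undefined pairs: %d\n",
              nrow(x), min(ut, na.rm = TRUE), max(ut, na.rm = TRUE), sum(is.na(ut))))
  invisible(x)
}

#' @export
tidy.cw_matrix <- function(x, ...) {
  counts <- attr(x, "counts")
  pair_table(unclass(x), value_name = "cw") |>
    dplyr::mutate(
      together = counts$together[cbind(.data$i, .data$j)],
      observed = counts$observed[cbind(.data$i, .data$j)]
    ) |>
    dplyr::select(-"i", -"j")
}

# upper-triangle long view of a symmetric sample x sample matrix
pair_table <- function(mat, value_name = "value") {
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  ids <- rownames(mat)
  out <- tibble::tibble(
    sample_a = ids[idx[, 1]],
    sample_b = ids[idx[, 2]],
    i = idx[, 1], j = idx[, 2]
  )
  out[[value_name]] <- mat[idx]
  out
}

#' Write a symmetric sample-by-sample matrix as TSV
#'
#' Sample ids appear as both header and first column; undefined entries are
#' written as `"NA"`.
#'
#' @param mat A symmetric matrix with sample-id dimnames (e.g. a `cw_matrix`
#'   or the `ncw` component of an [compute_ncw()] result).
#' @param path Output path.
#' @export
write_pair_matrix <- function(mat, path) {
  df <- tibble::as_tibble(unclass(mat))
  df <- tibble::add_column(df, sample_id = rownames(mat), .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}
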