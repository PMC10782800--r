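#' Compare original and normalized consensus weights
#'
#' Scatter of NCW (vertical) against the original CW (horizontal), one point
#' per sample pair, colored by the number of runs in which the pair was
#' co-observed. Pairs whose CW is inflated by few, uninformative runs fall
#' below the diagonal; well-supported pairs track it.
#'
#' @param ncw An `ncw_result` from [compute_ncw()].
#' @return A ggplot object. Plotting never alters numeric results.
#' @export
plot_compare_cw <- function(ncw) {
  stopifnot(inherits(ncw, "ncw_result"))
  df <- tidy(ncw)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cw, y = .data$ncw,
                                   colour = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 1.2) +
    ggplot2::scale_colour_gradient(low = "#d73027", high = "#1a9850",
                                   name = "runs co-observed") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "consensus weight (CW)",
                  y = "normalized consensus weight (NCW)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ncw_result <- function(object, ...) plot_compare_cw(object)

#' Stability of the permutation count
#'
#' Per permutation block, a box summary of the per-pair squared changes of
#' the cumulative NCW estimate, with a line tracing their sum (the squared
#' Euclidean distance between consecutive estimates). A trace collapsing
#' toward zero indicates enough permutations.
#'
#' @param trace A stability tibble from [stability_distances()], or an
#'   `ncw_result` (its trace is used).
#' @return A ggplot object.
#' @export
plot_stability <- function(trace) {
  if (inherits(trace, "ncw_result")) trace <- trace$stability
  if (is.null(trace)) stop("no stability trace (need >= 2 blocks)", call. = FALSE)
  long <- tidyr::unnest(dplyr::select(trace, "block", "distances"),
                        cols = "distances")
  ggplot2::ggplot() +
    ggplot2::geom_boxplot(data = long,
                          ggplot2::aes(x = factor(.data$block), y = .data$distances),
                          outlier.size = 0.4, fill = "grey85") +
    ggplot2::geom_line(data = trace,
                       ggplot2::aes(x = factor(.data$block), y = .data$sum_distance,
                                    group = 1), colour = "#d73027") +
    ggplot2::geom_point(data = trace,
                        ggplot2::aes(x = factor(.data$block), y = .data$sum_distance),
                        colour = "#d73027") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "permutation block",
                  y = "squared change in NCW (per pair; line = sum)") +
    ggplot2::theme_minimal()
}

#' Consensus clustering diagnostics
#'
#' Produces the customary companion plots of the resampling consensus step:
#' a consensus-matrix heatmap per k (samples ordered by the consensus
#' dendrogram), the consensus CDF per k, and the delta-area elbow curve.
#'
#' @param result A `consensus_result`.
#' @param k Which k to draw the heatmap for; default `chosen_k`.
#' @return A named list of ggplot objects: `heatmap`, `cdf`, `delta_area`.
#' @export
plot_consensus <- function(result, k = result$chosen_k) {
  stopifnot(inherits(result, "consensus_result"))
  f <- result$fcluster[[as.character(k)]]
  ord <- f$consensus_tree$order
  M <- f$consensus_matrix[ord, ord]
  ids <- factor(rownames(M), levels = rownames(M))
  hm_df <- tibble::tibble(
    a = rep(ids, times = ncol(M)),
    b = rep(ids, each = nrow(M)),
    consensus = as.vector(M)
  )
  heatmap <- ggplot2::ggplot(hm_df, ggplot2::aes(.data$a, .data$b,
                                                 fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("consensus matrix, k = %d", k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())

  cdf <- ggplot2::ggplot(result$cdf,
                         ggplot2::aes(.data$consensus, .data$cdf,
                                      colour = factor(.data$k))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "consensus value", y = "CDF", colour = "k") +
    ggplot2::theme_minimal()

  delta <- ggplot2::ggplot(result$areas,
                           ggplot2::aes(.data$k, .data$delta_area)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "k", y = "relative change in area under CDF") +
    ggplot2::theme_minimal()

  list(heatmap = heatmap, cdf = cdf, delta_area = delta)
}

#' @export
autoplot.consensus_result <- function(object, k = object$chosen_k, ...) {
  plot_consensus(object, k = k)$heatmap
}
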