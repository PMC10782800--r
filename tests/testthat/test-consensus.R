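block_similarity <- function(sizes) {
  part <- rep(seq_along(sizes), sizes)
  S <- outer(part, part, "==") * 1
  dimnames(S) <- list(paste0("s", seq_along(part)), paste0("s", seq_along(part)))
  S
}

test_that("perfect block structure is a fixed point of consensus clustering", {
  S <- block_similarity(c(3, 3))
  res <- consensus_cluster_ncw(S, maxK = 3, reps = 1, p_item = 1, seed = 1)
  f <- res$fcluster[["2"]]
  expect_equal(f$consensus_matrix, S)
  cl <- f$consensus_class
  expect_equal(nmi(cl, rep(1:2, each = 3)), 1)
})

test_that("no subsampling + deterministic inner algorithm gives binary consensus matrices", {
  set.seed(5)
  noise <- matrix(stats::runif(64, 0, 0.05), 8, 8)
  S <- block_similarity(c(4, 4)) * 0.9 + (noise + t(noise)) / 2
  diag(S) <- 1
  for (alg in c("hierarchical", "kmedoids")) {
    res <- consensus_cluster_ncw(S, maxK = 4, reps = 5, p_item = 1,
                                 inner_alg = alg, seed = 2)
    for (k in 2:4) {
      M <- res$fcluster[[as.character(k)]]$consensus_matrix
      expect_true(all(M %in% c(0, 1)), label = paste(alg, "k =", k))
    }
  }
})

test_that("consensus matrices are symmetric with unit diagonal and k non-empty classes", {
  coh <- generate_cohort(n_samples = 24, k_true = 3, n_runs = 12,
                         coverage_range = c(0.6, 1), noise_rate = 0.15, seed = 8)
  ncw <- compute_ncw(coh$matrix, nperm_blocks = 3, seed = 8)
  res <- consensus_cluster_ncw(ncw, maxK = 5, reps = 30, seed = 8)
  for (k in 2:5) {
    f <- res$fcluster[[as.character(k)]]
    M <- f$consensus_matrix
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, 24))
    expect_true(all(M >= 0 & M <= 1))
    expect_length(unique(f$consensus_class), k)
  }
})

test_that("all three inner algorithms recover a clean 3-cluster cohort", {
  coh <- generate_cohort(n_samples = 30, k_true = 3, n_runs = 15,
                         coverage_range = c(0.7, 1), noise_rate = 0.05, seed = 12)
  ncw <- compute_ncw(coh$matrix, nperm_blocks = 3, seed = 12)
  for (alg in c("hierarchical", "spectral", "kmedoids")) {
    res <- consensus_cluster_ncw(ncw, maxK = 5, reps = 20, inner_alg = alg, seed = 12)
    expect_equal(nmi(consensus_classes(res, 3), coh$truth), 1,
                 label = paste("NMI with", alg))
  }
})

test_that("CDF is monotone, areas non-decreasing, delta-area elbow finds k", {
  coh <- generate_cohort(n_samples = 30, k_true = 3, n_runs = 15,
                         coverage_range = c(0.6, 1), noise_rate = 0.1, seed = 3)
  ncw <- compute_ncw(coh$matrix, nperm_blocks = 3, seed = 3)
  res <- consensus_cluster_ncw(ncw, maxK = 6, reps = 50, seed = 3)
  expect_equal(res$chosen_k, 3L)
  for (k in 2:6) {
    cdf_k <- res$cdf$cdf[res$cdf$k == k]
    expect_true(all(diff(cdf_k) >= 0))
    expect_equal(cdf_k[length(cdf_k)], 1)
  }
  expect_true(all(diff(res$areas$area) >= -1e-12))
})

test_that("an all-ones consensus matrix has near-zero area under its CDF", {
  res <- structure(list(
    fcluster = list(`2` = list(consensus_matrix = matrix(1, 5, 5))),
    config = list(elbow_threshold = NULL)
  ), class = "consensus_result")
  res <- consensus_cdf_and_delta(res)
  expect_lt(res$areas$area[1], 0.02)
})

test_that("item- and cluster-consensus match a double-loop oracle", {
  set.seed(9)
  raw <- matrix(stats::runif(36), 6, 6)
  M <- (raw + t(raw)) / 2
  diag(M) <- 1
  dimnames(M) <- list(paste0("s", 1:6), paste0("s", 1:6))
  cl <- c(1L, 1L, 1L, 2L, 2L, 2L)
  res <- structure(list(
    fcluster = list(`2` = list(consensus_matrix = M, consensus_class =
                                 setNames(cl, rownames(M)))),
    config = list()
  ), class = "consensus_result")
  res <- item_and_cluster_consensus(res)
  orc <- oracle_icl(M, cl)
  expect_equal(res$cluster_consensus$cluster_consensus, unname(orc$cluster))
  for (c in 1:2) {
    got <- res$item_consensus[res$item_consensus$cluster == c, ]
    expect_equal(got$item_consensus, unname(orc$item[, c]))
  }
})

test_that("perfect blocks give unit within-cluster and zero cross-cluster consensus; singletons get 0", {
  S <- block_similarity(c(3, 3))
  res <- consensus_cluster_ncw(S, maxK = 2, reps = 1, p_item = 1, seed = 1)
  cc <- res$cluster_consensus[res$cluster_consensus$k == 2, ]
  expect_equal(cc$cluster_consensus, c(1, 1))
  ic <- res$item_consensus[res$item_consensus$k == 2, ]
  expect_equal(ic$item_consensus[ic$in_cluster], rep(1, 6))
  expect_equal(ic$item_consensus[!ic$in_cluster], rep(0, 6))

  M <- block_similarity(c(4, 1))
  cl <- setNames(c(1L, 1L, 1L, 1L, 2L), rownames(M))
  r2 <- structure(list(fcluster = list(`2` = list(consensus_matrix = M,
                                                  consensus_class = cl)),
                       config = list()), class = "consensus_result")
  r2 <- item_and_cluster_consensus(r2)
  expect_equal(r2$cluster_consensus$cluster_consensus[2], 0)
})

test_that("configuration is validated and runs are seed-deterministic", {
  S <- block_similarity(c(3, 3))
  expect_error(consensus_cluster_ncw(S, maxK = 6), "maxK")
  S_na <- S; S_na[1, 2] <- NA
  expect_error(consensus_cluster_ncw(S_na, maxK = 2), "undefined")

  coh <- generate_cohort(n_samples = 20, k_true = 2, n_runs = 8,
                         coverage_range = c(0.6, 1), noise_rate = 0.2, seed = 4)
  ncw <- compute_ncw(coh$matrix, nperm_blocks = 2, seed = 4)
  a <- consensus_cluster_ncw(ncw, maxK = 4, reps = 25, seed = 7)
  b <- consensus_cluster_ncw(ncw, maxK = 4, reps = 25, seed = 7)
  expect_identical(a$fcluster[["3"]]$consensus_matrix, b$fcluster[["3"]]$consensus_matrix)
  expect_identical(a$chosen_k, b$chosen_k)
})

test_that("tidy and glance summarise a consensus result", {
  S <- block_similarity(c(3, 3))
  res <- consensus_cluster_ncw(S, maxK = 3, reps = 2, p_item = 1, seed = 1)
  td <- tidy(res, k = 2)
  expect_named(td, c("k", "sample_id", "class", "item_consensus"))
  expect_equal(nrow(td), 6)
  gl <- glance(res)
  expect_equal(gl$maxK, 3)
  expect_true(gl$chosen_k %in% 2:3)
})
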