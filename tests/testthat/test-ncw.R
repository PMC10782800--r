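test_that("permute_column fixes missing positions and preserves the label multiset", {
  col <- c(1L, NA, 2L, 1L)
  arr <- column_arrangements(col)
  expect_length(arr, 3)  # 3!/2! arrangements of {1,1,2}
  set.seed(11)
  seen <- character()
  for (i in 1:200) {
    p <- permute_column(col)
    expect_true(is.na(p[2]))
    expect_identical(sort(p[!is.na(p)]), sort(col[!is.na(col)]))
    seen <- union(seen, paste(p, collapse = ","))
  }
  expect_setequal(seen, vapply(arr, paste, character(1), collapse = ","))

  constant <- c(3L, 3L, NA, 3L)
  expect_identical(permute_column(constant), constant)
})

test_that("permute_column draws arrangements uniformly", {
  col <- c(1L, NA, 2L, 1L)
  set.seed(99)
  draws <- replicate(30000, paste(permute_column(col), collapse = ","))
  counts <- table(draws)
  expect_length(counts, 3)
  # binomial 3-sigma band around 10000 per arrangement
  expect_true(all(abs(counts - 10000) <= 3 * sqrt(30000 * (1 / 3) * (2 / 3))))
})

test_that("pairs co-observed only in constant-label runs get NCW exactly 0", {
  # pair (s1, s2) co-observed only in the all-same-label column: its CW of 1
  # is fully explained by uninformativeness, so it must carry no weight
  grid <- matrix(c(1L, 1L, 1L, 1L,
                   1L, NA, 1L, 2L,
                   NA, 1L, 2L, 1L), 4, 3,
                 dimnames = list(paste0("s", 1:4), paste0("r", 1:3)))
  res <- compute_ncw(label_matrix(grid), nperm_blocks = 2, seed = 5)
  expect_equal(unclass(res$cw)["s1", "s2"], 1)
  expect_identical(res$ncw["s1", "s2"], 0)
  expect_equal(res$exceed_counts["s1", "s2"], res$total_perms)
})

test_that("Monte-Carlo exceedance matches exhaustive enumeration within 3 sigma", {
  grid <- matrix(rep(c(1L, 1L, 2L, 2L), 3), 4, 3,
                 dimnames = list(paste0("s", 1:4), paste0("r", 1:3)))
  exact <- oracle_exact_exceed(grid)
  expect_equal(exact$n_arrangements, 216)  # 6^3 column arrangements
  res <- compute_ncw(label_matrix(grid), nperm_blocks = 20, seed = 3)
  expect_equal(unclass(res$cw)[1, 2], 1)
  total <- res$total_perms
  mc_p <- res$exceed_counts / total
  ut <- which(upper.tri(grid %*% t(grid)))
  for (idx in ut) {
    p <- exact$p[idx]
    expect_lt(abs(mc_p[idx] - p), 3 * sqrt(p * (1 - p) / total) + 1e-12)
  }
})

test_that("equal CW backed by more informative runs earns higher NCW", {
  # p1/p2 share CW = 1 over 2 informative runs; q1/q2 over 10
  n <- 5
  ids <- c("p1", "p2", "q1", "q2", "f")
  grid <- matrix(NA_integer_, n, 12, dimnames = list(ids, paste0("r", 1:12)))
  grid[c("p1", "p2", "f"), 1:2] <- c(1L, 1L, 2L)
  grid[c("q1", "q2", "f"), 3:12] <- c(1L, 1L, 2L)
  res <- compute_ncw(label_matrix(grid), nperm_blocks = 5, seed = 2,
                     unobserved_policy = "zero") |> suppressWarnings()
  expect_equal(unclass(res$cw)["p1", "p2"], 1)
  expect_equal(unclass(res$cw)["q1", "q2"], 1)
  expect_gte(res$ncw["q1", "q2"], res$ncw["p1", "p2"])
  expect_gt(res$ncw["q1", "q2"], 0.9)
})

test_that("identical matrix and seed reproduce exceed counts bit-identically", {
  set.seed(21)
  grid <- random_label_grid(n = 10, n_runs = 6, k = 3, miss = 0.3)
  m <- label_matrix(grid)
  r1 <- compute_ncw(m, nperm_blocks = 3, seed = 17)
  r2 <- compute_ncw(m, nperm_blocks = 3, seed = 17)
  expect_identical(r1$exceed_counts, r2$exceed_counts)
  expect_identical(r1$ncw, r2$ncw)
  r3 <- compute_ncw(m, nperm_blocks = 3, seed = 18)
  expect_false(identical(r1$exceed_counts, r3$exceed_counts))
})

test_that("NCW is statistically invariant to label renaming and row reordering", {
  set.seed(31)
  repeat {  # need every pair co-observed at least once
    grid <- random_label_grid(n = 8, n_runs = 6, k = 3, miss = 0.2)
    if (all(oracle_counts(grid)$observed > 0)) break
  }
  base <- compute_ncw(label_matrix(grid), nperm_blocks = 10, seed = 4)

  relab <- grid
  for (j in seq_len(ncol(grid))) {
    newname <- sample(9)
    obs <- !is.na(grid[, j])
    relab[obs, j] <- newname[grid[obs, j]]
  }
  r2 <- compute_ncw(label_matrix(relab), nperm_blocks = 10, seed = 4)
  expect_equal(unclass(r2$cw), unclass(base$cw))  # CW exactly invariant
  expect_lt(max(abs(r2$ncw - base$ncw), na.rm = TRUE), 0.03)

  ord <- sample(nrow(grid))
  r3 <- compute_ncw(label_matrix(grid[ord, ]), nperm_blocks = 10, seed = 4)
  expect_lt(max(abs(r3$ncw[rownames(grid), rownames(grid)] - base$ncw),
                na.rm = TRUE), 0.03)
})

test_that("unobserved pairs follow the declared policy", {
  grid <- matrix(c(1L, 1L, NA, NA, NA, NA, 1L, 2L), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("a", "b")))
  m <- label_matrix(grid)
  expect_error(compute_ncw(m, nperm_blocks = 1, seed = 1),
               "never co-observed.*filter_by_coverage")
  expect_warning(res <- compute_ncw(m, nperm_blocks = 1, seed = 1,
                                    unobserved_policy = "zero"),
                 "never-co-observed")
  expect_equal(res$ncw["s1", "s3"], 0)
})

test_that("stability distances follow the squared-difference definition", {
  snap <- function(v) matrix(c(1, v, v, 1), 2, 2)
  tr <- stability_distances(list(snap(0.5), snap(0.5)))
  expect_equal(tr$sum_distance, 0)
  tr2 <- stability_distances(list(snap(0.5), snap(0.7)))
  expect_equal(tr2$sum_distance, 0.04)
  expect_equal(tr2$distances[[1]], 0.04)
  expect_error(stability_distances(list(snap(0.5), matrix(1, 3, 3))), "mismatched")
  expect_error(stability_distances(list(snap(0.5))), "length")
})

test_that("cumulative NCW stabilises: last block moves less than block 2", {
  for (s in 1:5) {
    coh <- generate_cohort(n_samples = 12, k_true = 3, n_runs = 8,
                           coverage_range = c(0.5, 1), noise_rate = 0.2, seed = s)
    res <- suppressWarnings(compute_ncw(coh$matrix, nperm_blocks = 10, seed = s,
                                        unobserved_policy = "zero"))
    tr <- res$stability
    expect_lte(tr$sum_distance[nrow(tr)], tr$sum_distance[1])
  }
})
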