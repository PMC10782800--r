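# Independent oracles used across tests. Deliberately naive: triple loops and
# full enumeration, never calling the code paths they check.

# pair/run triple-loop co-clustering counts
oracle_counts <- function(grid) {
  n <- nrow(grid)
  tog <- obs <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (r in seq_len(ncol(grid))) {
        if (!is.na(grid[i, r]) && !is.na(grid[j, r])) {
          obs[i, j] <- obs[i, j] + 1L
          if (grid[i, r] == grid[j, r]) tog[i, j] <- tog[i, j] + 1L
        }
      }
    }
  }
  list(together = tog, observed = obs)
}

oracle_cw <- function(grid) {
  cnt <- oracle_counts(grid)
  cw <- ifelse(cnt$observed > 0, cnt$together / cnt$observed, NA_real_)
  diag(cw) <- 1
  cw
}

# all distinct arrangements of a column's observed labels over its observed
# positions (missing positions fixed)
column_arrangements <- function(col) {
  obs <- which(!is.na(col))
  vals <- col[obs]
  perm_idx <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perm_idx(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  perms <- perm_idx(vals)
  keys <- vapply(perms, paste, character(1), collapse = ",")
  perms <- perms[!duplicated(keys)]
  lapply(perms, function(p) {
    out <- col
    out[obs] <- p
    out
  })
}

# exact exceedance probability P(permuted together >= observed together) per
# pair, by full enumeration of the cartesian product of column arrangements
oracle_exact_exceed <- function(grid) {
  arr <- lapply(seq_len(ncol(grid)), function(j) column_arrangements(grid[, j]))
  sizes <- vapply(arr, length, integer(1))
  stopifnot(prod(sizes) <= 1e4)
  obs_cnt <- oracle_counts(grid)
  n <- nrow(grid)
  exceed <- matrix(0, n, n)
  combos <- expand.grid(lapply(sizes, seq_len))
  for (row in seq_len(nrow(combos))) {
    g <- grid
    for (j in seq_len(ncol(grid))) g[, j] <- arr[[j]][[combos[row, j]]]
    tog <- oracle_counts(g)$together
    exceed <- exceed + (tog >= obs_cnt$together & obs_cnt$observed > 0)
  }
  list(p = exceed / nrow(combos), n_arrangements = nrow(combos),
       observed = obs_cnt$observed)
}

# random valid label matrix: every column keeps >= 2 observed entries
random_label_grid <- function(n = 8, n_runs = 5, k = 3, miss = 0.3) {
  grid <- matrix(NA_integer_, n, n_runs,
                 dimnames = list(paste0("s", seq_len(n)), paste0("r", seq_len(n_runs))))
  for (j in seq_len(n_runs)) {
    repeat {
      col <- sample.int(k, n, replace = TRUE)
      col[runif(n) < miss] <- NA_integer_
      if (sum(!is.na(col)) >= 2) break
    }
    grid[, j] <- col
  }
  grid
}

# brute-force item/cluster consensus by explicit double loops
oracle_icl <- function(M, cl) {
  ids <- rownames(M)
  cc <- sapply(sort(unique(cl)), function(c) {
    members <- which(cl == c)
    if (length(members) < 2) return(0)
    tot <- 0; np <- 0
    for (a in members) for (b in members) if (a < b) { tot <- tot + M[a, b]; np <- np + 1 }
    tot / np
  })
  ic <- matrix(0, length(ids), length(unique(cl)))
  for (i in seq_along(ids)) {
    for (c in sort(unique(cl))) {
      members <- setdiff(which(cl == c), i)
      ic[i, c] <- if (length(members)) mean(M[i, members]) else 0
    }
  }
  list(cluster = cc, item = ic)
}

# bare numeric values of a cw_matrix (drop class/dimnames/attached counts)
cw_values <- function(cw) {
  v <- unclass(cw)
  attributes(v) <- list(dim = dim(v))
  v
}

toy_label_df <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             r1 = c(1L, 1L, 2L), r2 = c(1L, 1L, NA))
}
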