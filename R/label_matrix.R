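#' Label matrices: samples x clustering runs with missing entries
#'
#' A `label_matrix` holds integer cluster labels for `n_samples` samples
#' (rows) across `n_runs` clustering runs (columns). A cell is `NA` when the
#' sample was not covered by that run — e.g. because the omics combination
#' behind the run lacks data for the sample. Labels are only meaningful
#' *within* a column: column j saying "2" and column k saying "2" does not
#' relate the two runs, so labels are never recoded across columns.
#'
#' Optional per-run metadata (`run_meta`) records how many omics platforms
#' each run integrates (`n_omics`); per-run sample coverage is always
#' recomputed from the grid, never trusted from metadata.
#'
#' @param labels An integer matrix (rows = samples, columns = runs, `NA` for
#'   missing), with row and column names; or a data frame whose first column
#'   holds sample identifiers and remaining columns hold run labels.
#' @param run_meta Optional data frame with columns `run_id` and `n_omics`
#'   (positive integer: number of omics platforms integrated in that run).
#'
#' @return A `label_matrix` object.
#'
#' @details Validation enforces: unique sample and run identifiers; every
#'   non-missing label a positive integer; every column observed for at least
#'   two samples (a column observed for fewer carries no pairwise
#'   co-clustering information and is rejected, with the offending column
#'   named in the error).
#'
#' @examples
#' df <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                  r1 = c(1L, 1L, 2L), r2 = c(1L, 1L, NA))
#' m <- label_matrix(df)
#' coverage(m)
#' @export
label_matrix <- function(labels, run_meta = NULL) {
  if (is.data.frame(labels)) {
    ids <- as.character(labels[[1]])
    grid <- as.matrix(labels[, -1, drop = FALSE])
    storage.mode(grid) <- "integer"
    rownames(grid) <- ids
  } else {
    grid <- labels
    if (!is.matrix(grid)) stop("`labels` must be a matrix or data frame", call. = FALSE)
    storage.mode(grid) <- "integer"
  }
  if (is.null(rownames(grid))) rownames(grid) <- paste0("s", seq_len(nrow(grid)))
  if (is.null(colnames(grid))) colnames(grid) <- paste0("run", seq_len(ncol(grid)))
  if (!is.null(run_meta)) {
    run_meta <- tibble::as_tibble(run_meta)
    if (!all(c("run_id", "n_omics") %in% names(run_meta))) {
      stop("`run_meta` needs columns `run_id` and `n_omics`", call. = FALSE)
    }
    run_meta$run_id <- as.character(run_meta$run_id)
  }
  out <- structure(list(labels = grid, run_meta = run_meta), class = "label_matrix")
  validate_label_matrix(out)
}

validate_label_matrix <- function(m) {
  grid <- m$labels
  if (anyDuplicated(rownames(grid))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(grid)[duplicated(rownames(grid))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(grid))) {
    stop("duplicate run ids: ",
         paste(unique(colnames(grid)[duplicated(colnames(grid))]), collapse = ", "),
         call. = FALSE)
  }
  vals <- grid[!is.na(grid)]
  if (length(vals) && any(vals < 1L)) {
    stop("labels must be positive integers; found value ", min(vals), call. = FALSE)
  }
  n_obs <- colSums(!is.na(grid))
  bad <- colnames(grid)[n_obs < 2L]
  if (length(bad)) {
    stop("column(s) with fewer than 2 observed samples carry no pairwise ",
         "information: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(m$run_meta)) {
    missing_meta <- setdiff(colnames(grid), m$run_meta$run_id)
    if (length(missing_meta)) {
      stop("run_meta lacks rows for run(s): ", paste(missing_meta, collapse = ", "),
           call. = FALSE)
    }
    if (any(m$run_meta$n_omics < 1)) stop("n_omics must be positive", call. = FALSE)
  }
  m
}

#' @export
print.label_matrix <- function(x, ...) {
  cov <- coverage(x)
  cat(sprintf("<label_matrix> %d samples x %d runs\n", nrow(x$labels), ncol(x$labels)))
  cat(sprintf("  coverage: %.3f - %.3f (median %.3f)\n",
              min(cov), max(cov), stats::median(cov)))
  if (!is.null(x$run_meta)) {
    cat(sprintf("  run_meta: n_omics %d - %d\n",
                min(x$run_meta$n_omics), max(x$run_meta$n_omics)))
  }
  invisible(x)
}

#' @rdname label_matrix
#' @param m,x A `label_matrix`.
#' @return `coverage()`: named numeric vector, per-run fraction of samples
#'   observed (the "existing sample rate"), recomputed from the grid.
#' @export
coverage <- function(m) {
  stopifnot(inherits(m, "label_matrix"))
  colSums(!is.na(m$labels)) / nrow(m$labels)
}

#' @rdname label_matrix
#' @export
sample_ids <- function(m) rownames(m$labels)

#' @rdname label_matrix
#' @export
run_ids <- function(m) colnames(m$labels)

#' Read / write a label matrix as TSV
#'
#' The on-disk format is plain tab-delimited text: a header row of run ids,
#' a first column of sample ids, and integer labels with missing cells
#' written as `"NA"` (empty cells are also accepted on read).
#'
#' @param path Path to a TSV file.
#' @param missing_marker String marking a missing cell (default `"NA"`);
#'   empty cells are treated as missing too.
#' @param run_meta_path Optional path to a run-metadata TSV with columns
#'   `run_id`, `n_omics` (a sidecar file, so the main matrix stays numeric).
#' @return `read_label_matrix()`: a validated [label_matrix]. `write_label_matrix()`:
#'   `path`, invisibly.
#' @export
read_label_matrix <- function(path, missing_marker = "NA", run_meta_path = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE)
  if (ncol(df) < 2) stop("expected a sample-id column plus at least one run column", call. = FALSE)
  ids <- df[[1]]
  grid <- as.matrix(df[, -1, drop = FALSE])
  is_missing <- grid == missing_marker | grid == "" | is.na(grid)
  # a non-missing cell must parse as an integer
  parsed <- suppressWarnings(as.numeric(grid))
  not_int <- !is_missing & (is.na(parsed) | parsed %% 1 != 0)
  if (any(not_int)) {
    w <- which(not_int, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer cell at sample '%s', run '%s': '%s'",
                 ids[w[1]], colnames(grid)[w[2]], grid[not_int][1]), call. = FALSE)
  }
  out <- matrix(NA_integer_, nrow(grid), ncol(grid),
                dimnames = list(ids, colnames(grid)))
  out[!is_missing] <- as.integer(parsed[!is_missing])
  meta <- if (!is.null(run_meta_path)) read_run_meta(run_meta_path) else NULL
  label_matrix(out, run_meta = meta)
}

#' @rdname read_label_matrix
#' @param m A [label_matrix].
#' @export
write_label_matrix <- function(m, path) {
  stopifnot(inherits(m, "label_matrix"))
  df <- tibble::as_tibble(m$labels)
  df <- tibble::add_column(df, sample_id = rownames(m$labels), .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname read_label_matrix
#' @export
read_run_meta <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    run_id = readr::col_character(), n_omics = readr::col_integer()
  ), progress = FALSE)
  tibble::as_tibble(df)
}

#' Keep runs whose sample coverage reaches a threshold
#'
#' Coverage (the existing sample rate) is recomputed per run from the grid;
#' runs with coverage `>= min_rate` are kept, in their original order. The
#' comparison is inclusive: a threshold of 0.40 retains runs covering exactly
#' 40% of the cohort.
#'
#' @param m A [label_matrix].
#' @param min_rate Minimum coverage, in (0, 1].
#' @return A [label_matrix] containing the retained runs.
#' @export
filter_by_coverage <- function(m, min_rate) {
  stopifnot(inherits(m, "label_matrix"), min_rate > 0, min_rate <= 1)
  keep <- coverage(m) >= min_rate
  if (!any(keep)) stop("no runs reach coverage ", min_rate, call. = FALSE)
  subset_runs(m, which(keep))
}

#' Select runs by how many omics platforms they integrate
#'
#' With `mode = "equal"`, keeps runs built from exactly `n` omics platforms;
#' with `mode = "larger"`, runs built from `n` or more. Requires `run_meta`
#' with an `n_omics` entry for every run.
#'
#' @param m A [label_matrix] with `run_meta`.
#' @param mode `"equal"` or `"larger"` (case-insensitive).
#' @param n The n-omics level (positive integer).
#' @return A [label_matrix] containing the selected runs, order preserved.
#' @export
select_runs <- function(m, mode = c("equal", "larger"), n) {
  stopifnot(inherits(m, "label_matrix"))
  mode <- match.arg(tolower(mode), c("equal", "larger"))
  if (is.null(m$run_meta)) {
    stop("select_runs() needs run_meta with n_omics for every run", call. = FALSE)
  }
  stopifnot(n >= 1)
  meta <- m$run_meta[match(colnames(m$labels), m$run_meta$run_id), ]
  keep <- if (mode == "equal") meta$n_omics == n else meta$n_omics >= n
  if (!any(keep)) {
    stop(sprintf("no runs match strategy %s n=%d", toupper(mode), as.integer(n)),
         call. = FALSE)
  }
  subset_runs(m, which(keep))
}

subset_runs <- function(m, idx) {
  grid <- m$labels[, idx, drop = FALSE]
  meta <- m$run_meta
  if (!is.null(meta)) meta <- meta[meta$run_id %in% colnames(grid), ]
  label_matrix(grid, run_meta = meta)
}

#' @export
tidy.label_matrix <- function(x, ...) {
  tibble::as_tibble(x$labels) |>
    tibble::add_column(sample_id = rownames(x$labels), .before = 1) |>
    tidyr::pivot_longer(-"sample_id", names_to = "run_id", values_to = "label")
}

#' @export
glance.label_matrix <- function(x, ...) {
  cov <- coverage(x)
  tibble::tibble(
    n_samples = nrow(x$labels),
    n_runs = ncol(x$labels),
    coverage_min = min(cov),
    coverage_max = max(cov),
    frac_missing = mean(is.na(x$labels))
  )
}

#' Per-run summary table
#'
#' @param m A [label_matrix].
#' @return A tibble with one row per run: `run_id`, recomputed `coverage`,
#'   number of observed samples, number of distinct labels, and `n_omics`
#'   when metadata is present.
#' @export
run_summary <- function(m) {
  stopifnot(inherits(m, "label_matrix"))
  out <- tibble::tibble(
    run_id = colnames(m$labels),
    coverage = unname(coverage(m)),
    n_observed = unname(colSums(!is.na(m$labels))),
    n_labels = unname(apply(m$labels, 2, function(v) length(unique(v[!is.na(v)]))))
  )
  if (!is.null(m$run_meta)) {
    out <- dplyr::left_join(out, m$run_meta[, c("run_id", "n_omics")], by = "run_id")
  }
  out
}
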