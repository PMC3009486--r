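# Run-block summarization: a Bayesian analysis produces several independent
# MCMC runs; averaging the RF rate over every pair of trees drawn from runs
# (i, j) collapses the t x t matrix to a k x k block matrix whose structure
# diagnoses convergence (similar runs => similar low block rates).

#' Run assignment: which run produced each tree
#'
#' @param labels character/factor vector of length t; `labels[i]` is the run
#'   label of tree ID `i - 1`.
#' @return Object of class `run_assignment` with `run_of` (character vector)
#'   and `runs` (distinct labels in order of first appearance).
#' @export
run_assignment <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyNA(labels) || any(!nzchar(labels)))
    stop_input("every tree needs a non-empty run label")
  structure(list(run_of = labels, runs = unique(labels)),
            class = "run_assignment")
}

#' Read a run-assignment file
#'
#' Two whitespace-separated columns: 0-based tree index, run label. Indices
#' must cover 0..t-1 exactly once.
#'
#' @param path input file.
#' @return A [run_assignment].
#' @export
read_run_file <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("tree", "run"),
                          colClasses = c("integer", "character"))
  t <- nrow(df)
  if (!setequal(df$tree, 0:(t - 1L)))
    stop_input("run file must label tree indices 0..%d exactly once", t - 1L)
  run_assignment(df$run[order(df$tree)])
}

#' Write a run-assignment file
#'
#' @param assignment a [run_assignment].
#' @param path output file.
#' @export
write_run_file <- function(assignment, path) {
  writeLines(paste(seq_along(assignment$run_of) - 1L, assignment$run_of), path)
  invisible(path)
}

#' Convert an RF distance matrix to RF rates
#'
#' @param M RF matrix.
#' @param n taxon count (defaults to the matrix attribute).
#' @return Matrix of percentages in `[0, 100]`.
#' @export
rf_rate_matrix <- function(M, n = attr(M, "n")) {
  if (is.null(n)) stop_input("taxon count n required")
  rf_rate(unclass(M), n)
}

#' Block-average RF rates between runs
#'
#' Off-diagonal block (i, j) is the mean rate over all cross-run tree pairs;
#' diagonal block (i, i) is the mean over distinct within-run pairs, with
#' self-distances (a tree against itself) excluded so they do not bias the
#' within-run mean downward.
#'
#' @param rates t x t RF-rate matrix (see [rf_rate_matrix]).
#' @param assignment a [run_assignment] covering all t trees.
#' @return Object of class `run_block_summary`: `block_rates` and `counts`
#'   (k x k matrices), `runs`, and `cluster_order`/`linkage` once
#'   [cluster_runs] has been applied.
#' @export
block_average <- function(rates, assignment) {
  rates <- unclass(rates)
  t <- nrow(rates)
  if (length(assignment$run_of) != t)
    stop_input("assignment labels %d trees but the matrix has %d", length(assignment$run_of), t)
  runs <- assignment$runs
  k <- length(runs)
  block <- matrix(NA_real_, k, k, dimnames = list(runs, runs))
  counts <- matrix(0, k, k, dimnames = list(runs, runs))
  idx <- lapply(runs, function(r) which(assignment$run_of == r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sub <- rates[idx[[i]], idx[[j]], drop = FALSE]
    if (i == j) {
      ni <- length(idx[[i]])
      counts[i, j] <- ni * (ni - 1)
      block[i, j] <- if (ni > 1L) sum(sub) / (ni * (ni - 1)) else 0
    } else {
      counts[i, j] <- length(idx[[i]]) * length(idx[[j]])
      block[i, j] <- mean(sub)
    }
  }
  structure(list(block_rates = block, counts = counts, runs = runs,
                 cluster_order = runs, linkage = NULL),
            class = "run_block_summary")
}

#' @export
print.run_block_summary <- function(x, ...) {
  cat("run_block_summary:", length(x$runs), "runs\n")
  print(round(x$block_rates, 2))
  invisible(x)
}

#' Hierarchically cluster runs on their block rates
#'
#' Agglomerative clustering (via `stats::hclust`) of the k runs, treating the
#' block-rate matrix as a dissimilarity; the resulting leaf order arranges the
#' runs for heatmap display so that similar runs are adjacent.
#'
#' @param summary a `run_block_summary`.
#' @param method linkage: `"complete"` (default), `"average"`, or `"single"`.
#' @return The summary with `cluster_order` (run labels in leaf order) and
#'   `linkage` (the `hclust` merge structure) filled in. With fewer than two
#'   runs a warning is issued and the summary is returned unchanged.
#' @export
cluster_runs <- function(summary, method = c("complete", "average", "single")) {
  method <- match.arg(method)
  k <- length(summary$runs)
  if (k < 2L) {
    warning("fewer than 2 runs: nothing to cluster")
    return(summary)
  }
  d <- summary$block_rates
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = method)
  summary$cluster_order <- summary$runs[hc$order]
  summary$linkage <- hc
  summary
}

#' Export a heatmap-ready block table as CSV
#'
#' Long-format CSV in clustered row/column order with one line per block
#' cell: `run_i, run_j, mean_rf_rate, n_pairs, rate_bin, bin_count`, where
#' `rate_bin` is the integer-percent bin of the cell's rate and `bin_count`
#' the number of block cells falling in that bin (the color-key histogram).
#'
#' @param summary a `run_block_summary` (ideally after [cluster_runs]).
#' @param path output CSV file.
#' @export
export_heatmap_table <- function(summary, path) {
  ord <- match(summary$cluster_order, summary$runs)
  B <- summary$block_rates[ord, ord, drop = FALSE]
  Cn <- summary$counts[ord, ord, drop = FALSE]
  bins <- floor(B)
  bin_tab <- table(bins)
  df <- data.frame(
    run_i = rep(rownames(B), times = ncol(B)),
    run_j = rep(colnames(B), each = nrow(B)),
    mean_rf_rate = as.vector(B),
    n_pairs = as.vector(Cn),
    rate_bin = as.vector(bins),
    bin_count = as.vector(bin_tab[as.character(bins)])
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a block table written by [export_heatmap_table]
#'
#' @param path CSV file.
#' @return List with `block_rates` and `counts` matrices in the file's
#'   (clustered) order.
#' @export
read_heatmap_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  runs <- unique(df$run_i)
  k <- length(runs)
  B <- matrix(df$mean_rf_rate, k, k, dimnames = list(runs, runs))
  Cn <- matrix(df$n_pairs, k, k, dimnames = list(runs, runs))
  list(block_rates = B, counts = Cn)
}
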