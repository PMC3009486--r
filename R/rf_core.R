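#' Robinson-Foulds distance between two trees (brute-force reference)
#'
#' Computes half the size of the symmetric difference between the two trees'
#' nontrivial bipartition sets. For two binary trees this equals
#' `(n - 3) - |shared bipartitions|`. This is the independent reference used to
#' verify the map/reduce pipeline; it never shares code with it beyond
#' bipartition extraction.
#'
#' @param tree_i,tree_j `ape::phylo` trees on the same taxon set.
#' @param taxa the shared [taxa_index].
#' @return Non-negative number (an integer for binary trees).
#' @export
rf_distance_oracle <- function(tree_i, tree_j, taxa) {
  bi <- extract_bipartitions(tree_i, taxa)
  bj <- extract_bipartitions(tree_j, taxa)
  (length(setdiff(bi, bj)) + length(setdiff(bj, bi))) / 2
}

#' Convert a shared-bipartition count to an RF distance
#'
#' The pipeline counts shared bipartitions per tree pair (a similarity); the
#' RF distance is that count subtracted from n - 3, the number of internal
#' edges of a binary tree on n taxa and hence the maximum RF distance.
#'
#' @param similarity shared-bipartition count, `0 <= similarity <= n - 3`.
#' @param n taxon count.
#' @return `(n - 3) - similarity`.
#' @export
similarity_to_rf <- function(similarity, n) {
  if (n < 4L) stop_input("n must be at least 4")
  if (any(similarity < 0) || any(similarity > n - 3L))
    stop_internal("similarity %s outside [0, n - 3 = %d]",
                  paste(similarity[similarity < 0 | similarity > n - 3L],
                        collapse = ","), n - 3L)
  (n - 3L) - similarity
}

#' RF rate: distance normalized to a percentage
#'
#' The RF distance divided by the internal-edge count n - 3 and multiplied by
#' 100, so identical trees score 0% and maximally different binary trees 100%.
#'
#' @param distance RF distance(s), `0 <= distance <= n - 3`.
#' @param n taxon count, at least 4.
#' @return Percentage(s) in `[0, 100]`.
#' @export
rf_rate <- function(distance, n) {
  if (n < 4L) stop_input("RF rate needs n >= 4, got %s", n)
  if (any(distance < 0) || any(distance > n - 3L))
    stop_input("distance outside [0, n - 3]")
  100 * distance / (n - 3L)
}

#' Brute-force all-pairs RF matrix
#'
#' Direct O(t^2) computation of the t x t RF matrix from per-tree bipartition
#' sets. Serves as the equivalence oracle for [run_mrsrf] and [mrsrf_pq].
#'
#' @param trees a `tree_collection` or list of `ape::phylo` trees.
#' @param taxa the shared [taxa_index]; defaults to the collection's.
#' @return t x t numeric matrix with zero diagonal, class `rf_matrix` with
#'   attributes `n` (taxa) and `t` (trees).
#' @export
all_pairs_oracle <- function(trees, taxa = attr(trees, "taxa")) {
  if (length(trees) < 1L) stop_input("need at least one tree")
  bips <- lapply(trees, extract_bipartitions, taxa = taxa)
  t <- length(trees)
  M <- matrix(0, t, t)
  if (t > 1L) {
    for (i in 1:(t - 1L)) for (j in (i + 1L):t) {
      d <- (length(setdiff(bips[[i]], bips[[j]])) +
            length(setdiff(bips[[j]], bips[[i]]))) / 2
      M[i, j] <- d
      M[j, i] <- d
    }
  }
  structure(M, class = "rf_matrix", n = taxa$n, t = t)
}

#' Bipartition hashing scheme
#'
#' The default `canonical-key` mode uses the canonical bit mask itself as the
#' bipartition identifier, which is collision-free by construction. The
#' `double-hash` mode reproduces the classic two-function scheme: `h1(B)` is a
#' table slot from a random universal hash and `h2(B)` a shortened bipartition
#' identifier (BID); its coefficients are drawn deterministically from `seed`.
#'
#' @param mode `"canonical-key"` or `"double-hash"`.
#' @param h1_size hash table size for `h1` (double-hash mode).
#' @param h2_size range of the shortened identifier `h2` (double-hash mode).
#' @param seed integer seed for the random hash coefficients.
#' @return An object of class `hash_scheme`.
#' @export
hash_scheme <- function(mode = c("canonical-key", "double-hash"),
                        h1_size = 1021L, h2_size = 2147483647, seed = 17L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, h1_size = as.numeric(h1_size),
                 h2_size = as.numeric(h2_size), seed = as.integer(seed)),
            class = "hash_scheme")
}

# deterministic per-position coefficients for the universal hashes
hash_coefficients <- function(scheme, width) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scheme$seed)
  list(a1 = sample.int(2^20, width, replace = TRUE),
       a2 = sample.int(2^20, width, replace = TRUE))
}

#' Hash a canonical bipartition
#'
#' @param mask canonical bit-string mask.
#' @param scheme a [hash_scheme].
#' @return List with `slot` (the `h1` table location) and `id` (the
#'   bipartition identifier: the mask itself in canonical-key mode, the `h2`
#'   value in double-hash mode).
#' @export
hash_bipartition <- function(mask, scheme = hash_scheme()) {
  bits <- bip_mask_bits(mask)
  co <- hash_coefficients(scheme, length(bits))
  # accumulate mod to stay in exact double range
  acc <- function(coef, m) {
    s <- 0
    for (i in seq_along(bits)) if (bits[i]) s <- (s + coef[i]) %% m
    s
  }
  slot <- acc(co$a1, scheme$h1_size)
  id <- if (scheme$mode == "canonical-key") mask else acc(co$a2, scheme$h2_size)
  list(slot = slot, id = id)
}

#' Bookkeeping formulas for a tree collection
#'
#' The number of matrix cells is t^2 and, for binary trees, the total number of
#' bipartitions processed by the pipeline is t(n - 3).
#'
#' @param t number of trees.
#' @param n number of taxa.
#' @return List with `matrix_cells`, `total_bipartitions` and `max_rf`.
#' @export
collection_stats <- function(t, n) {
  list(matrix_cells = as.numeric(t)^2,
       total_bipartitions = as.numeric(t) * (n - 3),
       max_rf = n - 3)
}

#' Write an RF (or RF-rate) matrix as plain text
#'
#' Format: first line the tree count `t`, then `t` whitespace-separated rows —
#' integers for distances, fixed two-decimal percentages for rates.
#'
#' @param M square matrix.
#' @param path output file.
#' @param rate logical; `TRUE` writes two-decimal percentages.
#' @export
write_rf_matrix <- function(M, path, rate = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(M)), con)
  fmt <- if (rate) function(r) sprintf("%.2f", r) else function(r) format(r, scientific = FALSE, trim = TRUE)
  for (i in seq_len(nrow(M))) writeLines(paste(fmt(M[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read a plain-text RF matrix written by [write_rf_matrix]
#'
#' @param path input file.
#' @return Numeric square matrix.
#' @export
read_rf_matrix <- function(path) {
  lines <- readLines(path)
  t <- as.integer(lines[1L])
  if (is.na(t) || length(lines) < t + 1L) stop_input("malformed matrix file %s", path)
  rows <- lapply(lines[2:(t + 1L)], function(l) as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]]))
  if (any(lengths(rows) != t)) stop_input("ragged matrix rows in %s", path)
  do.call(rbind, rows)
}

check_rf_matrix <- function(M, n) {
  if (nrow(M) != ncol(M)) stop_internal("RF matrix is not square")
  if (any(diag(M) != 0)) stop_internal("RF matrix has nonzero diagonal")
  if (!isTRUE(all.equal(M, t(M)))) stop_internal("RF matrix is not symmetric")
  if (any(M < 0) || any(M > n - 3L)) stop_internal("RF entry outside [0, n - 3]")
  invisible(TRUE)
}
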