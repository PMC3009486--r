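# Global orchestration: the t x t matrix is tiled across a grid of N
# simulated worker nodes; each node computes one p x q submatrix via the
# two-phase pipeline and the tiles are concatenated.

#' Cluster configuration (N nodes x c cores)
#'
#' @param nodes number of (simulated) nodes N >= 1.
#' @param cores_per_node cores per node c >= 1; serial execution is N = 1,
#'   c = 1.
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(nodes = 1L, cores_per_node = 1L) {
  nodes <- as.integer(nodes); cores_per_node <- as.integer(cores_per_node)
  if (is.na(nodes) || nodes < 1L || is.na(cores_per_node) || cores_per_node < 1L)
    stop_input("nodes and cores_per_node must be >= 1")
  structure(list(nodes = nodes, cores_per_node = cores_per_node),
            class = "cluster_config")
}

#' Grid shape for N nodes
#'
#' A perfect square N gives a sqrt(N) x sqrt(N) grid; otherwise, starting from
#' i = floor(sqrt(N)), i is decremented until it divides N evenly, giving an
#' N/i x i grid. The input size has no bearing on the shape, and rows >= cols
#' always.
#'
#' @param N number of nodes.
#' @return Integer vector `c(rows, cols)` with `rows * cols == N`.
#' @export
grid_shape <- function(N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop_input("node count must be >= 1")
  i <- as.integer(floor(sqrt(N)))
  if (i * i == N) return(c(rows = i, cols = i))
  while (N %% i != 0L) i <- i - 1L
  c(rows = N %/% i, cols = i)
}

#' Grid layout: node cells in row-major order
#'
#' @param N number of nodes.
#' @return Object of class `grid_layout`: `rows`, `cols`, and `node_cells`, a
#'   list of `c(row_block, col_block)` (1-based) per node.
#' @export
grid_layout <- function(N) {
  shape <- grid_shape(N)
  cells <- list()
  for (a in seq_len(shape[["rows"]]))
    for (b in seq_len(shape[["cols"]]))
      cells[[length(cells) + 1L]] <- c(row_block = a, col_block = b)
  structure(list(rows = shape[["rows"]], cols = shape[["cols"]],
                 N = N, node_cells = cells), class = "grid_layout")
}

#' Assign contiguous tree-ID blocks to grid nodes
#'
#' The row axis is split into `rows` contiguous near-equal blocks of tree IDs
#' (remainder to the earliest blocks), the column axis into `cols` blocks;
#' node (a, b) receives (row block a, column block b). The N submatrices tile
#' the t x t matrix exactly.
#'
#' @param t number of trees.
#' @param layout a [grid_layout].
#' @return List per node of `list(row_ids, col_ids)` (0-based tree IDs).
#' @export
assign_tree_blocks <- function(t, layout) {
  t <- as.integer(t)
  if (t < layout$rows || t < layout$cols)
    stop_input("t = %d trees cannot fill a %d x %d grid", t, layout$rows, layout$cols)
  row_blocks <- chunk_input(0:(t - 1L), layout$rows)
  col_blocks <- chunk_input(0:(t - 1L), layout$cols)
  lapply(layout$node_cells, function(cell)
    list(row_ids = row_blocks[[cell[["row_block"]]]],
         col_ids = col_blocks[[cell[["col_block"]]]]))
}

#' Assemble node submatrices into the full t x t RF matrix
#'
#' Places each tile at its (row_ids, col_ids) position, verifying that the
#' tiles cover every cell exactly once and that the assembled matrix is
#' symmetric with a zero diagonal.
#'
#' @param submatrices list of `mrsrf_submatrix` objects (or lists with `rf`,
#'   `row_ids`, `col_ids`).
#' @param t number of trees.
#' @param n number of taxa (for bound checks).
#' @return t x t integer matrix of RF distances, class `rf_matrix`.
#' @export
assemble_matrix <- function(submatrices, t, n) {
  M <- matrix(0L, t, t)
  cover <- matrix(0L, t, t)
  for (sub in submatrices) {
    ri <- sub$row_ids + 1L; ci <- sub$col_ids + 1L
    if (any(ri < 1L | ri > t) || any(ci < 1L | ci > t))
      stop_internal("tile indices outside 0..t-1")
    M[ri, ci] <- sub$rf
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  if (any(cover == 0L)) stop_internal("assembly incomplete: %d uncovered cells", sum(cover == 0L))
  if (any(cover > 1L)) stop_internal("assembly overlap: %d cells covered twice", sum(cover > 1L))
  check_rf_matrix(M, n)
  structure(M, class = "rf_matrix", n = n, t = t)
}

#' @export
print.rf_matrix <- function(x, ...) {
  cat(sprintf("rf_matrix: %d x %d trees, %d taxa (max RF %d)\n",
              nrow(x), ncol(x), attr(x, "n"), attr(x, "n") - 3L))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))), drop = FALSE])
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Compute the full t x t RF matrix
#'
#' Organizes the (simulated) nodes into a grid, assigns each node a
#' contiguous block pair of tree IDs, runs the two-phase [mrsrf_pq] pipeline
#' per node with `cores_per_node` chunks per side, and concatenates the
#' submatrices. The result is cell-identical for every cluster configuration.
#'
#' @param trees a `tree_collection` (see [parse_newick_file]) or list of
#'   `ape::phylo` trees.
#' @param taxa the shared [taxa_index]; defaults to the collection's.
#' @param cluster a [cluster_config].
#' @param engine optional [engine_config] per node; defaults to
#'   `engine_config(cores_per_node, cores_per_node)`.
#' @param allow_multifurcating unresolved trees are refused unless `TRUE`, in
#'   which case distances follow the shared-bipartition route
#'   `(n - 3) - similarity` (which can exceed the symmetric-difference value
#'   for non-binary trees).
#' @param write_submatrices optional directory; each node's tile is written as
#'   `submatrix_<node>.txt` in the [write_submatrix] dialect.
#' @param export_hashtable optional path; writes the global bipartition table
#'   (one line per bipartition: canonical mask in hex, left tree IDs, `||`,
#'   right tree IDs) as a compact alternative to the full matrix.
#' @return t x t integer `rf_matrix` of RF distances.
#' @export
run_mrsrf <- function(trees, taxa = attr(trees, "taxa"),
                      cluster = cluster_config(),
                      engine = NULL,
                      allow_multifurcating = FALSE,
                      write_submatrices = NULL,
                      export_hashtable = NULL) {
  t <- length(trees)
  if (t < 1L) stop_input("need at least one tree")
  if (is.null(taxa)) taxa <- taxa_index(sort(trees[[1L]]$tip.label))
  if (!allow_multifurcating) {
    bad <- which(!vapply(trees, is_binary_unrooted, logical(1)))
    if (length(bad))
      stop_input("tree %d is multifurcating; set allow_multifurcating = TRUE to use the (n-3) - similarity route", bad[1L] - 1L)
  }
  if (is.null(engine))
    engine <- engine_config(cluster$cores_per_node, cluster$cores_per_node)

  if (t == 1L) {
    M <- structure(matrix(0L, 1L, 1L), class = "rf_matrix", n = taxa$n, t = 1L)
    if (!is.null(export_hashtable)) export_bipartition_table(trees, taxa, export_hashtable)
    return(M)
  }

  layout <- grid_layout(min(cluster$nodes, t))
  assignment <- assign_tree_blocks(t, layout)
  subs <- lapply(assignment, function(blk)
    mrsrf_pq(trees[blk$row_ids + 1L], trees[blk$col_ids + 1L], taxa,
             config = engine, row_ids = blk$row_ids, col_ids = blk$col_ids))

  if (!is.null(write_submatrices)) {
    dir.create(write_submatrices, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(subs))
      write_submatrix(subs[[k]], file.path(write_submatrices,
                                           sprintf("submatrix_%d.txt", k - 1L)))
  }
  if (!is.null(export_hashtable)) export_bipartition_table(trees, taxa, export_hashtable)

  assemble_matrix(subs, t, taxa$n)
}

#' Build the global bipartition table for a whole collection
#'
#' One row per unique bipartition with the sorted IDs of all trees containing
#' it on both sides of the partition (the diagonal-block convention).
#'
#' @param trees tree list.
#' @param taxa the [taxa_index].
#' @return List of `hash_row`s sorted by canonical mask.
#' @export
build_bipartition_table <- function(trees, taxa = attr(trees, "taxa")) {
  tab <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    for (mask in extract_bipartitions(trees[[i]], taxa))
      tab[[mask]] <- c(tab[[mask]], i - 1L)
  }
  lapply(sort(ls(tab)), function(mask) {
    tids <- sort(unique(tab[[mask]]))
    structure(list(bip = mask, left = tids, right = tids), class = "hash_row")
  })
}

#' Export the global bipartition table as plain text
#'
#' One line per bipartition: canonical mask in hex, the left tree IDs, `||`,
#' the right tree IDs. Storing this table is a compact alternative to the
#' t x t matrix, from which the matrix can be regenerated.
#'
#' @param trees tree list.
#' @param taxa the [taxa_index].
#' @param path output file.
#' @export
export_bipartition_table <- function(trees, taxa = attr(trees, "taxa"), path) {
  rows <- build_bipartition_table(trees, taxa)
  lines <- vapply(rows, function(r)
    paste(bip_mask_hex(r$bip),
          paste(r$left, collapse = " "), "||",
          paste(r$right, collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}
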