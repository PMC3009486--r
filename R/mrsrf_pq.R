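# Phase 1 builds the partitioned global bipartition table ("global hash
# table"): one row per unique bipartition, holding the row-side and
# column-side tree IDs that contain it, separated by the "||" partition.
# Phase 2 scans the table to accumulate shared-bipartition counts per tree
# pair and converts them to RF distances by subtraction from n - 3.

#' Phase-1 map: emit marked bipartition occurrences for a chunk of trees
#'
#' Builds a local hash table for the chunk and emits one (bipartition, entry)
#' pair per unique bipartition found, carrying a marker that records which
#' side (1 = row set, 2 = column set) the chunk came from, together with the
#' chunk's tree IDs containing the bipartition.
#'
#' @param tree_chunk list of `list(tid =, tree =)` records.
#' @param marker 1 (row side) or 2 (column side).
#' @param taxa the shared [taxa_index].
#' @return List of `list(key = mask, value = list(marker, tids))` pairs.
#' @export
phase1_map <- function(tree_chunk, marker, taxa) {
  local_tab <- new.env(parent = emptyenv())
  for (rec in tree_chunk) {
    for (mask in extract_bipartitions(rec$tree, taxa)) {
      local_tab[[mask]] <- c(local_tab[[mask]], rec$tid)
    }
  }
  masks <- sort(ls(local_tab))
  lapply(masks, function(mask) {
    list(key = mask,
         value = list(marker = marker, tids = sort(unique(local_tab[[mask]]))))
  })
}

#' Phase-1 reduce: merge marked entries into one global hash table row
#'
#' Combines the per-mapper tree-ID lists for one bipartition so that row-side
#' trees (marker 1) are separated from column-side trees (marker 2), forming
#' one row `left || right` of the global hash table.
#'
#' @param bipartition canonical mask (the key).
#' @param entries list of `list(marker, tids)` values from [phase1_map].
#' @return A `hash_row`: `list(bip, left, right)` with both ID lists sorted.
#' @export
phase1_reduce <- function(bipartition, entries) {
  left <- sort(unlist(lapply(entries, function(e) if (e$marker == 1L) e$tids)))
  right <- sort(unlist(lapply(entries, function(e) if (e$marker == 2L) e$tids)))
  if (anyDuplicated(left) || anyDuplicated(right))
    stop_internal("duplicate tree ID within one side for bipartition %s", bipartition)
  structure(list(bip = bipartition,
                 left = as.integer(left %||% integer(0)),
                 right = as.integer(right %||% integer(0))),
            class = "hash_row")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Comparison cost of a hash table row
#'
#' A row with u tree IDs left of the partition and v on the right requires
#' u * v pairwise similarity increments.
#'
#' @param row a `hash_row`.
#' @return `length(left) * length(right)`.
#' @export
row_cost <- function(row) length(row$left) * length(row$right)

#' Partition hash table rows among mappers by comparison cost
#'
#' Cuts the rows (kept in sorted-bipartition order) into `m` contiguous groups
#' whose cumulative u*v costs approximate an equal share of the total: the cut
#' for group g falls where the running total reaches g/m of the total cost.
#' When every row has zero cost the rows are split into near-equal-sized
#' groups instead.
#'
#' @param rows list of `hash_row`s.
#' @param m number of groups (>= 1).
#' @return List of `m` row groups (possibly empty) whose concatenation is `rows`.
#' @export
partition_rows_by_cost <- function(rows, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop_input("mapper count must be >= 1")
  costs <- vapply(rows, row_cost, numeric(1))
  total <- sum(costs)
  if (total == 0) return(chunk_input(rows, m))
  groups <- vector("list", m)
  cum <- cumsum(costs)
  start <- 1L
  for (g in seq_len(m)) {
    if (start > length(rows)) { groups[[g]] <- rows[integer(0)]; next }
    if (g == m) { groups[[g]] <- rows[start:length(rows)]; break }
    cut <- which(cum >= total * g / m)[1L]
    cut <- max(cut, start)
    groups[[g]] <- rows[start:cut]
    start <- cut + 1L
  }
  for (g in seq_len(m)) if (is.null(groups[[g]])) groups[[g]] <- rows[integer(0)]
  groups
}

#' Phase-2 map: local similarity matrix from a portion of the hash table
#'
#' For every row of its portion, the mapper increments cell (i, j) of a local
#' p x q similarity matrix for each pair of a left-side tree i and right-side
#' tree j. Rows with an empty side are discarded — they contribute nothing.
#' The mapper then emits one (row tree ID, q-vector) pair per row of its local
#' matrix, zero vectors included.
#'
#' @param row_group list of `hash_row`s.
#' @param row_ids,col_ids tree IDs of the row set and column set.
#' @return List of `list(key = tid, value = integer q-vector)` pairs.
#' @export
phase2_map <- function(row_group, row_ids, col_ids) {
  p <- length(row_ids); q <- length(col_ids)
  S <- matrix(0L, p, q)
  for (row in row_group) {
    if (length(row$left) == 0L || length(row$right) == 0L) next
    li <- match(row$left, row_ids)
    ci <- match(row$right, col_ids)
    if (anyNA(li) || anyNA(ci))
      stop_internal("hash row for %s references unknown tree ID", row$bip)
    S[li, ci] <- S[li, ci] + 1L
  }
  lapply(seq_len(p), function(i) list(key = row_ids[i], value = S[i, ]))
}

#' Phase-2 reduce: sum local similarity rows and convert to RF
#'
#' Column-sums the per-mapper vectors for one row tree ID to form that tree's
#' final similarity row, then subtracts every cell from n - 3 to produce its
#' RF distance row.
#'
#' @param row_tid the row tree ID (key).
#' @param vectors list of equal-length q-vectors, one per phase-2 mapper.
#' @param n taxon count.
#' @return `list(similarity =, rf =)`, both integer q-vectors.
#' @export
phase2_reduce <- function(row_tid, vectors, n) {
  q <- length(vectors[[1L]])
  if (any(lengths(vectors) != q))
    stop_internal("similarity vectors for tree %s differ in length", row_tid)
  sim <- Reduce(`+`, vectors)
  list(similarity = sim, rf = similarity_to_rf(sim, n))
}

#' Compute a p x q RF submatrix with the two-phase map/reduce pipeline
#'
#' Phase 1 builds the partitioned global bipartition table from the row and
#' column tree sets (split into `config$mappers` chunks per side); phase 2
#' partitions the table rows by comparison cost, accumulates shared-bipartition
#' counts, and converts them to RF distances. When the row and column sets are
#' identical (a diagonal block), every tree's ID is placed on both sides of
#' each table row, so self pairs count n - 3 shared bipartitions and the
#' diagonal is 0.
#'
#' @param row_trees,col_trees lists of `ape::phylo` trees (sets R and C).
#' @param taxa the shared [taxa_index].
#' @param config an [engine_config]; the output never depends on it.
#' @param row_ids,col_ids global tree IDs; default `0..p-1` and `p..p+q-1`.
#'   Pass identical IDs (with identical trees) for a diagonal block.
#' @return Object of class `mrsrf_submatrix`: list with `rf` and `similarity`
#'   (p x q integer matrices), `row_ids`, `col_ids`, the phase-1 `table`, and
#'   `stats` (row count and total u*v cost).
#' @export
mrsrf_pq <- function(row_trees, col_trees, taxa, config = engine_config(),
                     row_ids = NULL, col_ids = NULL) {
  p <- length(row_trees); q <- length(col_trees)
  if (p < 1L || q < 1L) stop_input("both tree sets must be non-empty")
  if (is.null(row_ids)) row_ids <- seq_len(p) - 1L
  if (is.null(col_ids)) col_ids <- p + seq_len(q) - 1L
  diagonal <- identical(as.integer(row_ids), as.integer(col_ids))

  wrap <- function(trees, ids) mapply(function(tr, id) list(tid = id, tree = tr),
                                      trees, ids, SIMPLIFY = FALSE)
  row_chunks <- chunk_input(wrap(row_trees, row_ids), config$mappers)
  col_chunks <- if (diagonal) row_chunks else chunk_input(wrap(col_trees, col_ids), config$mappers)
  marked <- c(lapply(row_chunks, function(ch) list(marker = 1L, items = ch)),
              lapply(col_chunks, function(ch) list(marker = 2L, items = ch)))

  p1 <- run_mapreduce(
    marked,
    map_fn = function(chunk) phase1_map(chunk$items, chunk$marker, taxa),
    reduce_fn = phase1_reduce,
    config = config
  )
  rows <- lapply(p1, `[[`, "value")
  total_cost <- sum(vapply(rows, row_cost, numeric(1)))

  groups <- partition_rows_by_cost(rows, config$mappers)
  p2 <- run_mapreduce(
    groups,
    map_fn = function(g) phase2_map(g, row_ids, col_ids),
    reduce_fn = function(tid, vectors) phase2_reduce(tid, vectors, taxa$n),
    config = config
  )

  sim <- matrix(0L, p, q)
  rf <- matrix(0L, p, q)
  for (pair in p2) {
    i <- match(pair$key, row_ids)
    sim[i, ] <- pair$value$similarity
    rf[i, ] <- pair$value$rf
  }
  # self-comparison cells are 0 by definition; for binary trees the similarity
  # is already n - 3 there, so this only matters on multifurcating input
  rf[outer(as.integer(row_ids), as.integer(col_ids), "==")] <- 0L
  structure(list(rf = rf, similarity = sim,
                 row_ids = as.integer(row_ids), col_ids = as.integer(col_ids),
                 table = rows,
                 stats = list(table_rows = length(rows), total_cost = total_cost)),
            class = "mrsrf_submatrix")
}

#' @export
print.mrsrf_submatrix <- function(x, ...) {
  cat(sprintf("mrsrf_submatrix: %d x %d (hash rows: %d, total u*v cost: %g)\n",
              nrow(x$rf), ncol(x$rf), x$stats$table_rows, x$stats$total_cost))
  invisible(x)
}

#' Write a p x q submatrix in the plain-text tile dialect
#'
#' Format: header `p q`, a line of row tree IDs, a line of column tree IDs,
#' then p rows of integers. The same dialect is consumed by [read_submatrix]
#' and the assembler.
#'
#' @param sub an `mrsrf_submatrix`.
#' @param path output file.
#' @export
write_submatrix <- function(sub, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(sub$rf), ncol(sub$rf)), con)
  writeLines(paste(sub$row_ids, collapse = " "), con)
  writeLines(paste(sub$col_ids, collapse = " "), con)
  for (i in seq_len(nrow(sub$rf)))
    writeLines(paste(sub$rf[i, ], collapse = " "), con)
  invisible(path)
}

#' Read a submatrix tile written by [write_submatrix]
#'
#' @param path input file.
#' @return List with `rf`, `row_ids`, `col_ids`.
#' @export
read_submatrix <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  row_ids <- as.integer(strsplit(trimws(lines[2L]), "[[:space:]]+")[[1L]])
  col_ids <- as.integer(strsplit(trimws(lines[3L]), "[[:space:]]+")[[1L]])
  rf <- do.call(rbind, lapply(lines[3L + seq_len(dims[1L])], function(l)
    as.integer(strsplit(trimws(l), "[[:space:]]+")[[1L]])))
  list(rf = rf, row_ids = row_ids, col_ids = col_ids)
}
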