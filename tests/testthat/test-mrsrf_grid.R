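test_that("grid shapes follow the square/decrement rule", {
  expect_equal(grid_shape(4), c(rows = 2L, cols = 2L))
  expect_equal(grid_shape(18), c(rows = 6L, cols = 3L))
  expect_equal(grid_shape(7), c(rows = 7L, cols = 1L))
  expect_equal(grid_shape(1), c(rows = 1L, cols = 1L))
  for (N in 1:24) {
    s <- grid_shape(N)
    expect_equal(s[["rows"]] * s[["cols"]], N)
    expect_gte(s[["rows"]], s[["cols"]])
    if (isTRUE(all.equal(sqrt(N), round(sqrt(N)))))
      expect_equal(s[["rows"]], s[["cols"]])
  }
  expect_error(grid_shape(0), class = "mrsrf_input_error")
})

test_that("tree-block assignment tiles the index space with remainder to front", {
  layout <- grid_layout(4)
  blocks <- assign_tree_blocks(4, layout)
  expect_equal(blocks[[1]]$row_ids, 0:1)
  expect_equal(blocks[[1]]$col_ids, 0:1)
  # node N2 (second row, first column): R = {T_t/2..T_t-1}, C = {T_0..T_t/2-1}
  expect_equal(blocks[[3]]$row_ids, 2:3)
  expect_equal(blocks[[3]]$col_ids, 0:1)

  b5 <- assign_tree_blocks(5, grid_layout(2))
  expect_equal(lengths(lapply(b5, `[[`, "row_ids")), c(3L, 2L))

  # every (i, j) cell covered exactly once
  for (t in c(6, 11)) for (N in c(2, 4, 6)) {
    blocks <- assign_tree_blocks(t, grid_layout(N))
    cover <- matrix(0L, t, t)
    for (b in blocks)
      cover[b$row_ids + 1L, b$col_ids + 1L] <- cover[b$row_ids + 1L, b$col_ids + 1L] + 1L
    expect_true(all(cover == 1L))
  }
  expect_error(assign_tree_blocks(2, grid_layout(9)), class = "mrsrf_input_error")
})

test_that("assembly round-trips tiles and rejects missing or overlapping ones", {
  set.seed(31)
  trees <- random_collection(10, 8)
  taxa <- attr(trees, "taxa")
  M <- run_mrsrf(trees, taxa, cluster_config(1, 1))
  blocks <- assign_tree_blocks(8, grid_layout(4))
  tiles <- lapply(blocks, function(b)
    list(rf = unclass(M)[b$row_ids + 1L, b$col_ids + 1L, drop = FALSE],
         row_ids = b$row_ids, col_ids = b$col_ids))
  expect_equal(unclass(assemble_matrix(tiles, 8, taxa$n)), unclass(M),
               ignore_attr = TRUE)
  expect_error(assemble_matrix(tiles[-2], 8, taxa$n), "uncovered",
               class = "mrsrf_internal_error")
  expect_error(assemble_matrix(c(tiles, tiles[2]), 8, taxa$n), "overlap",
               class = "mrsrf_internal_error")
})

test_that("the full pipeline matrix equals the oracle on the worked example", {
  trees <- worked_example()
  M <- run_mrsrf(trees, cluster = cluster_config(1, 1))
  expect_equal(unclass(M), unclass(all_pairs_oracle(trees)), ignore_attr = TRUE)
  expect_equal(unclass(M)[1, ], c(0L, 1L, 0L, 1L))

  single <- run_mrsrf(trees[1], taxa_index(c("A", "B", "C", "D", "E")))
  expect_equal(unclass(single), matrix(0L, 1, 1), ignore_attr = TRUE)
})

test_that("the matrix is cell-identical across cluster configurations", {
  set.seed(37)
  trees <- random_collection(12, 16, moves = 3)
  ref <- run_mrsrf(trees, cluster = cluster_config(1, 1))
  for (N in c(2, 4, 8)) for (c in c(2, 4)) {
    M <- run_mrsrf(trees, cluster = cluster_config(N, c))
    expect_equal(unclass(M), unclass(ref), label = sprintf("N=%d c=%d", N, c))
  }
})

test_that("multifurcating trees are refused by default but allowed by flag", {
  trees <- parse_newick_file("((A,B),C,D,E);\n((A,B),C,(D,E));")
  expect_error(run_mrsrf(trees), "multifurcating", class = "mrsrf_input_error")
  M <- run_mrsrf(trees, allow_multifurcating = TRUE)
  # shared-bipartition route: one shared split -> (n-3) - 1 = 1
  expect_equal(unclass(M)[1, 2], 1L)
})

test_that("submatrix files and the hash-table export are written on request", {
  set.seed(43)
  trees <- random_collection(8, 6)
  taxa <- attr(trees, "taxa")
  dir <- withr::local_tempdir()
  ht <- withr::local_tempfile(fileext = ".txt")
  M <- run_mrsrf(trees, taxa, cluster_config(4, 1),
                 write_submatrices = dir, export_hashtable = ht)
  files <- list.files(dir, pattern = "^submatrix_")
  expect_length(files, 4L)
  tiles <- lapply(file.path(dir, files), read_submatrix)
  expect_equal(unclass(assemble_matrix(tiles, 6, taxa$n)), unclass(M),
               ignore_attr = TRUE)

  lines <- readLines(ht)
  expect_length(lines, length(build_bipartition_table(trees, taxa)))
  expect_true(all(grepl("\\|\\|", lines)))
})
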