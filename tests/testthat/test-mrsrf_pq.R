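we_setup <- function() {
  trees <- worked_example()
  list(trees = trees, taxa = attr(trees, "taxa"))
}

test_that("phase-1 map emits the worked example's marked hash table", {
  s <- we_setup()
  chunk <- list(list(tid = 0L, tree = s$trees[[1]]),
                list(tid = 1L, tree = s$trees[[2]]))
  out <- phase1_map(chunk, marker = 1L, taxa = s$taxa)
  shown <- lapply(out, function(p)
    list(bip = bip_display(p$key, s$taxa), marker = p$value$marker,
         tids = p$value$tids))
  bips <- vapply(shown, `[[`, character(1), "bip")
  expect_setequal(bips, c("AB|CDE", "ABC|DE", "ABD|CE"))
  expect_equal(shown[[match("AB|CDE", bips)]]$tids, c(0L, 1L))
  expect_equal(shown[[match("ABC|DE", bips)]]$tids, 0L)
  expect_equal(shown[[match("ABD|CE", bips)]]$tids, 1L)
  expect_true(all(vapply(shown, `[[`, integer(1), "marker") == 1L))

  expect_length(phase1_map(list(), 1L, s$taxa), 0L)
})

test_that("a chunk of identical trees emits each bipartition once with all TIDs", {
  s <- we_setup()
  chunk <- lapply(0:3, function(i) list(tid = i, tree = s$trees[[1]]))
  out <- phase1_map(chunk, 2L, s$taxa)
  expect_length(out, 2L)
  for (p in out) expect_equal(p$value$tids, 0:3)
})

test_that("phase-1 reduce separates row-side from column-side TIDs", {
  row <- phase1_reduce("00011", list(list(marker = 1L, tids = 0L),
                                     list(marker = 2L, tids = c(2L, 3L))))
  expect_equal(row$left, 0L)
  expect_equal(row$right, c(2L, 3L))

  only_left <- phase1_reduce("00101", list(list(marker = 1L, tids = 1L)))
  expect_equal(only_left$left, 1L)
  expect_length(only_left$right, 0L)

  merged <- phase1_reduce("00111", list(list(marker = 1L, tids = c(4L, 7L)),
                                        list(marker = 1L, tids = c(2L, 9L)),
                                        list(marker = 1L, tids = 5L)))
  expect_equal(merged$left, c(2L, 4L, 5L, 7L, 9L))
  expect_error(phase1_reduce("00111", list(list(marker = 1L, tids = 1L),
                                           list(marker = 1L, tids = 1L))),
               class = "mrsrf_internal_error")
})

test_that("row cost is u*v: the ABC|DE row needs exactly two comparisons", {
  row <- phase1_reduce("x", list(list(marker = 1L, tids = 0L),
                                 list(marker = 2L, tids = c(2L, 3L))))
  expect_equal(row_cost(row), 2)
  expect_equal(row_cost(phase1_reduce("x", list(list(marker = 1L, tids = 1L)))), 0)
  expect_equal(row_cost(list(left = 1:3, right = 1:4)), 12)
})

test_that("cost partitioning cuts at equal cumulative shares and loses nothing", {
  mk <- function(u, v) list(bip = "x", left = seq_len(u), right = seq_len(v))
  rows <- list(mk(1, 2), mk(2, 1), mk(1, 2), mk(2, 1))
  groups <- partition_rows_by_cost(rows, 2)
  expect_length(groups, 2L)
  expect_equal(sum(vapply(groups[[1]], row_cost, numeric(1))), 4)
  expect_equal(sum(vapply(groups[[2]], row_cost, numeric(1))), 4)
  expect_equal(do.call(c, groups), rows)

  expect_equal(partition_rows_by_cost(rows, 1)[[1]], rows)

  zero <- list(mk(1, 0), mk(0, 2), mk(3, 0))
  zg <- partition_rows_by_cost(zero, 2)
  expect_equal(do.call(c, zg), zero)
  expect_true(diff(range(lengths(zg))) <= 1)
})

test_that("phase-2 map reproduces the worked example's local emissions", {
  r1 <- phase1_reduce("a", list(list(marker = 1L, tids = 0L),
                                list(marker = 2L, tids = c(2L, 3L))))
  r2 <- phase1_reduce("b", list(list(marker = 1L, tids = 1L)))
  out <- phase2_map(list(r1, r2), row_ids = 0:1, col_ids = 2:3)
  expect_equal(out[[1]], list(key = 0L, value = c(1L, 1L)))
  expect_equal(out[[2]], list(key = 1L, value = c(0L, 0L)))

  empty <- phase2_map(list(), row_ids = 0:1, col_ids = 2:3)
  expect_equal(empty[[1]]$value, c(0L, 0L))

  full <- phase1_reduce("c", list(list(marker = 1L, tids = 0:1),
                                  list(marker = 2L, tids = 2:3)))
  out2 <- phase2_map(list(full), 0:1, 2:3)
  expect_equal(do.call(rbind, lapply(out2, `[[`, "value")),
               matrix(1L, 2, 2))
})

test_that("phase-2 reduce sums mapper vectors and subtracts from n - 3", {
  res <- phase2_reduce(0L, list(c(1L, 1L), c(1L, 0L)), n = 5)
  expect_equal(res$similarity, c(2L, 1L))
  expect_equal(res$rf, c(0L, 1L))
  single <- phase2_reduce(1L, list(c(0L, 2L)), n = 5)
  expect_equal(single$similarity, c(0L, 2L))
  expect_error(phase2_reduce(0L, list(c(1L, 1L), c(1L, 0L, 0L)), 5),
               class = "mrsrf_internal_error")
  expect_error(phase2_reduce(0L, list(c(3L, 0L)), 5),
               class = "mrsrf_internal_error")
})

test_that("the worked-example submatrix is [[0,1],[1,2]] and matches the oracle", {
  s <- we_setup()
  sub <- mrsrf_pq(s$trees[1:2], s$trees[3:4], s$taxa, engine_config(2, 2),
                  row_ids = 0:1, col_ids = 2:3)
  expect_equal(sub$rf, matrix(c(0L, 1L, 1L, 2L), 2, byrow = TRUE))
  expect_equal(sub$similarity, matrix(c(2L, 1L, 1L, 0L), 2, byrow = TRUE))
  oracle <- all_pairs_oracle(s$trees, s$taxa)
  expect_equal(sub$rf, unclass(oracle)[1:2, 3:4], ignore_attr = TRUE)
})

test_that("diagonal blocks are symmetric with zero diagonal", {
  set.seed(13)
  trees <- random_collection(10, 6)
  taxa <- attr(trees, "taxa")
  sub <- mrsrf_pq(trees, trees, taxa, engine_config(2, 2),
                  row_ids = 0:5, col_ids = 0:5)
  expect_equal(diag(sub$rf), rep(0L, 6))
  expect_equal(sub$rf, t(sub$rf))
})

test_that("pipeline equals the brute-force oracle on random splits", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    trees <- random_collection(n, 20, moves = sample(1:5, 1))
    taxa <- attr(trees, "taxa")
    sub <- mrsrf_pq(trees[1:10], trees[11:20], taxa, engine_config(3, 2),
                    row_ids = 0:9, col_ids = 10:19)
    oracle <- all_pairs_oracle(trees, taxa)
    expect_equal(sub$rf, unclass(oracle)[1:10, 11:20], ignore_attr = TRUE)
  }
})

test_that("conservation: total u*v cost equals the similarity cell sum", {
  set.seed(19)
  trees <- random_collection(12, 14, moves = 2)
  taxa <- attr(trees, "taxa")
  sub <- mrsrf_pq(trees[1:7], trees[8:14], taxa, engine_config(2, 2),
                  row_ids = 0:6, col_ids = 7:13)
  expect_equal(sub$stats$total_cost, sum(sub$similarity))
})

test_that("output is invariant to mapper/reducer counts and the discard rule", {
  set.seed(29)
  trees <- random_collection(10, 12, moves = 4)
  taxa <- attr(trees, "taxa")
  ref <- mrsrf_pq(trees[1:6], trees[7:12], taxa, engine_config(1, 1),
                  row_ids = 0:5, col_ids = 6:11)
  for (m in c(2, 4)) for (r in c(1, 3)) {
    sub <- mrsrf_pq(trees[1:6], trees[7:12], taxa, engine_config(m, r),
                    row_ids = 0:5, col_ids = 6:11)
    expect_equal(sub$rf, ref$rf, label = sprintf("m=%d r=%d", m, r))
  }
  # dropping one-sided rows before phase 2 never changes the submatrix
  keep <- Filter(function(row) row_cost(row) > 0, ref$table)
  out <- run_mapreduce(partition_rows_by_cost(keep, 2),
                       function(g) phase2_map(g, 0:5, 6:11),
                       function(tid, v) phase2_reduce(tid, v, taxa$n),
                       engine_config(2, 2))
  rf <- do.call(rbind, lapply(out, function(p) p$value$rf))
  expect_equal(rf, ref$rf)
})

test_that("submatrix tiles round-trip through the text dialect", {
  s <- we_setup()
  sub <- mrsrf_pq(s$trees[1:2], s$trees[3:4], s$taxa, row_ids = 0:1, col_ids = 2:3)
  f <- withr::local_tempfile(fileext = ".txt")
  write_submatrix(sub, f)
  back <- read_submatrix(f)
  expect_equal(back$rf, sub$rf)
  expect_equal(back$row_ids, 0:1)
  expect_equal(back$col_ids, 2:3)
})
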