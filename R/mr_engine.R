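#' Engine configuration for the map/shuffle/reduce runner
#'
#' @param mappers number of map tasks (m >= 1).
#' @param reducers number of reduce tasks (r >= 1).
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(mappers = 1L, reducers = 1L) {
  mappers <- as.integer(mappers); reducers <- as.integer(reducers)
  if (is.na(mappers) || mappers < 1L || is.na(reducers) || reducers < 1L)
    stop_input("mappers and reducers must be >= 1")
  structure(list(mappers = mappers, reducers = reducers), class = "engine_config")
}

#' Split items into k contiguous chunks
#'
#' Chunk sizes differ by at most one, with the remainder going to the earliest
#' chunks, and concatenating the chunks restores the original order.
#'
#' @param items a list or vector.
#' @param k number of chunks (>= 1); chunks may be empty when `k` exceeds the
#'   item count.
#' @return List of `k` chunks.
#' @export
chunk_input <- function(items, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_input("chunk count must be >= 1")
  n <- length(items)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  lapply(seq_len(k), function(i) {
    if (sizes[i] == 0L) items[integer(0)] else items[starts[i]:ends[i]]
  })
}

#' Run a deterministic map/shuffle/reduce job
#'
#' `map_fn(chunk)` returns a list of `list(key =, value =)` pairs; the shuffle
#' groups values by key equality; `reduce_fn(key, values)` sees every key
#' exactly once with the full list of its values. Keys must be length-1 atomic
#' values (strings or numbers). The output is sorted by key, so it is
#' identical for every mapper/reducer count and scheduling order — parallelism
#' is a contract, not a mandate, and this sequential runner is the reference
#' schedule.
#'
#' @param input_chunks list of input chunks (typically from [chunk_input]).
#' @param map_fn function(chunk) -> list of key/value pairs.
#' @param reduce_fn function(key, values) -> output value.
#' @param config an [engine_config]; `reducers` controls only how keys are
#'   batched, never the result.
#' @return List of `list(key =, value =)` pairs sorted by key. Attribute
#'   `stats` records task, key and value counts.
#' @export
run_mapreduce <- function(input_chunks, map_fn, reduce_fn,
                          config = engine_config()) {
  pairs <- list()
  for (ci in seq_along(input_chunks)) {
    emitted <- tryCatch(map_fn(input_chunks[[ci]]), error = function(e)
      stop_internal("map task %d failed: %s", ci, conditionMessage(e)))
    pairs <- c(pairs, emitted)
  }
  if (length(pairs) == 0L) {
    out <- list()
    attr(out, "stats") <- list(map_tasks = length(input_chunks), keys = 0L, values = 0L)
    return(out)
  }
  keys <- vapply(pairs, function(p) p$key, pairs[[1L]]$key)
  ukeys <- sort(unique(keys))
  groups <- split(lapply(pairs, `[[`, "value"), match(keys, ukeys))
  # batch sorted keys across r reducers; batching cannot affect the output
  batches <- chunk_input(seq_along(ukeys), config$reducers)
  out <- vector("list", length(ukeys))
  for (batch in batches) {
    for (ki in batch) {
      val <- tryCatch(reduce_fn(ukeys[ki], groups[[as.character(ki)]]),
                      error = function(e)
        stop_internal("reduce for key '%s' failed: %s", ukeys[ki], conditionMessage(e)))
      out[[ki]] <- list(key = ukeys[ki], value = val)
    }
  }
  attr(out, "stats") <- list(map_tasks = length(input_chunks),
                             keys = length(ukeys), values = length(pairs))
  out
}
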