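# Seeded generators emulating Bayesian posterior tree samples: each MCMC run
# explores a neighborhood of tree space, so a run is modeled as NNI
# perturbations of one base topology, with independent base topologies per
# run. All randomness flows through R's RNG, so a single set.seed() makes
# every collection reproducible.

#' Simulation configuration for run-structured tree collections
#'
#' @param n_taxa taxa per tree (>= 4).
#' @param t_trees total number of trees (split as evenly as possible over runs).
#' @param n_runs number of runs (independent base topologies).
#' @param moves NNI moves applied per sampled tree (perturbation radius).
#' @param seed integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 20L, t_trees = 40L, n_runs = 2L,
                       moves = 2L, seed = 1L) {
  n_taxa <- as.integer(n_taxa); t_trees <- as.integer(t_trees)
  n_runs <- as.integer(n_runs); moves <- as.integer(moves)
  if (is.na(n_taxa) || n_taxa < 4L) stop_input("n_taxa must be >= 4")
  if (is.na(t_trees) || t_trees < 1L) stop_input("t_trees must be >= 1")
  if (is.na(n_runs) || n_runs < 1L || n_runs > t_trees)
    stop_input("n_runs must be between 1 and t_trees")
  if (is.na(moves) || moves < 0L) stop_input("moves must be >= 0")
  structure(list(n_taxa = n_taxa, t_trees = t_trees, n_runs = n_runs,
                 moves = moves, seed = as.integer(seed)), class = "sim_config")
}

#' Random unrooted binary tree by sequential edge attachment
#'
#' Starts from the 3-leaf star and attaches each remaining leaf to an edge
#' chosen uniformly at random, which keeps the tree binary at every step.
#' Draws from R's global RNG; call `set.seed()` for reproducibility.
#'
#' @param n_taxa number of leaves (>= 4).
#' @param labels optional leaf labels; default `t1..tn`.
#' @return An unrooted binary `ape::phylo` tree.
#' @export
random_binary_tree <- function(n_taxa, labels = NULL) {
  n_taxa <- as.integer(n_taxa)
  if (is.na(n_taxa) || n_taxa < 4L) stop_input("n_taxa must be >= 4")
  if (is.null(labels)) labels <- paste0("t", seq_len(n_taxa))
  if (length(labels) != n_taxa) stop_input("need %d labels", n_taxa)
  # nodes: 1..n leaves, n+1.. internal; edges directed parent -> child,
  # rooted (for construction only) at the first internal node
  root <- n_taxa + 1L
  edges <- rbind(c(root, 1L), c(root, 2L), c(root, 3L))
  next_node <- n_taxa + 2L
  for (leaf in seq_len(n_taxa)[-(1:3)]) {
    e <- sample.int(nrow(edges), 1L)
    a <- edges[e, 1L]; b <- edges[e, 2L]
    x <- next_node; next_node <- next_node + 1L
    edges[e, ] <- c(a, x)
    edges <- rbind(edges, c(x, b), c(x, leaf))
  }
  kids <- split(edges[, 2L], edges[, 1L])
  newick_of <- function(node) {
    if (node <= n_taxa) return(labels[node])
    paste0("(", paste(vapply(kids[[as.character(node)]], newick_of, character(1)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(newick_of(root), ";"))
}

#' Perturb a binary tree with random NNI moves
#'
#' Applies `k_moves` nearest-neighbor-interchange moves (via
#' `phangorn::rNNI`); the result stays binary on the same taxa. A single NNI
#' replaces exactly one nontrivial bipartition, so `k_moves = 1` yields an RF
#' distance of exactly 1 and `k_moves` bounds the RF distance from above.
#'
#' @param tree binary `ape::phylo` tree.
#' @param k_moves number of NNI moves (>= 0; 0 returns the tree unchanged).
#' @return A perturbed `ape::phylo` tree.
#' @export
nni_perturb <- function(tree, k_moves) {
  k_moves <- as.integer(k_moves)
  if (is.na(k_moves) || k_moves < 0L) stop_input("k_moves must be >= 0")
  if (k_moves == 0L) return(tree)
  phangorn::rNNI(tree, moves = k_moves, n = 1L)
}

#' Generate a run-structured tree collection
#'
#' Draws one independent base topology per run and samples each run's trees
#' as NNI perturbations of its base, mimicking within-run similarity and
#' cross-run dissimilarity of posterior samples. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config].
#' @return List with `trees` (a `tree_collection`), `assignment` (a
#'   [run_assignment] with labels `run1..runK`), and `taxa`.
#' @export
generate_run_structured_collection <- function(config) {
  if (!inherits(config, "sim_config")) stop_input("config must be a sim_config")
  set.seed(config$seed)
  labels <- paste0("t", seq_len(config$n_taxa))
  taxa <- taxa_index(sort(labels))
  sizes <- lengths(chunk_input(seq_len(config$t_trees), config$n_runs))
  trees <- list()
  run_of <- character(0)
  for (r in seq_len(config$n_runs)) {
    base <- random_binary_tree(config$n_taxa, labels)
    for (s in seq_len(sizes[r])) {
      trees[[length(trees) + 1L]] <- nni_perturb(base, config$moves)
      run_of <- c(run_of, paste0("run", r))
    }
  }
  list(trees = structure(trees, class = "tree_collection", taxa = taxa),
       assignment = run_assignment(run_of),
       taxa = taxa)
}
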