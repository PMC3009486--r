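# Four 5-taxon trees whose nontrivial bipartition sets are
#   T0 = {AB|CDE, ABC|DE}, T1 = {AB|CDE, ABD|CE},
#   T2 = {AB|CDE, ABC|DE}, T3 = {ABC|DE, BC|ADE}
# with T0, T1 forming the row file and T2, T3 the column file.
worked_example <- function() {
  parse_newick_file(paste(
    "((A,B),C,(D,E));",
    "((A,B),D,(C,E));",
    "((A,B),C,(D,E));",
    "((B,C),A,(D,E));",
    sep = "\n"))
}

random_collection <- function(n_taxa, t_trees, moves = 3L) {
  labels <- paste0("t", seq_len(n_taxa))
  taxa <- taxa_index(sort(labels))
  base <- random_binary_tree(n_taxa, labels)
  trees <- lapply(seq_len(t_trees), function(i) nni_perturb(base, moves))
  structure(trees, class = "tree_collection", taxa = taxa)
}

display_set <- function(tree, taxa) {
  unname(vapply(extract_bipartitions(tree, taxa), bip_display,
                character(1), taxa = taxa))
}
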