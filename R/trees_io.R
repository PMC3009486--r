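#' Build a taxon index
#'
#' A `taxa_index` fixes the order of the taxon labels shared by every tree in
#' one analysis. Bipartition bit masks are expressed over this order, so the
#' index must be identical for all trees being compared.
#'
#' @param labels character vector of distinct, non-empty taxon names.
#' @return An object of class `taxa_index` with fields `labels` and `n`.
#' @export
taxa_index <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 4L)
    stop_input("a taxon set must contain at least 4 taxa, got %d", length(labels))
  if (any(!nzchar(labels)))
    stop_input("taxon labels must be non-empty strings")
  if (anyDuplicated(labels))
    stop_input("duplicate taxon label: %s", labels[duplicated(labels)][1L])
  structure(list(labels = labels, n = length(labels)), class = "taxa_index")
}

#' @export
print.taxa_index <- function(x, ...) {
  cat("taxa_index:", x$n, "taxa (", paste(utils::head(x$labels, 6L), collapse = ", "),
      if (x$n > 6L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Parse a Newick tree collection
#'
#' Reads one or more Newick trees (all over the same taxon set) from a file or
#' from literal text. Trees are assigned 0-based tree IDs in input order.
#' Branch lengths and internal node labels are accepted and discarded; RF
#' comparison is purely topological.
#'
#' @param x path to a Newick file, or a character string of Newick text
#'   (semicolon-terminated trees).
#' @return A `tree_collection`: a list of `ape::phylo` trees with attribute
#'   `taxa` (a [taxa_index]); tree `i` of the list has tree ID `i - 1`.
#' @export
parse_newick_file <- function(x) {
  is_path <- length(x) == 1L && !grepl("[(;]", x) && file.exists(x)
  txt <- if (is_path) readLines(x, warn = FALSE) else unlist(strsplit(x, "\n"))
  trees <- tryCatch(
    ape::read.tree(text = paste(txt, collapse = "\n")),
    error = function(e) NULL
  )
  if (is.null(trees)) {
    # locate the offending line for the error message
    for (i in seq_along(txt)) {
      if (!grepl("[^[:space:]]", txt[i])) next
      ok <- tryCatch({ape::read.tree(text = txt[i]); TRUE}, error = function(e) FALSE)
      if (!ok) stop_input("malformed Newick at line %d", i)
    }
    stop_input("malformed Newick input")
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop_input("no trees found in input")
  for (i in seq_along(trees)) {
    tl <- trees[[i]]$tip.label
    if (anyDuplicated(tl))
      stop_input("tree %d: duplicate leaf label '%s'", i - 1L,
                 tl[duplicated(tl)][1L])
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop_input("tree %d: taxon set differs from tree 0", i - 1L)
  }
  taxa <- taxa_index(ref)
  structure(trees, class = "tree_collection", taxa = taxa)
}

#' @export
print.tree_collection <- function(x, ...) {
  taxa <- attr(x, "taxa")
  cat("tree_collection:", length(x), "trees on", taxa$n, "taxa\n")
  invisible(x)
}

#' Write trees as Newick text
#'
#' @param trees a `tree_collection` or plain list of `ape::phylo` trees.
#' @param path optional output file; if `NULL` the Newick text is returned.
#' @return Newick text (one tree per line), invisibly when written to a file.
#' @export
write_newick <- function(trees, path = NULL) {
  txt <- if (length(trees) == 0L) character(0)
         else vapply(trees, function(tr) ape::write.tree(tr), character(1))
  if (is.null(path)) return(paste(txt, collapse = "\n"))
  writeLines(txt, path)
  invisible(path)
}

# canonical mask: bit string over taxon indices with the first taxon's bit
# forced to 0, so a split and its complement map to one key
bip_canonical <- function(member) {
  if (member[1L]) member <- !member
  paste(as.integer(member), collapse = "")
}

bip_mask_bits <- function(mask) {
  as.integer(strsplit(mask, "", fixed = TRUE)[[1L]])
}

#' Human-readable form of a canonical bipartition mask
#'
#' @param mask canonical bit-string mask as produced by [extract_bipartitions].
#' @param taxa the [taxa_index] the mask is expressed over.
#' @return A string `"S1|S2"` with the side containing the first taxon printed
#'   first. Single-character labels are concatenated; longer labels are
#'   comma-separated.
#' @export
bip_display <- function(mask, taxa) {
  bits <- bip_mask_bits(mask)
  if (length(bits) != taxa$n) stop_input("mask width does not match taxon count")
  sep <- if (all(nchar(taxa$labels) == 1L)) "" else ","
  s1 <- paste(taxa$labels[bits == 0L], collapse = sep)
  s2 <- paste(taxa$labels[bits == 1L], collapse = sep)
  paste0(s1, "|", s2)
}

# hex export form of a canonical mask, most-significant bit = taxon 1
bip_mask_hex <- function(mask) {
  bits <- bip_mask_bits(mask)
  pad <- (4L - length(bits) %% 4L) %% 4L
  bits <- c(bits, rep(0L, pad))
  nyb <- vapply(seq_len(length(bits) / 4L), function(i) {
    b <- bits[(4L * i - 3L):(4L * i)]
    sum(b * c(8L, 4L, 2L, 1L))
  }, integer(1))
  paste(sprintf("%x", nyb), collapse = "")
}

#' Extract the nontrivial bipartitions of a tree
#'
#' Each internal edge of the unrooted tree splits the taxa into two sets; the
#' trivial splits induced by leaf edges are excluded. A rooted input has its
#' degree-2 root suppressed first. For a binary tree on n taxa this yields
#' exactly n - 3 bipartitions.
#'
#' @param tree an `ape::phylo` tree whose tips are a subset of `taxa`.
#' @param taxa the [taxa_index] of the analysis.
#' @return Sorted character vector of canonical bit-string masks; each mask has
#'   a `0` for the first taxon's side (see [bip_display] to render).
#' @export
extract_bipartitions <- function(tree, taxa) {
  idx <- match(tree$tip.label, taxa$labels)
  if (anyNA(idx))
    stop_input("leaf label '%s' not in taxon index",
               tree$tip.label[which(is.na(idx))[1L]])
  tr <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  n <- taxa$n
  pp <- ape::prop.part(tr)
  masks <- character(0)
  for (clade in pp) {
    sz <- length(clade)
    if (sz < 2L || sz > n - 2L) next      # trivial split or whole-tree clade
    member <- logical(n)
    member[idx[clade]] <- TRUE
    masks <- c(masks, bip_canonical(member))
  }
  sort(unique(masks))
}

# TRUE when the unrooted topology is fully resolved
is_binary_unrooted <- function(tree) {
  tr <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  tr$Nnode == ape::Ntip(tr) - 2L
}
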