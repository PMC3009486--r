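---
title: "Computing all-pairs Robinson-Foulds matrices by map/reduce decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing all-pairs Robinson-Foulds matrices by map/reduce decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsrf)
```

## The problem

Bayesian phylogenetic analyses return thousands of candidate trees sampled
from a posterior distribution. Summarizing such a collection — and deciding
whether independent MCMC runs have converged on the same region of tree
space — starts from the *t* × *t* matrix of pairwise Robinson-Foulds (RF)
distances. Entry (*i*, *j*) is the RF distance between trees *T~i~* and
*T~j~*: half the size of the symmetric difference between the two trees'
sets of nontrivial bipartitions. A bipartition (split) is the two-way
division of the taxon set induced by removing one internal edge of the
unrooted tree; an unrooted binary tree on *n* taxa has exactly *n* − 3 of
them, so the RF distance ranges from 0 to *n* − 3. The **RF rate** rescales
it to a percentage, 100 · *d* / (*n* − 3), so that 0% means identical
topologies and 100% maximally different ones.

Computing all *t*² entries naively is expensive because most bipartitions
are shared by many trees. This package organizes the computation the way
fast hash-based algorithms do: invert the data once into a *global
bipartition table* mapping each unique split to the IDs of the trees
containing it, then count, for every tree pair, how many splits they share.
For two binary trees the distance is recovered as
(*n* − 3) − (shared splits), which agrees with the symmetric-difference
definition; the package asserts that identity on random instances rather
than assuming it.

## The two-phase pipeline

`mrsrf_pq()` computes one *p* × *q* block of the matrix from a row tree set
ℛ and a column tree set 𝒞, in two map/shuffle/reduce phases executed on a
deterministic in-process engine (`run_mapreduce()`):

1. **Phase 1 (table construction).** Each mapper takes a chunk of trees
   carrying a marker (1 = row side, 2 = column side), extracts their
   canonical bipartition masks, and emits one (bipartition, marked TID list)
   pair per split it saw. The reducer for a bipartition merges the lists
   into a table row `left || right`, separating row-side from column-side
   trees so that trees from the same side are never compared to each other.
2. **Phase 2 (counting).** A row with *u* IDs left of `||` and *v* on the
   right implies *u·v* shared-split increments, so rows are dealt to mappers
   in contiguous groups of approximately equal total *u·v* cost. Each mapper
   accumulates a local *p* × *q* similarity matrix (rows with an empty side
   contribute nothing) and emits one (row TID, row vector) pair per row of
   its local matrix. The reducer column-sums the per-mapper vectors and
   subtracts every cell from *n* − 3.

A conservation identity ties the phases together: the total *u·v* cost of
the table equals the sum of all similarity cells, because every
shared-bipartition pair is counted exactly once. The tests assert it on
every kind of block.

For the full matrix, `run_mrsrf()` arranges *N* simulated worker nodes into
a grid (a perfect square *N* gives √*N* × √*N*; otherwise *i* = ⌊√*N*⌋ is
decremented until it divides *N*, giving *N*/*i* × *i* — e.g. 2 × 2 for
*N* = 4 and 6 × 3 for *N* = 18), splits the tree IDs into contiguous
near-equal blocks along each axis (remainder to the earliest blocks, our
choice where block sizing is otherwise unspecified), runs `mrsrf_pq()` per
node with `cores_per_node` chunks per side, and concatenates the tiles,
verifying exact single coverage, symmetry, and a zero diagonal.

"Nodes" and "cores" here are simulated workers: the engine runs a
sequential reference schedule, and the contract — asserted across
(*N*, *c*, mappers, reducers) combinations — is that the output is
cell-identical to the serial run. Parallel scheduling could be added behind
the same contract without touching the algorithm.

### Diagonal blocks and degenerate inputs

When ℛ = 𝒞 every tree ID is placed on both sides of each table row and
self-pairs are counted, which keeps the uniform *u·v* accounting; a binary
tree shares all *n* − 3 splits with itself, so its diagonal cell is 0
automatically. Self-comparison cells are additionally pinned to 0, which
only matters for multifurcating input (below). Duplicate trees are legal
and simply produce zero distances. A single tree yields the 1 × 1 zero
matrix.

Multifurcating trees have fewer than *n* − 3 splits, and the two RF routes
diverge: (*n* − 3) − shared exceeds the symmetric-difference value. The
pipeline therefore refuses unresolved trees unless
`allow_multifurcating = TRUE`, in which case it reports the
(*n* − 3) − similarity value, keeping the table arithmetic intact, while
`rf_distance_oracle()` remains available for the symmetric-difference
number.

### Hashing

Bipartitions are keyed by a canonical mask: a bit vector over the taxon
index with the first taxon's side fixed to 0, so a split and its complement
compare equal with no pairwise testing. This canonical-key scheme is
collision-free by construction and is the default. A classic double-hash
mode (`hash_scheme("double-hash")`) — a random universal *h₁* for the table
slot and *h₂* for a shortened bipartition identifier — is provided for
fidelity experiments, but correctness is never made to depend on an
unstated collision probability, which is why it is not the default.

## Run-block summaries for convergence

Given a run label per tree (`run_assignment()`), `block_average()`
collapses the RF-rate matrix to a *k* × *k* block matrix: off-diagonal
block (*i*, *j*) is the mean rate over all cross-run pairs, and diagonal
block (*i*, *i*) averages over distinct within-run pairs with self-pairs
excluded — including the *t* zero self-distances would bias the within-run
mean downward, which is exactly the quantity convergence diagnostics care
about. `cluster_runs()` then orders the runs by agglomerative clustering of
the block matrix (`stats::hclust`; complete linkage by default since the
linkage is otherwise unspecified, with average/single available), and
`export_heatmap_table()` writes a heatmap-ready CSV with pair counts and an
integer-percent histogram of the block values. Converged analyses show
within-run block rates comparable to cross-run rates; separated runs show
the within < cross pattern.

## The synthetic generator

Real inputs are posterior samples; the generator emulates their one
structural feature the summarizer depends on — within-run cohesion versus
cross-run separation — by drawing one independent base topology per run
(sequential random edge attachment of leaves, which keeps the tree binary
at every step; no claim of exact uniformity over tree space is made or
needed) and sampling each run's trees as `moves` random NNI perturbations
of its base (`phangorn::rNNI`). NNI was chosen over SPR because a single
NNI changes exactly one split of a binary tree, giving the sharp test
RF = 1 at `moves = 1`; `moves` also bounds the RF distance from above. All
randomness flows from one seed, so collections are byte-reproducible.

What the generator does *not* emulate: MCMC autocorrelation, posterior
weights, branch lengths, or the tree-space geometry of real likelihood
surfaces. Passing tests therefore demonstrate algebraic correctness of the
pipeline on arbitrary binary topologies, not statistical properties of real
posteriors.

Default simulation conditions are desk-scale: 20 taxa, 40 trees, 2 runs,
2 NNI moves. The verification suite runs the pipeline against a brute-force
all-pairs oracle on dozens of random collections of up to 50 trees and 20
taxa, and checks configuration invariance on a fixed 40-tree collection —
sizes at which the exhaustive oracle is itself trustworthy and fast. The
field-scale collections the method is meant for (tens of thousands of
trees) differ only in constant factors, not in code path.

## Numerical choices

The whole distance path is integer arithmetic; rates become floating point
only at output. Similarity cells are bounded by *n* − 3 and checked, as are
matrix symmetry, zero diagonal, and tile coverage after assembly — a
violated invariant raises an internal-consistency error rather than
returning a silently wrong matrix. Engine output is sorted by key, and all
ID lists are kept in ascending order, making every artifact byte-stable.

## Limitations

- All trees must share one taxon set; inputs with differing leaf sets are
  rejected rather than pruned to a common subset.
- The engine is a correctness model of map/reduce, not a performance layer;
  wall-clock scaling of the original multi-core setting is out of scope.
- RF itself saturates quickly for distant trees; the block summaries
  inherit that insensitivity at high rates.
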