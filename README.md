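# mrsrf

All-pairs Robinson-Foulds (RF) distance matrices for phylogenetic tree
collections, computed through a two-phase map/shuffle/reduce pipeline over a
global bipartition hash table.

## What it does and for whom

A Bayesian phylogenetic analysis yields thousands of sampled trees; comparing
every pair of them is the starting point for summarizing the sample and for
checking that independent MCMC runs converged. For trees *T_i*, *T_j* on a
shared set of *n* taxa, the RF distance is

    RF(T_i, T_j) = |B(T_i) Δ B(T_j)| / 2

where *B(T)* is the set of nontrivial bipartitions (splits) of the unrooted
tree — for binary trees equivalently (n − 3) − |B(T_i) ∩ B(T_j)|. The **RF
rate** is 100 · RF / (n − 3), from 0% (identical) to 100% (maximally
different).

Instead of comparing trees pairwise, the package inverts the collection into
a table mapping each unique bipartition to the trees containing it (phase 1),
then counts shared splits per tree pair from that table and subtracts from
n − 3 (phase 2). The t × t matrix is tiled across a grid of simulated worker
nodes, each computing one p × q block; the result is provably identical for
every node/core/mapper/reducer configuration, and a brute-force oracle
(`all_pairs_oracle`) verifies it in the tests. A run-block summarizer
averages RF rates between MCMC runs and clusters the runs for heatmap
display, the standard convergence picture.

## Worked example

Four 5-taxon trees, the first and third identical:

```r
library(mrsrf)
trees <- parse_newick_file("((A,B),C,(D,E));
((A,B),D,(C,E));
((A,B),C,(D,E));
((B,C),A,(D,E));")
M <- run_mrsrf(trees, cluster = cluster_config(4, 2))  # 4 nodes x 2 cores
M
#> rf_matrix: 4 x 4 trees, 5 taxa (max RF 2)
#>      [,1] [,2] [,3] [,4]
#> [1,]    0    1    0    1
#> [2,]    1    0    1    2
#> [3,]    0    1    0    1
#> [4,]    1    2    1    0
rf_rate_matrix(M)[1, ]
#> [1]  0 50  0 50
```

Trees 0 and 2 share both of their splits (distance 0); trees 1 and 3 share
neither, so their distance is the maximum n − 3 = 2 (rate 100%). The same
matrix is produced for any `cluster_config`.

Run-level convergence summary on a simulated two-run collection:

```r
sim <- generate_run_structured_collection(sim_config(20, 40, n_runs = 2, seed = 1))
rates <- rf_rate_matrix(run_mrsrf(sim$trees))
s <- cluster_runs(block_average(rates, sim$assignment))
s$block_rates   # 2 x 2 mean RF rates: within-run < cross-run
```

A command-line wrapper with `compute`, `summarize`, and `simulate`
subcommands is installed at `inst/scripts/mrsrf`.

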