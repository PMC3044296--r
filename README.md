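# pathgroups

Fast heuristic reconstruction of ancestral gene orders on a fixed
phylogeny under the double-cut-and-join (DCJ) rearrangement distance.

## The problem

A genome is modelled as a set of linear chromosomes, each an ordered run
of signed genes over a shared universe `1..n`; the sign records reading
orientation. The DCJ distance `d(G1, G2)` — the minimum number of
rearrangement operations (inversions, reciprocal translocations, fusions,
fissions, all subsumed by double-cut-and-join) transforming one genome
into the other — is computed from the breakpoint graph on gene
extremities: one genome's adjacencies are blue edges, the other's red,
telomeres are capped so every vertex carries one edge of each colour, and
the graph decomposes into κ alternating cycles, giving

    d(G1, G2) = n′ − κ

with `n′` the number of blue edges after capping.

Given an unrooted binary tree whose `N` leaves carry known genomes, the
*small phylogeny problem* asks for the `N − 2` ancestral genomes
minimizing the total DCJ length over all `2N − 3` edges; with `N = 3` it
is the *gene-order median problem*. Both are NP-hard, yet instances of
biological interest have thousands of genes, which rules out exact
solvers once genomes are substantially rearranged.

This package implements the *pathgroups* approach: a data structure for
greedy cycle maximization. Every non-cap ancestral vertex anchors a
pathgroup of up to three partially built breakpoint-graph paths (one per
incident tree branch). At each step a red (ancestral) adjacency is added
in the pathgroup of highest priority, closing as many alternating cycles
as possible while never closing a circular chromosome; bookkeeping per
step is constant (at most four secondary and eight tertiary pathgroups
are touched), so a full reconstruction runs in time linear in the number
of genes. Three priority schemes trade accuracy against work: the basic
one-step look-ahead (7 priority levels), a refined scheme that also
scores the net change in potential cycles over all affected pathgroups
(55 levels), and a two-step look-ahead (165 levels). On top of the
single-pass solver, iterative median-based refinement with an
accept-if-not-worse (simulated annealing) rule polishes full-tree
reconstructions.

A rearrangement simulator (90% inversions / 10% reciprocal
translocations by default, matching the accuracy-experiment protocol)
generates test instances with known history, so reconstruction accuracy
can be quantified as `d/τ`, reconstructed versus true tree length.

## A worked example

```r
library(pathgroups)

# one inversion apart
a <- genome(c(1L, 2L, 3L, 4L), name = "A")
b <- genome(c(1L, -3L, -2L, 4L), name = "B")
dcj_distance(a, b)
#> DCJ distance d = 1  (n' = 5 blue edges, kappa = 4 cycles)

solve_median(a, a, b)
#> Pathgroups median (refined scheme)
#>   branch distances: 0 0 1
#>   total: 1
#>   ancestor: 4 genes on 1 chromosome(s)

# a 10-leaf tree, 1000 genes, 100 random rearrangements per branch
sim <- simulate_tree(n = 1000, leaves = 10, ops_per_branch = 100,
                     chromosomes = 10, seed = 1)
fit <- solve_small_phylogeny(sim$tree, sim$leaf_genomes, scheme = "lookahead2")
fit
#> Pathgroups small phylogeny (lookahead2 scheme): 10 leaves, 8 ancestors
#>   total tree length: 1692 over 17 edges
tree_length(sim$tree, sim$leaf_genomes, sim$true_ancestors)
#> [1] 1682
```

The reconstruction recovers a history of length 1692 against a true
simulated length of 1682 (`d/τ = 1.006`): at this rearrangement rate
(0.1n per branch) the greedy solution is within a percent of the planted
scenario. `run_experiment()` wraps this loop over replicates and reports
per-replicate `d`, `τ` and `d/τ`; `refine_by_medians()` improves a fit by
sweeping median re-solves over the internal nodes.

A command-line interface with `distance`, `median`, `phylo` and
`simulate` subcommands ships as `inst/cli/pathgroups.R`; see `?pg_main`.

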