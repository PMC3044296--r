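---
title: "Greedy cycle maximization for ancestral gene-order reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy cycle maximization for ancestral gene-order reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgroups)
```

## The model

A genome is a set of linear chromosomes over a shared universe of `n`
distinct signed genes; every gene appears exactly once, its sign giving
the reading orientation. Equality of genomes ignores chromosome order
and whole-chromosome orientation (a chromosome read backwards with all
signs negated is the same chromosome); `canonical_genome()` fixes a
deterministic representative for comparison and hashing. Gene families,
unsigned genes and circular chromosomes are out of scope: duplicated or
missing genes are hard validation errors, and circular input is not
representable.

Each gene `g` contributes a tail extremity (encoded `2g-1`) and a head
extremity (`2g`); a gene with positive sign contributes them in the
order tail, head; with negative sign head, tail. Neighbouring genes on a
chromosome define an *adjacency*, the unordered pair of their facing
extremities; a genome of `n` genes on `c` chromosomes has `n - c`
adjacencies and `2c` telomere extremities.

The DCJ distance between two genomes is read off the breakpoint graph:
blue edges are the first genome's adjacencies, red the second's.
Telomeres are capped — each first-genome telomere joins a cap by a blue
edge, each second-genome telomere by a red edge; a path whose two loose
ends are both first-genome caps is closed with a red edge, both
second-genome caps with a blue edge (which counts towards the blue edge
total), and one of each collapses its caps to a single vertex. Every
component is then an alternating cycle, and `d = n' - kappa`, with `n'`
the blue edges after capping and `kappa` the cycle count. The
implementation (`dcj_distance()`) never materializes caps; it classifies
each path component by the colours its two ends are missing, which is
equivalent and keeps genome objects clean.

One point deserves emphasis because it shaped the test suite: the DCJ
metric counts operations that may pass through *circular* intermediate
states even when start and end are fully linear. A brute-force
shortest-path search that forbids circular products computes a different
(larger) distance on some instances — the smallest counterexamples have
three genes. The package's brute-force oracle therefore searches over
adjacency sets with circular components allowed; with that search space
the formula and the oracle agree on the full genome space for up to four
genes. The *reconstruction*, by contrast, must never output circular
chromosomes, and the greedy algorithm enforces that strictly.

## Pathgroups and the greedy step

For an ancestor being reconstructed, its red adjacencies are shared
across the breakpoint graphs towards all three neighbours. A *pathgroup*
anchors at one ancestral extremity and holds the up-to-three partial
alternating paths (one per incident tree branch) currently ending there;
initially every blue edge of a given genome is a path. A *fragment* is a
maximal run of genes already joined by red edges; fragments start as
singleton genes, only ever grow by concatenation, and each fragment
surviving to the end becomes one linear chromosome of the ancestor.

A greedy step picks the live pathgroup of highest priority and adds one
red edge from its anchor `x` to the far endpoint `y` of one of its
paths. This closes every path of the group that runs from `x` to `y`
(each closed path is a finished cycle), concatenates the remaining paths
with those anchored at `y`, joins the fragments containing `x` and `y`,
and deletes the two pathgroups at `x` and `y` — the live count falls by
exactly two per step, which the engine asserts on every run. The edge
`x`–`y` is forbidden when `x` and `y` are the two ends of the same
fragment (it would close a circular chromosome) and caps never receive
red edges. A step touches at most four *secondary* pathgroups (those at
the far ends of the merged paths) and at most eight *tertiary* ones
(their partners), so priority maintenance is constant work per step and
the whole solve is linear in `n`.

### Scoring a candidate edge

The number of cycles a candidate edge can close (1–3) is the primary
score. The implementation refines this count in one deliberate way: on a
branch where the candidate edge does not close a cycle but would merge
two paths *both of which already end in caps*, the candidate is charged
-1, because caps never take red edges — the merged component is frozen,
and one capping cycle of the final distance computation is forfeited
with certainty. Under the literal "cycles created" count, the end-game
steps at telomere extremities (close one cycle on one branch, merge two
cap-ended paths on the other two) are systematically harmful: they made
the median of `(G1, G1, G3)` exceed `d(G1, G3)` in about a third of
random small instances. With the net count those steps score zero or
less, never fire, and the identical-pair median is exact on every
instance we enumerate; the measured accuracy on large simulated medians
also improves slightly. A pathgroup whose every candidate scores below
one has no priority and waits (possibly forever — its extremities then
end as ancestral telomeres).

### Priority schemes

Candidates and groups are ranked lexicographically by

1. `cycles` — net cycles closable now (3 > 2 > 1);
2. `best_next` — the best cycle count available in any affected
   pathgroup immediately after the step (3 > 2 > 1);
3. `net_delta` — refined and two-step schemes only: the net change in
   potential cycles summed over all affected pathgroups (secondary,
   tertiary, and the up-to-two groups at the joined fragment's ends);
4. `second_step` — two-step scheme only: the best cycle count available
   one step further, after the best affected group is itself processed.

A three-cycle step is already perfect, so its class is not subdivided by
`best_next`/`net_delta` (the two-step scheme still subdivides it by
`second_step`). `net_delta` saturates at ±4: a step has at most four
secondary pathgroups, each typically moving by at most one potential
cycle; tertiary and fragment-end effects rarely push past that, and
saturation keeps the level table finite. This yields 7 levels for the
basic scheme, `1 + 2·3·9 = 55` for the refined scheme, and `55·3 = 165`
for the two-step scheme; `priority_levels()` enumerates the classes from
the engine's own level map rather than from these closed forms, and the
counts are what the acceptance script reports. The width of the
saturation band is the one free choice in this enumeration; the 9-value
band is the smallest symmetric one consistent with the
four-secondary-groups bound, and we fixed it before measuring anything
else.

Look-ahead quantities are measured by actually applying the candidate
edge to the live structures, reading off the affected groups, and
undoing the changes through a change log — never by cloning the state —
so the per-step cost stays bounded. Within a priority level, groups are
served in queue order (most recent priority assignment last); remaining
ties fall to the smallest anchor vertex, and among equally good candidate
edges the smallest target vertex wins. These tie-breaks are arbitrary
but fixed: every solve is bit-reproducible.

## Small phylogeny

For a tree with several ancestors, every internal node keeps a full
pathgroup table, and all tables share one bucket queue: the highest
priority group anywhere is processed next. Paths towards a neighbouring
*ancestor* are initially missing — the pathgroup holds a bare vertex in
that slot — and every red edge fixed at one ancestor immediately becomes
blue material in the neighbour's corresponding paths; the two ends of a
tree edge literally share one path structure, each side contributing its
own colour. Since missing paths cannot close cycles, groups near given
genomes naturally outrank groups deep in the tree; no special ordering
rule is needed. With three leaves the machinery reduces exactly to the
median solver (the test suite asserts bit-identical ancestors).

The per-branch cycle counting extends to shared structures: closing a
path counts as a cycle only when both its ends already carry the other
side's colour, i.e. when the closure really completes an alternating
cycle rather than leaving a component that still needs edges from the
neighbouring ancestor.

## Iterative median refinement

`refine_by_medians()` revisits internal nodes in a seeded random order,
re-solves the median of each node's three current neighbour genomes, and
accepts the proposal whenever its local objective (the sum of the three
incident branch distances, which is exactly the change in the global
objective) is **less than or equal to** the current one. Accepting equal
moves is the annealing regime that lets the search drift across plateaus
instead of freezing in the first local minimum; there is no temperature
schedule. The default budget is 50 sweeps; the trace of every proposal
(old/new local objective, acceptance, running total) is returned, and
the total is non-increasing by construction. Random-genome
initialization (`random_initial_ancestors()`) is available for studying
how much the single greedy pass actually contributes; with enough sweeps
the refined objective no longer remembers the initialization.

## The simulator

`simulate_tree()` emulates the accuracy protocol used throughout:
a uniform random signed genome (default 10 chromosomes) is placed at an
internal node and evolved outward, applying a fixed number of random
operations per branch — 90% inversions, 10% reciprocal translocations by
default. Inversions pick a chromosome uniformly and two distinct gene
gaps uniformly (whole-chromosome inversions allowed; zero-length draws
redrawn); translocations pick two distinct chromosomes, one gap in each,
and one of the two rejoining orientations uniformly, redrawing draws
that would leave an empty chromosome or merely swap/flip whole
chromosomes, so the chromosome count is invariant and every counted
operation is structurally effective. A translocation requested of a
single-chromosome genome is resampled as an inversion. Breakpoints are
uniform *per chromosome*, not genome-wide, so long chromosomes are not
favoured — the alternative weighting was considered and rejected as a
sensitivity concern rather than a modelling need.

Accuracy is reported as `d/τ`, where `d` is the reconstructed total tree
length and `τ` the *inherent* length of the simulation — the total
branch length measured with the true ancestors in place. The raw
operation count (`tau_ops`) is reported alongside: random operations
partially cancel, so the inherent length falls a few percent short of
the count already at per-branch rate `0.2n`, and using the count as the
denominator would flatter or penalize the reconstruction for reasons
that have nothing to do with it. At rates well past `0.3n` the measure
loses meaning altogether — distances saturate at `n` per branch while
operations keep accumulating, so any inference method reports `d` far
below the operation count there.

What the simulator does *not* emulate: gene gain and loss, unequal
family sizes, transpositions as primitive events, rate variation across
branches, or any sequence-level signal. Passing accuracy tests on these
simulations therefore demonstrates that the greedy recovers rearrangement
histories of the assumed kind; it says nothing about ortholog
assignment or content differences, which real data sets must resolve
before this machinery applies.

## Problem sizes and numerical choices

The package's own quantitative checks run at desk scale, chosen so the
full suite completes in minutes on one CPU while leaving the qualitative
structure of the full-scale experiments intact: median accuracy at
`n = 1000` genes, per-branch rate `0.2n`, 10 replicates (mean `d/τ`
within ±0.02 of 1); scheme comparisons on 10-leaf trees at `n = 300`
with 10 replicates, where the orderings basic ≥ refined ≥ two-step ≥
refined-plus-50-sweeps hold with clear margins; and structural bounds
instrumented over more than 10⁴ greedy steps. The brute-force cross
checks (BFS over the full genome space, exhaustive medians) run at
`n ≤ 4`, where the spaces are enumerable.

Degenerate inputs are handled explicitly: single-gene genomes admit no
red edges and return unchanged; zero-rate simulations yield `τ = 0` and
an `NA` accuracy ratio rather than a division by zero; genomes whose
chromosome count equals `n` have only cap-bounded paths and reconstruct
to themselves trivially.

## Known limitations

The greedy pass is single-shot: it cannot repair an early mistake, and
its accuracy degrades once per-branch rates pass roughly `0.2n`
(refinement sweeps push this boundary but do not remove it). The
priority schemes look at most two steps ahead; the saturation band on
`net_delta` discards distinctions beyond ±4, which is harmless in the
regimes we measure but is an approximation. Memory is spent generously —
every gene holds two pathgroups per internal node — so very large trees
with very large genomes will feel it before they feel the running time.
Tree topology search is deliberately out of scope: the tree is an input,
and scanning topologies is a thin outer loop left to the caller.
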