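Package: pathgroups
Title: Ancestral Gene-Order Reconstruction by Greedy Cycle Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heuristic reconstruction of ancestral genomes on a fixed
    phylogeny under the double-cut-and-join (DCJ) rearrangement distance.
    Implements the pathgroups data structure and a greedy cycle-maximization
    algorithm for the gene-order median problem and the small phylogeny
    problem, with one-step, refined and two-step look-ahead priority
    schemes, iterative median-based local improvement with an
    accept-if-not-worse rule, and a rearrangement simulator (inversions and
    reciprocal translocations) for accuracy experiments. Genomes are sets
    of linear chromosomes of signed gene identifiers, read and written in a
    GRIMM-style dialect; trees are Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
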