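#' Draw a uniform random genome
#'
#' A uniform random signed order of the genes `1..n`, cut into the
#' requested number of non-empty linear chromosomes.
#'
#' @param n gene count.
#' @param chromosomes chromosome count (`1 <= chromosomes <= n`).
#' @param name optional label.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a [genome].
#' @export
random_genome <- function(n, chromosomes = 10L, name = NULL, seed = NULL) {
  n <- as.integer(n); chromosomes <- as.integer(chromosomes)
  if (n < chromosomes || chromosomes < 1L)
    stop_pg("pg_invalid_arg", "need n >= chromosomes >= 1")
  with_seed(seed, {
    perm <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
    cuts <- if (chromosomes > 1L)
      sort(sample.int(n - 1L, chromosomes - 1L)) else integer(0)
    bounds <- c(0L, cuts, n)
    chroms <- lapply(seq_len(chromosomes), function(i)
      perm[(bounds[i] + 1L):bounds[i + 1L]])
    genome(chroms, name = name, n = n)
  })
}

# Inversion: reverse and negate the segment between breakpoints i < j of
# one chromosome (positions counted in gene gaps 0..m, both chromosome
# ends allowed).
invert_segment <- function(chrom, i, j) {
  m <- length(chrom)
  stopifnot(i >= 0L, j <= m, i < j)
  c(if (i > 0L) chrom[seq_len(i)],
    -rev(chrom[(i + 1L):j]),
    if (j < m) chrom[(j + 1L):m])
}

# Reciprocal translocation: cut chromosome u at gap i and v at gap j and
# exchange the pieces; orientation 1 swaps the suffixes, orientation 2
# joins each prefix to the reversed-and-negated other prefix.  Both
# products must be non-empty.
translocate_segments <- function(cu, cv, i, j, orientation = 1L) {
  mu <- length(cu); mv <- length(cv)
  stopifnot(i >= 0L, i <= mu, j >= 0L, j <= mv)
  A <- if (i > 0L) cu[seq_len(i)] else integer(0)
  B <- if (i < mu) cu[(i + 1L):mu] else integer(0)
  C <- if (j > 0L) cv[seq_len(j)] else integer(0)
  D <- if (j < mv) cv[(j + 1L):mv] else integer(0)
  if (orientation == 1L) list(c(A, D), c(C, B))
  else list(c(A, -rev(C)), c(-rev(B), D))
}

#' Apply random rearrangements to a genome
#'
#' Draws `k` operations independently: with probability
#' `inversion_fraction` a chromosomal inversion (a chromosome chosen
#' uniformly, two distinct breakpoints chosen uniformly among its gene
#' gaps including the ends; the enclosed segment is reversed and negated),
#' otherwise a reciprocal translocation (two distinct chromosomes, one
#' breakpoint in each, pieces exchanged with a uniformly random choice of
#' the two rejoining orientations). Draws that would be no-ops or would
#' leave an empty chromosome are redrawn, so `k` counts effective
#' operations and the chromosome count never changes; a translocation
#' requested on a single-chromosome genome is resampled as an inversion.
#'
#' @param g a [genome].
#' @param k number of operations.
#' @param inversion_fraction proportion of inversions (default 0.9).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return the rearranged [genome], with attribute `"ops"`: a data frame
#'   recording every applied operation.
#' @export
apply_rearrangements <- function(g, k, inversion_fraction = 0.9, seed = NULL) {
  stopifnot(inherits(g, "genome"), k >= 0L,
            inversion_fraction >= 0, inversion_fraction <= 1)
  chroms <- g$chromosomes
  nc <- length(chroms)
  ops <- vector("list", k)
  with_seed(seed, {
    for (t in seq_len(k)) {
      inv <- runif(1L) < inversion_fraction || nc < 2L
      if (inv) {
        repeat {
          u <- sample.int(nc, 1L)
          m <- length(chroms[[u]])
          bp <- sort(sample.int(m + 1L, 2L) - 1L)
          if (bp[1L] < bp[2L]) break
        }
        chroms[[u]] <- invert_segment(chroms[[u]], bp[1L], bp[2L])
        ops[[t]] <- data.frame(op = "inversion", chrom1 = u, chrom2 = NA_integer_,
                               bp1 = bp[1L], bp2 = bp[2L], orientation = NA_integer_)
      } else {
        repeat {
          uv <- sample.int(nc, 2L)
          mu <- length(chroms[[uv[1L]]]); mv <- length(chroms[[uv[2L]]])
          i <- sample.int(mu + 1L, 1L) - 1L
          j <- sample.int(mv + 1L, 1L) - 1L
          ori <- sample.int(2L, 1L)
          prod <- translocate_segments(chroms[[uv[1L]]], chroms[[uv[2L]]],
                                       i, j, ori)
          # both-ends breakpoints only swap or flip whole chromosomes
          if (length(prod[[1L]]) > 0L && length(prod[[2L]]) > 0L &&
              !((i == 0L || i == mu) && (j == 0L || j == mv))) break
        }
        chroms[[uv[1L]]] <- prod[[1L]]
        chroms[[uv[2L]]] <- prod[[2L]]
        ops[[t]] <- data.frame(op = "translocation", chrom1 = uv[1L],
                               chrom2 = uv[2L], bp1 = i, bp2 = j,
                               orientation = ori)
      }
    }
  })
  out <- genome(chroms, name = g$name, n = g$n)
  attr(out, "ops") <- if (k > 0L) do.call(rbind, ops) else
    data.frame(op = character(), chrom1 = integer(), chrom2 = integer(),
               bp1 = integer(), bp2 = integer(), orientation = integer())
  out
}

#' Simulate rearrangement evolution along a tree
#'
#' Places a uniform random ancestor at an internal node and evolves it
#' outward along every branch of an unrooted binary topology, applying a
#' fixed number of random rearrangements per branch. All node genomes
#' (leaves and true ancestors) are recorded, so reconstruction accuracy
#' can be measured against the known simulated history.
#'
#' @param n gene count per genome.
#' @param leaves number of leaf genomes (`N >= 3`).
#' @param ops_per_branch rearrangements applied on every branch.
#' @param chromosomes chromosome count of the root ancestor (default 10).
#' @param inversion_fraction proportion of inversions (default 0.9).
#' @param topology `"balanced"` (default) or `"random"`.
#' @param seed integer seed.
#' @return an object of class `"pg_simulation"`: list with `tree` (a
#'   `phylo`), `leaf_genomes` (named list), `true_ancestors` (list indexed
#'   by internal node), `tau_per_branch`, `tau_total` and the
#'   configuration.
#' @export
simulate_tree <- function(n, leaves, ops_per_branch, chromosomes = 10L,
                          inversion_fraction = 0.9,
                          topology = c("balanced", "random"), seed = NULL) {
  topology <- match.arg(topology)
  stopifnot(leaves >= 3L, ops_per_branch >= 0L)
  labels <- paste0("L", seq_len(leaves))
  with_seed(seed, {
    tree <- if (topology == "balanced") balanced_topology(labels)
            else validate_tree(ape::rtree(leaves, rooted = FALSE,
                                          tip.label = labels))
    N <- length(tree$tip.label)
    A <- tree$Nnode
    genomes <- vector("list", N + A)
    # start at the first internal node and evolve outward over the
    # (undirected) tree
    root <- N + 1L
    genomes[[root]] <- random_genome(n, chromosomes, name = "root")
    adj <- lapply(seq_len(N + A), function(i) integer(0))
    for (k in seq_len(nrow(tree$edge))) {
      u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
      adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    }
    queue <- root
    visited <- logical(N + A); visited[root] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (v in adj[[u]]) {
        if (visited[v]) next
        visited[v] <- TRUE
        genomes[[v]] <- apply_rearrangements(genomes[[u]], ops_per_branch,
                                             inversion_fraction)
        queue <- c(queue, v)
      }
    }
    leaf_genomes <- lapply(seq_len(N), function(i) {
      g <- genomes[[i]]; g$name <- tree$tip.label[i]; g
    })
    names(leaf_genomes) <- tree$tip.label
    true_ancestors <- lapply(seq_len(A), function(a) {
      g <- genomes[[N + a]]; g$name <- paste0("M", a); g
    })
    structure(list(
      tree = tree,
      leaf_genomes = leaf_genomes,
      true_ancestors = true_ancestors,
      tau_per_branch = ops_per_branch,
      tau_total = ops_per_branch * nrow(tree$edge),
      config = list(n = n, leaves = leaves, ops_per_branch = ops_per_branch,
                    chromosomes = chromosomes,
                    inversion_fraction = inversion_fraction,
                    topology = topology, seed = seed)
    ), class = "pg_simulation")
  })
}

#' @export
print.pg_simulation <- function(x, ...) {
  cat(sprintf("Simulated tree: %d leaves, n = %d genes, %d chromosome(s), %d ops/branch (tau_total = %d)\n",
              length(x$leaf_genomes), x$config$n, x$config$chromosomes,
              x$tau_per_branch, x$tau_total))
  invisible(x)
}

#' Reconstruction-accuracy experiment
#'
#' For each replicate: simulate a tree, hide the true ancestors,
#' reconstruct them with the greedy solver (optionally followed by
#' iterative median refinement), and compare `d`, the total tree length of
#' the reconstruction, with `tau`, the number of rearrangements inherent
#' in the simulated tree: the total branch length measured with the known
#' simulated ancestors in place. (`tau_ops`, also reported, is the raw
#' count of operations performed; random operations can partially cancel,
#' so `tau <= tau_ops`.) The accuracy measure is the ratio `d/tau` (close
#' to 1 when the reconstruction recovers the simulated history; `NA` when
#' `tau = 0`).
#'
#' @param n,leaves,ops_per_branch,chromosomes,inversion_fraction,topology
#'   simulation settings, see [simulate_tree()].
#' @param scheme priority scheme for reconstruction.
#' @param sweeps refinement sweeps after the single greedy pass (0 = none).
#' @param replicates number of independent replicates (default 10).
#' @param seed integer seed; replicate `r` uses `seed + r - 1`.
#' @return an object of class `"pg_experiment"`: a data frame with one row
#'   per replicate (`replicate`, `d`, `tau`, `ratio`) and attributes
#'   `mean_ratio` and `config`.
#' @export
run_experiment <- function(n, leaves, ops_per_branch, scheme = "refined",
                           sweeps = 0L, replicates = 10L, chromosomes = 10L,
                           inversion_fraction = 0.9, topology = "balanced",
                           seed = 1L) {
  rows <- lapply(seq_len(replicates), function(r) {
    sim <- simulate_tree(n, leaves, ops_per_branch, chromosomes,
                         inversion_fraction, topology, seed = seed + r - 1L)
    fit <- solve_small_phylogeny(sim$tree, sim$leaf_genomes, scheme = scheme)
    if (sweeps > 0L)
      fit <- refine_by_medians(fit, leaf_genomes = sim$leaf_genomes,
                               sweeps = sweeps, scheme = scheme,
                               seed = seed + r - 1L)
    tau <- as.integer(tree_length(sim$tree, sim$leaf_genomes,
                                  sim$true_ancestors))
    data.frame(replicate = r, d = fit$total, tau = tau,
               tau_ops = sim$tau_total,
               ratio = if (tau > 0L) fit$total / tau else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_ratio") <- mean(out$ratio)
  attr(out, "config") <- list(n = n, leaves = leaves,
                              ops_per_branch = ops_per_branch,
                              scheme = scheme, sweeps = sweeps,
                              chromosomes = chromosomes,
                              inversion_fraction = inversion_fraction,
                              topology = topology, seed = seed)
  class(out) <- c("pg_experiment", "data.frame")
  out
}

#' @export
print.pg_experiment <- function(x, ...) {
  print.data.frame(x)
  cat(sprintf("mean d/tau = %.4f over %d replicate(s)\n",
              attr(x, "mean_ratio"), nrow(x)))
  invisible(x)
}

#' @export
plot.pg_experiment <- function(x, ...) {
  plot(x$replicate, x$ratio, xlab = "replicate", ylab = "d / tau",
       pch = 19, ...)
  abline(h = 1, lty = 2)
  abline(h = attr(x, "mean_ratio"), col = 2)
  invisible(x)
}
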