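#' Reconstruct all ancestral genomes on a fixed unrooted binary tree
#'
#' Single-pass greedy solution of the small phylogeny problem: one full
#' set of pathgroups is kept for every internal node, with paths towards
#' not-yet-decided neighbouring ancestors initially missing (replaced by a
#' single vertex). At each step the pathgroup of highest priority among
#' all internal nodes is processed; each red (ancestral) adjacency fixed
#' at one ancestor immediately becomes blue material in the pathgroups of
#' adjacent ancestors. The pass ends when no pathgroup anywhere has a
#' priority; every ancestor is then assembled from its red fragments, each
#' surviving fragment becoming one linear chromosome.
#'
#' @param tree a `phylo` object (see [read_tree()]); leaf labels must name
#'   entries of `leaf_genomes`.
#' @param leaf_genomes named list of [genome]s over one gene universe.
#' @param scheme priority scheme, see [solve_median()].
#' @return an object of class `"pg_phylogeny"`: list with `ancestors`
#'   (list of [genome]s indexed by internal node; ancestor `i` is ape node
#'   `N + i`), `total` (sum of DCJ distances over all `2N - 3` edges),
#'   `per_edge`, `tree`, `scheme`, `stats`.
#' @examples
#' a <- genome(c(1L, 2L, 3L, 4L), name = "A")
#' b <- genome(c(1L, -3L, -2L, 4L), name = "B")
#' tr <- validate_tree(ape::read.tree(text = "(A,B,C);"))
#' solve_small_phylogeny(tr, list(A = a, B = a, C = b))
#' @export
solve_small_phylogeny <- function(tree, leaf_genomes,
                                  scheme = c("refined", "basic", "lookahead2")) {
  scheme <- match.arg(scheme)
  tree <- validate_tree(tree, names(leaf_genomes))
  n <- check_same_universe(leaf_genomes)
  st <- tree_structure(tree)
  leaves_in_order <- leaf_genomes[tree$tip.label]
  sol <- pg_solve_cpp(
    n,
    btype = st$type,
    bpeer = st$peer,
    leaf_partner = lapply(leaves_in_order, adjacency_partner),
    scheme = scheme_code(scheme))
  ancestors <- lapply(seq_len(st$A), function(a)
    assemble_genome(sol$red[a, ], n, name = paste0("M", a)))
  tl <- tree_length(tree, leaf_genomes, ancestors)
  structure(list(
    ancestors = ancestors,
    total = as.integer(tl),
    per_edge = attr(tl, "per_edge"),
    tree = tree,
    scheme = scheme,
    stats = sol[c("steps", "cycles_made", "init_groups", "final_groups",
                  "conservation_ok", "max_secondary", "max_tertiary")]
  ), class = "pg_phylogeny")
}

#' @export
print.pg_phylogeny <- function(x, ...) {
  N <- length(x$tree$tip.label)
  cat(sprintf("Pathgroups small phylogeny (%s scheme): %d leaves, %d ancestors\n",
              x$scheme, N, length(x$ancestors)))
  cat(sprintf("  total tree length: %d over %d edges\n",
              x$total, length(x$per_edge)))
  if (!is.null(x$refinement))
    cat(sprintf("  after %d refinement sweep(s); objective trace: %s\n",
                max(x$refinement$sweep),
                paste(tapply(x$refinement$total_after, x$refinement$sweep, min),
                      collapse = " ")))
  invisible(x)
}

#' @export
summary.pg_phylogeny <- function(object, ...) {
  print(object)
  edges <- object$tree$edge
  N <- length(object$tree$tip.label)
  lab <- function(v) if (v <= N) object$tree$tip.label[v] else paste0("M", v - N)
  for (k in seq_len(nrow(edges)))
    cat(sprintf("  %s -- %s: %d\n", lab(edges[k, 1]), lab(edges[k, 2]),
                object$per_edge[k]))
  invisible(object)
}

#' Random genomes as initial ancestral reconstructions
#'
#' Draws an independent uniform random signed arrangement of the gene
#' universe into a fixed number of linear chromosomes for every internal
#' node of the tree.
#'
#' @param tree a `phylo` object.
#' @param leaf_genomes named list of [genome]s (fixes the gene universe).
#' @param chromosomes chromosome count per random ancestor.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return list of [genome]s indexed by internal node.
#' @export
random_initial_ancestors <- function(tree, leaf_genomes, chromosomes = 10L,
                                     seed = NULL) {
  tree <- validate_tree(tree, names(leaf_genomes))
  n <- check_same_universe(leaf_genomes)
  A <- tree$Nnode
  with_seed(seed, lapply(seq_len(A), function(a)
    random_genome(n, chromosomes, name = paste0("M", a))))
}

#' Iterative median-based improvement of ancestral reconstructions
#'
#' Repeatedly revisits each internal node and re-solves the median of its
#' three neighbours' current genomes; the node's genome is replaced
#' whenever the proposal's local objective (the sum of the node's three
#' incident branch distances) is less than *or equal to* the current one.
#' Accepting equal-cost moves is the simulated-annealing regime that
#' escapes premature capture by local minima; nodes are visited in a
#' seeded random order each sweep. The total objective is non-increasing
#' across accepted moves.
#'
#' @param fit a `"pg_phylogeny"` object from [solve_small_phylogeny()], or
#'   a tree (with `leaf_genomes` and `initial_ancestors` supplied).
#' @param leaf_genomes,initial_ancestors inputs when `fit` is a tree;
#'   ignored otherwise (the fit's own leaves must then be given via
#'   `leaf_genomes`).
#' @param sweeps number of sweeps over all internal nodes (default 50).
#' @param scheme priority scheme for the inner medians.
#' @param seed integer seed driving the node visit order.
#' @return a `"pg_phylogeny"` object with refined `ancestors`, updated
#'   `total`/`per_edge`, and a `refinement` data frame tracing every
#'   proposal: sweep, node, old and new local objective, acceptance, and
#'   the total objective after the proposal.
#' @export
refine_by_medians <- function(fit, leaf_genomes = NULL,
                              initial_ancestors = NULL, sweeps = 50L,
                              scheme = c("refined", "basic", "lookahead2"),
                              seed = NULL) {
  scheme <- match.arg(scheme)
  if (inherits(fit, "pg_phylogeny")) {
    tree <- fit$tree
    if (is.null(leaf_genomes))
      stop_pg("pg_missing_genome", "leaf_genomes must be supplied")
    ancestors <- if (is.null(initial_ancestors)) fit$ancestors else initial_ancestors
  } else {
    tree <- validate_tree(fit, names(leaf_genomes))
    ancestors <- initial_ancestors
    if (is.null(ancestors))
      stop_pg("pg_missing_genome", "initial_ancestors must be supplied")
  }
  if (sweeps < 0L) stop_pg("pg_invalid_arg", "sweeps must be >= 0")
  st <- tree_structure(tree)
  N <- st$N
  neighbour_genome <- function(type, peer) {
    if (type == 0L) leaf_genomes[[tree$tip.label[peer]]] else ancestors[[peer]]
  }
  local_objective <- function(a, g) {
    sum(vapply(1:3, function(k)
      dcj_distance(g, neighbour_genome(st$type[a, k], st$peer[a, k]))$d,
      integer(1)))
  }
  trace <- list()
  # replacing one ancestor changes only its three incident edges, so the
  # total objective can be tracked incrementally from the local objectives
  running_total <- as.integer(tree_length(tree, leaf_genomes, ancestors))
  with_seed(seed, {
    for (sw in seq_len(sweeps)) {
      for (a in sample.int(st$A)) {
        nbrs <- lapply(1:3, function(k)
          neighbour_genome(st$type[a, k], st$peer[a, k]))
        old_obj <- local_objective(a, ancestors[[a]])
        med <- solve_median(nbrs[[1L]], nbrs[[2L]], nbrs[[3L]],
                            scheme = scheme, name = paste0("M", a))
        accepted <- med$total <= old_obj
        if (accepted) {
          ancestors[[a]] <- med$ancestor
          running_total <- running_total + med$total - old_obj
        }
        trace[[length(trace) + 1L]] <- data.frame(
          sweep = sw, node = a, old_local = old_obj, new_local = med$total,
          accepted = accepted, total_after = running_total)
      }
    }
  })
  tl <- tree_length(tree, leaf_genomes, ancestors)
  structure(list(
    ancestors = ancestors,
    total = as.integer(tl),
    per_edge = attr(tl, "per_edge"),
    tree = tree,
    scheme = scheme,
    stats = NULL,
    refinement = if (length(trace)) do.call(rbind, trace) else
      data.frame(sweep = integer(), node = integer(), old_local = integer(),
                 new_local = integer(), accepted = logical(),
                 total_after = integer())
  ), class = "pg_phylogeny")
}
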