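#' Read an unrooted binary phylogeny from a Newick file
#'
#' Parses the tree with \pkg{ape}, suppresses a degree-2 root if present
#' (rooted binary input is silently unrooted), and validates that the
#' result is strictly binary: every internal node of an unrooted tree on
#' `N` leaves has degree 3, giving exactly `N - 2` internal nodes and
#' `2N - 3` edges. Branch lengths are ignored.
#'
#' @param path Newick file path.
#' @param genome_names optional character vector; when given, the leaf
#'   label set must equal it exactly.
#' @return an \pkg{ape} `phylo` object, unrooted and binary.
#' @export
read_tree <- function(path, genome_names = NULL) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e)
                   stop_pg("pg_tree_parse",
                           sprintf("cannot parse Newick in '%s': %s",
                                   path, conditionMessage(e))))
  if (is.null(tr))
    stop_pg("pg_tree_parse", sprintf("cannot parse Newick in '%s'", path))
  validate_tree(tr, genome_names)
}

#' @rdname read_tree
#' @param tree a `phylo` object to validate in place of a file.
#' @export
validate_tree <- function(tree, genome_names = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L)
    stop_pg("pg_tree_invalid", "a tree needs at least 3 leaves")
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  N <- length(tree$tip.label)
  if (tree$Nnode != N - 2L || nrow(tree$edge) != 2L * N - 3L)
    stop_pg("pg_tree_polytomy",
            sprintf("tree is not strictly binary (N=%d leaves needs %d internal nodes, found %d)",
                    N, N - 2L, tree$Nnode))
  deg <- tabulate(c(tree$edge), nbins = N + tree$Nnode)
  if (any(deg[(N + 1L):(N + tree$Nnode)] != 3L))
    stop_pg("pg_tree_polytomy", "internal node of degree != 3")
  if (anyDuplicated(tree$tip.label))
    stop_pg("pg_tree_invalid", "duplicate leaf labels")
  if (!is.null(genome_names)) {
    missing_g <- setdiff(tree$tip.label, genome_names)
    missing_t <- setdiff(genome_names, tree$tip.label)
    if (length(missing_g) || length(missing_t))
      stop_pg("pg_tree_name_mismatch",
              sprintf("leaf/genome name mismatch (tree-only: %s; genome-only: %s)",
                      paste(missing_g, collapse = ","),
                      paste(missing_t, collapse = ",")))
  }
  tree
}

# Adjacency view of an unrooted binary phylo: for each internal node
# (ancestor) its three neighbours, each either a leaf or another ancestor.
# Returns list with: A (# ancestors), type (A x 3; 0 leaf, 1 ancestor),
# peer (A x 3; leaf index or ancestor index, 1-based), and for every edge
# of the tree the (node, node) pair in ape numbering.
tree_structure <- function(tree) {
  N <- length(tree$tip.label)
  A <- tree$Nnode
  type <- matrix(NA_integer_, A, 3L)
  peer <- matrix(NA_integer_, A, 3L)
  slot <- integer(A)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]
    for (side in 1:2) {
      a <- if (side == 1L) u else v
      b <- if (side == 1L) v else u
      if (a > N) {
        ai <- a - N
        slot[ai] <- slot[ai] + 1L
        type[ai, slot[ai]] <- if (b <= N) 0L else 1L
        peer[ai, slot[ai]] <- if (b <= N) b else b - N
      }
    }
  }
  stopifnot(all(slot == 3L))
  list(N = N, A = A, type = type, peer = peer, edge = tree$edge)
}

# Balanced-as-possible unrooted binary topology on N >= 3 labelled leaves.
balanced_topology <- function(labels) {
  N <- length(labels)
  stopifnot(N >= 3L)
  build <- function(lab) {
    n <- length(lab)
    if (n == 1L) return(lab)
    k <- ceiling(n / 2)
    sprintf("(%s,%s)", build(lab[seq_len(k)]), build(lab[(k + 1L):n]))
  }
  k <- ceiling(N / 2)
  txt <- sprintf("(%s,%s);", build(labels[seq_len(k)]), build(labels[(k + 1L):N]))
  validate_tree(ape::read.tree(text = txt))
}
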