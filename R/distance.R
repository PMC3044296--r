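# Vertex encoding: gene g has a tail extremity 2g-1 and a head extremity 2g.
# A gene +g contributes its extremities in order (tail, head); -g in order
# (head, tail). Successive extremities across gene boundaries form
# adjacencies; the first and last extremity of a chromosome are telomeres.

vertex_tail <- function(g) 2L * g - 1L
vertex_head <- function(g) 2L * g

# Partner vector: for each extremity 1..2n, the extremity adjacent to it in
# this genome, or 0 for a telomere.
adjacency_partner <- function(g) {
  partner <- integer(2L * g$n)
  for (ch in g$chromosomes) {
    first <- ifelse(ch > 0L, vertex_tail(abs(ch)), vertex_head(abs(ch)))
    last <- ifelse(ch > 0L, vertex_head(abs(ch)), vertex_tail(abs(ch)))
    m <- length(ch)
    if (m > 1L) {
      partner[last[-m]] <- first[-1L]
      partner[first[-1L]] <- last[-m]
    }
  }
  partner
}

#' Adjacency set of a genome
#'
#' Decomposes a genome into its adjacencies (unordered pairs of gene
#' extremities that are neighbours on a chromosome) and its telomeres
#' (extremities at chromosome ends). A genome of `n` genes on `c`
#' chromosomes has exactly `n - c` adjacencies and `2c` telomeres.
#'
#' Extremities are encoded as integers: gene `g` has tail `2g-1` and head
#' `2g`.
#'
#' @param g a [genome].
#' @return an object of class `"adjacency_set"`: list with `adjacencies`
#'   (two-column integer matrix), `telomeres` (integer vector) and
#'   `partner` (length-`2n` partner vector, 0 marking a telomere).
#' @export
build_adjacencies <- function(g) {
  partner <- adjacency_partner(g)
  v <- seq_along(partner)
  sel <- partner > 0L & v < partner
  structure(list(
    adjacencies = cbind(v[sel], partner[sel], deparse.level = 0),
    telomeres = v[partner == 0L],
    partner = partner
  ), class = "adjacency_set")
}

#' DCJ distance between two genomes
#'
#' The minimum number of double-cut-and-join operations (subsuming
#' inversion, reciprocal translocation, fusion, fission) transforming one
#' genome into the other, computed from the breakpoint graph: one genome's
#' adjacencies are blue edges, the other's red; telomeres are capped so
#' every vertex has one blue and one red edge, and the graph decomposes
#' into kappa alternating cycles. With n-prime blue edges after capping,
#' `d = n' - kappa`.
#'
#' Capping rules: each telomere of the first genome is joined by a blue
#' edge to a cap, each telomere of the second by a red edge to a cap; a
#' path whose two ends are first-genome caps is closed by a red edge, one
#' with two second-genome caps by a blue edge (which counts towards
#' n-prime), and a path with one cap of each colour has the caps collapsed
#' to a single vertex. Every resulting component is an alternating cycle.
#'
#' @param g1,g2 [genome] objects over the same gene universe.
#' @return an object of class `"dcj_distance"`: list with integer elements
#'   `d`, `n_prime`, `kappa`.
#' @examples
#' a <- genome(c(1L, 2L, 3L, 4L))
#' b <- genome(c(1L, -3L, -2L, 4L))
#' dcj_distance(a, b)$d  # one inversion
#' @export
dcj_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "genome"), inherits(g2, "genome"))
  if (g1$n != g2$n)
    stop_pg("pg_universe_mismatch", "genomes are over different gene universes")
  n <- g1$n
  blue <- adjacency_partner(g1)
  red <- adjacency_partner(g2)
  nv <- 2L * n
  visited <- logical(nv)
  kappa <- 0L
  extra_blue <- 0L
  # path components: start from every vertex missing at least one colour
  for (v in seq_len(nv)) {
    if (visited[v] || (blue[v] > 0L && red[v] > 0L)) next
    visited[v] <- TRUE
    if (blue[v] == 0L && red[v] == 0L) {
      # isolated vertex: one cap of each colour, collapsed -> one cycle
      kappa <- kappa + 1L
      next
    }
    # end type at v: missing blue -> cap of genome 1; missing red -> genome 2
    end1_g2cap <- (red[v] == 0L)
    need <- if (blue[v] == 0L) "red" else "blue"
    cur <- v
    repeat {
      nxt <- if (need == "red") red[cur] else blue[cur]
      if (nxt == 0L) break
      cur <- nxt
      visited[cur] <- TRUE
      need <- if (need == "red") "blue" else "red"
    }
    end2_g2cap <- (need == "red")  # path ends needing a red edge: G2 telomere
    kappa <- kappa + 1L
    if (end1_g2cap && end2_g2cap) extra_blue <- extra_blue + 1L
  }
  # remaining components are closed alternating cycles
  for (v in seq_len(nv)) {
    if (visited[v]) next
    kappa <- kappa + 1L
    cur <- v
    col <- "blue"
    repeat {
      visited[cur] <- TRUE
      cur <- if (col == "blue") blue[cur] else red[cur]
      col <- if (col == "blue") "red" else "blue"
      if (cur == v && col == "blue") break
    }
  }
  c1 <- length(g1$chromosomes)
  n_prime <- n + c1 + extra_blue
  structure(list(d = n_prime - kappa, n_prime = n_prime, kappa = kappa),
            class = "dcj_distance")
}

#' @export
print.dcj_distance <- function(x, ...) {
  cat(sprintf("DCJ distance d = %d  (n' = %d blue edges, kappa = %d cycles)\n",
              x$d, x$n_prime, x$kappa))
  invisible(x)
}

#' Total DCJ length of a labelled tree
#'
#' Sum of DCJ distances over all edges of an unrooted binary tree whose
#' leaves carry given genomes and whose internal nodes carry (reconstructed
#' or simulated) ancestral genomes.
#'
#' @param tree a `phylo` object (see [read_tree()]).
#' @param leaf_genomes named list of [genome]s; names must cover
#'   `tree$tip.label`.
#' @param ancestor_genomes list of [genome]s indexed by internal node
#'   (ancestor `i` is ape node `N + i`).
#' @return integer total; per-edge distances in attribute `"per_edge"`.
#' @export
tree_length <- function(tree, leaf_genomes, ancestor_genomes) {
  N <- length(tree$tip.label)
  lookup <- function(node) {
    if (node <= N) {
      g <- leaf_genomes[[tree$tip.label[node]]]
      if (is.null(g))
        stop_pg("pg_missing_genome",
                sprintf("no genome for leaf '%s'", tree$tip.label[node]))
      g
    } else {
      g <- ancestor_genomes[[node - N]]
      if (is.null(g))
        stop_pg("pg_missing_genome",
                sprintf("no genome for ancestor %d", node - N))
      g
    }
  }
  per_edge <- vapply(seq_len(nrow(tree$edge)), function(k) {
    dcj_distance(lookup(tree$edge[k, 1L]), lookup(tree$edge[k, 2L]))$d
  }, integer(1))
  structure(sum(per_edge), per_edge = per_edge)
}
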