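# Reassemble a genome from the engine's red-edge matching.  `red` is a
# length-2n vector giving each extremity's chosen red partner (0 = none,
# i.e. an ancestral telomere).  Every maximal run of genes connected by
# red edges becomes one linear chromosome; the engine never produces
# circular fragments.
assemble_genome <- function(red, n, name = NULL) {
  seen <- logical(n)
  chroms <- list()
  other_end <- function(v) if (v %% 2L == 1L) v + 1L else v - 1L
  for (start in seq_len(2L * n)) {
    if (red[start] != 0L) next
    g0 <- (start + 1L) %/% 2L
    if (seen[g0]) next
    genes <- integer(0)
    v <- start
    repeat {
      g <- (v + 1L) %/% 2L
      if (seen[g]) stop_pg("pg_internal", "circular fragment in reconstruction")
      seen[g] <- TRUE
      genes <- c(genes, if (v %% 2L == 1L) g else -g)
      w <- other_end(v)
      nxt <- red[w]
      if (nxt == 0L) break
      v <- nxt
    }
    chroms[[length(chroms) + 1L]] <- genes
  }
  if (!all(seen)) stop_pg("pg_internal", "reconstruction did not cover all genes")
  genome(chroms, name = name, n = n)
}

check_same_universe <- function(genomes) {
  ns <- vapply(genomes, n_genes, integer(1))
  if (length(unique(ns)) != 1L)
    stop_pg("pg_universe_mismatch", "genomes are over different gene universes")
  ns[[1L]]
}

#' Heuristic gene-order median of three genomes
#'
#' Finds a genome approximately minimizing the sum of DCJ distances to the
#' three inputs, by greedy cycle maximization over the pathgroups data
#' structure: each non-cap ancestral vertex anchors a pathgroup holding one
#' alternating path per input genome, and at every step a red (ancestral)
#' adjacency is added in the pathgroup of highest priority, creating at
#' least one breakpoint-graph cycle and never a circular chromosome.
#' Worst-case running time is linear in the number of genes.
#'
#' @param g1,g2,g3 [genome] objects over the same gene universe.
#' @param scheme priority scheme: `"basic"` (7 levels: cycles creatable
#'   now, then cycles creatable next step), `"refined"` (55 levels: adds
#'   the net change in potential cycles over all affected pathgroups) or
#'   `"lookahead2"` (165 levels: adds the best cycle count two steps
#'   ahead).
#' @param name label for the reconstructed ancestor.
#' @return an object of class `"pg_median"`: list with `ancestor` (a
#'   [genome]), `distances` (DCJ distance to each input), `total`, `scheme`
#'   and `stats` (step counts and instrumentation from the greedy run).
#' @examples
#' a <- genome(c(1L, 2L, 3L, 4L), name = "A")
#' b <- genome(c(1L, -3L, -2L, 4L), name = "B")
#' solve_median(a, a, b)
#' @export
solve_median <- function(g1, g2, g3, scheme = c("refined", "basic", "lookahead2"),
                         name = "M") {
  scheme <- match.arg(scheme)
  genomes <- list(g1, g2, g3)
  n <- check_same_universe(genomes)
  sol <- pg_solve_cpp(
    n,
    btype = matrix(0L, 1L, 3L),
    bpeer = matrix(1:3, 1L, 3L),
    leaf_partner = lapply(genomes, adjacency_partner),
    scheme = scheme_code(scheme))
  ancestor <- assemble_genome(sol$red[1L, ], n, name = name)
  distances <- vapply(genomes, function(g) dcj_distance(ancestor, g)$d, integer(1))
  structure(list(
    ancestor = ancestor,
    distances = distances,
    total = sum(distances),
    scheme = scheme,
    stats = sol[c("steps", "cycles_made", "init_groups", "final_groups",
                  "conservation_ok", "max_secondary", "max_tertiary")]
  ), class = "pg_median")
}

#' @export
print.pg_median <- function(x, ...) {
  cat(sprintf("Pathgroups median (%s scheme)\n", x$scheme))
  cat(sprintf("  branch distances: %s\n", paste(x$distances, collapse = " ")))
  cat(sprintf("  total: %d\n", x$total))
  cat(sprintf("  ancestor: %d genes on %d chromosome(s)\n",
              x$ancestor$n, length(x$ancestor$chromosomes)))
  invisible(x)
}

#' @export
summary.pg_median <- function(object, ...) {
  print(object)
  s <- object$stats
  cat(sprintf("  greedy steps: %d, cycles made: %d\n", s$steps, s$cycles_made))
  cat(sprintf("  pathgroups: %d -> %d (conservation %s)\n",
              s$init_groups, s$final_groups,
              if (s$conservation_ok) "ok" else "VIOLATED"))
  cat(sprintf("  max secondary/tertiary pathgroups per step: %d / %d\n",
              s$max_secondary, s$max_tertiary))
  invisible(object)
}

#' @export
coef.pg_median <- function(object, ...) object$distances
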