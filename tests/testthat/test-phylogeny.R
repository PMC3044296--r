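sim_leaves <- function(n, N, ops, chroms = 3L, seed = 1L) {
  simulate_tree(n, N, ops, chromosomes = chroms, seed = seed)
}

test_that("small phylogeny on three leaves reduces exactly to the median", {
  for (seed in c(2L, 9L, 27L)) {
    sim <- sim_leaves(60L, 3L, 6L, seed = seed)
    for (sch in c("basic", "refined", "lookahead2")) {
      fit <- solve_small_phylogeny(sim$tree, sim$leaf_genomes, scheme = sch)
      med <- solve_median(sim$leaf_genomes[[sim$tree$tip.label[1L]]],
                          sim$leaf_genomes[[sim$tree$tip.label[2L]]],
                          sim$leaf_genomes[[sim$tree$tip.label[3L]]],
                          scheme = sch)
      expect_equal(fit$total, med$total)
      expect_identical(fit$ancestors[[1L]]$chromosomes,
                       med$ancestor$chromosomes)
    }
  }
})

test_that("identical leaves reconstruct to identical ancestors at total 0", {
  g <- random_genome(40L, 2L, seed = 4L)
  leaves <- setNames(lapply(1:5, function(i) { g$name <- paste0("L", i); g }),
                     paste0("L", 1:5))
  tr <- validate_tree(ape::read.tree(text = "((L1,L2),(L3,L4),L5);"))
  fit <- solve_small_phylogeny(tr, leaves)
  expect_equal(fit$total, 0L)
  for (anc in fit$ancestors) expect_true(genome_equal(anc, g))
})

test_that("reconstruction total sits between the leaf-distance bound and the true scenario cost", {
  for (seed in c(5L, 15L)) {
    sim <- sim_leaves(50L, 4L, 3L, seed = seed)
    fit <- solve_small_phylogeny(sim$tree, sim$leaf_genomes, scheme = "refined")
    # any tree connecting the leaves is at least as long as the widest
    # leaf pair distance
    labs <- sim$tree$tip.label
    pairmax <- max(vapply(utils::combn(length(labs), 2L, simplify = FALSE),
                          function(ij) dcj_distance(sim$leaf_genomes[[labs[ij[1L]]]],
                                                    sim$leaf_genomes[[labs[ij[2L]]]])$d,
                          integer(1)))
    expect_gte(fit$total, pairmax)
    # at this low rate the greedy should not exceed the simulated op count
    expect_lte(fit$total, sim$tau_total)
    # reported per-edge distances match a recomputation from the output
    tl <- tree_length(sim$tree, sim$leaf_genomes, fit$ancestors)
    expect_equal(fit$total, as.integer(tl))
    expect_equal(fit$per_edge, attr(tl, "per_edge"))
  }
})

test_that("random initial ancestors are seeded, valid and distinct across seeds", {
  sim <- sim_leaves(30L, 6L, 2L, seed = 3L)
  a1 <- random_initial_ancestors(sim$tree, sim$leaf_genomes, chromosomes = 2L,
                                 seed = 42L)
  a2 <- random_initial_ancestors(sim$tree, sim$leaf_genomes, chromosomes = 2L,
                                 seed = 42L)
  a3 <- random_initial_ancestors(sim$tree, sim$leaf_genomes, chromosomes = 2L,
                                 seed = 43L)
  expect_length(a1, sim$tree$Nnode)
  expect_identical(lapply(a1, `[[`, "chromosomes"),
                   lapply(a2, `[[`, "chromosomes"))
  expect_false(identical(lapply(a1, `[[`, "chromosomes"),
                         lapply(a3, `[[`, "chromosomes")))
  for (g in a1) {
    expect_s3_class(g, "genome")
    expect_length(g$chromosomes, 2L)
  }
})

test_that("median refinement never increases the objective and accepts equal-cost moves", {
  sim <- sim_leaves(60L, 6L, 8L, seed = 21L)
  fit <- solve_small_phylogeny(sim$tree, sim$leaf_genomes, scheme = "basic")
  ref <- refine_by_medians(fit, leaf_genomes = sim$leaf_genomes, sweeps = 5L,
                           scheme = "refined", seed = 7L)
  expect_lte(ref$total, fit$total)
  expect_true(all(diff(ref$refinement$total_after) <= 0L))
  expect_true(all(ref$refinement$new_local[ref$refinement$accepted] <=
                  ref$refinement$old_local[ref$refinement$accepted]))
  # at a fixed point every proposal is accepted with equal cost
  sim3 <- sim_leaves(40L, 3L, 4L, seed = 2L)
  f3 <- solve_small_phylogeny(sim3$tree, sim3$leaf_genomes)
  r3 <- refine_by_medians(f3, leaf_genomes = sim3$leaf_genomes, sweeps = 2L,
                          seed = 1L)
  expect_equal(r3$total, f3$total)
})

test_that("refinement from random ancestors strictly improves a non-degenerate start", {
  sim <- sim_leaves(50L, 5L, 5L, seed = 33L)
  anc <- random_initial_ancestors(sim$tree, sim$leaf_genomes, chromosomes = 3L,
                                  seed = 8L)
  before <- as.integer(tree_length(sim$tree, sim$leaf_genomes, anc))
  ref <- refine_by_medians(sim$tree, leaf_genomes = sim$leaf_genomes,
                           initial_ancestors = anc, sweeps = 3L, seed = 9L)
  expect_lt(ref$total, before)
  expect_error(refine_by_medians(sim$tree, leaf_genomes = sim$leaf_genomes,
                                 initial_ancestors = anc, sweeps = -1L),
               class = "pg_invalid_arg")
})
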