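test_that("adjacencies and telomeres follow the extremity model", {
  # chromosome [i, j, -k] = [1, 2, -3]: adjacencies {1h,2t} and {2h,3h},
  # telomeres 1t and 3t
  adj <- build_adjacencies(genome(c(1L, 2L, -3L)))
  expect_equal(adj$adjacencies, cbind(c(2L, 4L), c(3L, 6L)))
  expect_equal(adj$telomeres, c(1L, 5L))

  # single-gene chromosome: no adjacencies, both extremities telomeres
  adj1 <- build_adjacencies(genome(list(5L, c(1L, 2L, 3L, 4L))))
  expect_equal(nrow(adj1$adjacencies), 3L)
  expect_true(all(c(9L, 10L) %in% adj1$telomeres))
  expect_length(adj1$telomeres, 4L)
})

test_that("a genome of n genes in c chromosomes has n-c adjacencies and 2c telomeres", {
  set.seed(11)
  for (rep in 1:15) {
    n <- sample(5:40, 1L)
    cc <- sample.int(min(n, 6L), 1L)
    adj <- build_adjacencies(random_genome(n, cc))
    expect_equal(nrow(adj$adjacencies), n - cc)
    expect_length(adj$telomeres, 2L * cc)
  }
})

test_that("DCJ distance matches hand-checked cases", {
  a <- genome(c(1L, 2L, 3L, 4L))
  expect_equal(dcj_distance(a, a)$d, 0L)
  expect_equal(dcj_distance(a, genome(c(1L, -3L, -2L, 4L)))$d, 1L)  # one inversion
  # fission / fusion
  expect_equal(dcj_distance(genome(list(1:2)), genome(list(1L, 2L)))$d, 1L)
  # d = 0 iff equal under flip/reorder equivalence, any chromosome count
  g <- genome(list(c(2L, -4L), c(1L, 3L)))
  expect_equal(dcj_distance(g, genome(list(c(-3L, -1L), c(4L, -2L))))$d, 0L)
})

test_that("DCJ distance equals the BFS oracle on the full genome space (n <= 3)", {
  for (n in 2:3) {
    space <- all_linear_genomes(n)
    for (src in space) {
      dist <- bfs_distances(src, n)
      gs <- genome(src, n = n)
      for (key in names(space)) {
        expect_equal(dcj_distance(gs, genome(space[[key]], n = n))$d,
                     dist[[key]])
      }
    }
  }
})

test_that("DCJ distance equals the BFS oracle from every identity structure (n = 4)", {
  n <- 4L
  space <- all_linear_genomes(n)
  # every pair relabels to (identity structure, something), so these
  # sources cover the whole pair space up to renaming
  srcs <- list(list(1:4), list(1L, 2:4), list(1:2, 3:4), list(1:3, 4L),
               list(1L, 2L, 3:4), list(1L, 2:3, 4L), list(1:2, 3L, 4L),
               list(1L, 2L, 3L, 4L))
  for (src in srcs) {
    dist <- bfs_distances(src, n)
    gs <- genome(src, n = n)
    for (key in names(space))
      expect_equal(dcj_distance(gs, genome(space[[key]], n = n))$d,
                   dist[[key]])
  }
})

test_that("DCJ distance is invariant under relabelling of the gene universe", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(4:8, 1L)
    g1 <- genome(rand_chroms(n, 3L), n = n)
    g2 <- genome(rand_chroms(n, 3L), n = n)
    # random signed relabelling map
    map <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
    relab <- function(g) genome(lapply(g$chromosomes, function(ch)
      as.integer(sign(ch)) * map[abs(ch)]), n = n)
    expect_equal(dcj_distance(relab(g1), relab(g2))$d, dcj_distance(g1, g2)$d)
  }
})

test_that("DCJ distance satisfies the metric axioms on random instances (n <= 6)", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:6, 1L)
    g1 <- genome(rand_chroms(n, 3L), n = n)
    g2 <- genome(rand_chroms(n, 3L), n = n)
    g3 <- genome(rand_chroms(n, 3L), n = n)
    d12 <- dcj_distance(g1, g2)$d
    d21 <- dcj_distance(g2, g1)$d
    d13 <- dcj_distance(g1, g3)$d
    d23 <- dcj_distance(g2, g3)$d
    expect_gte(d12, 0L)
    expect_lte(d12, n)                 # d never exceeds n
    expect_equal(d12, d21)             # symmetry
    expect_equal(d12 == 0L, genome_equal(g1, g2))
    expect_lte(d13, d12 + d23)         # triangle inequality
  }
})

test_that("universe mismatch is rejected", {
  expect_error(dcj_distance(genome(1:3), genome(1:4)),
               class = "pg_universe_mismatch")
})

test_that("tree length sums DCJ distances over all edges", {
  a <- genome(c(1L, 2L, 3L, 4L), name = "A")
  b <- genome(c(1L, -3L, -2L, 4L), name = "B")
  cg <- genome(list(c(2L, 1L), c(3L, 4L)), name = "C")
  tr <- validate_tree(ape::read.tree(text = "(A,B,C);"))
  leaves <- list(A = a, B = b, C = cg)
  # all nodes identical
  expect_equal(as.integer(tree_length(tr, list(A = a, B = a, C = a), list(a))), 0L)
  # star tree with centre equal to A
  expect_equal(as.integer(tree_length(tr, leaves, list(a))),
               dcj_distance(a, b)$d + dcj_distance(a, cg)$d)
  expect_error(tree_length(tr, leaves[1:2], list(a)),
               class = "pg_missing_genome")
})
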