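# direct access to the engine for structural checks
pg_solve_raw <- function(genomes, scheme = "refined", init_levels = FALSE) {
  n <- genomes[[1L]]$n
  pathgroups:::pg_solve_cpp(
    n, btype = matrix(0L, 1L, 3L), bpeer = matrix(1:3, 1L, 3L),
    leaf_partner = lapply(genomes, pathgroups:::adjacency_partner),
    scheme = pathgroups:::scheme_code(scheme), init_levels = init_levels)
}

level_key <- function(scheme, cycles, best_next = 1L, net_delta = 0L,
                      second_step = 1L) {
  pathgroups:::pg_level_of_cpp(pathgroups:::scheme_code(scheme),
                               cycles, best_next, net_delta, second_step)
}

test_that("median of three identical genomes is that genome at distance 0", {
  g <- genome(list(c(1L, -2L, 3L), c(4L, 5L)), name = "G")
  for (sch in c("basic", "refined", "lookahead2")) {
    m <- solve_median(g, g, g, scheme = sch)
    expect_true(genome_equal(m$ancestor, g))
    expect_equal(m$total, 0L)
    expect_equal(m$distances, c(0L, 0L, 0L))
  }
})

test_that("initial pathgroups of identical genomes all sit in the top bucket", {
  g <- genome(c(1L, 2L, 3L))
  sol <- pg_solve_raw(list(g, g, g), "refined", init_levels = TRUE)
  lev <- sol$init_levels[1L, ]
  # interior extremities (1h,2t,2h,3t) can complete three cycles at once;
  # the telomere extremities (1t, 3h) have only cap-bounded paths and no
  # priority at all
  expect_equal(lev, c(-1L, 0L, 0L, 0L, 0L, -1L))
})

test_that("initial priorities of a hand-enumerated one-inversion instance", {
  g1 <- genome(c(1L, 2L, 3L))
  g3 <- genome(c(1L, -2L, 3L))
  sol <- pg_solve_raw(list(g1, g1, g3), "refined", init_levels = TRUE)
  lev <- sol$init_levels[1L, ]
  # group at 1h (vertex 2): paths (2,3), (2,3), (2,4): completing 2-3
  # closes two cycles and sets up a three-cycle group at 2h/3t, raising
  # the potential of both affected groups by one -> key (2, 3, +2)
  expect_equal(lev[2L], level_key("refined", 2L, 3L, 2L))
  expect_equal(lev[5L], level_key("refined", 2L, 3L, 2L))
  # telomere-side groups have no priority
  expect_equal(lev[1L], -1L)
  expect_equal(lev[6L], -1L)
  # the solved median recovers a source genome at total d(g1,g3)
  m <- solve_median(g1, g1, g3)
  expect_equal(m$total, dcj_distance(g1, g3)$d)
})

test_that("single-gene genomes admit no red edges and return the gene intact", {
  g <- genome(1L)
  m <- solve_median(g, g, g)
  expect_equal(m$stats$steps, 0)
  expect_true(genome_equal(m$ancestor, g))
  expect_equal(m$total, 0L)
})

test_that("pathgroup count drops by exactly two per greedy step", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(c(20L, 50L, 120L), 1L)
    g0 <- random_genome(n, sample(1:4, 1L))
    gs <- lapply(1:3, function(j) apply_rearrangements(g0, n %/% 5))
    m <- solve_median(gs[[1L]], gs[[2L]], gs[[3L]],
                      scheme = sample(c("basic", "refined", "lookahead2"), 1L))
    expect_true(m$stats$conservation_ok)
    expect_equal(m$stats$final_groups,
                 m$stats$init_groups - 2 * m$stats$steps)
    # output validity: exactly the gene universe, linear chromosomes
    expect_s3_class(m$ancestor, "genome")
    expect_equal(m$ancestor$n, n)
  }
})

test_that("secondary and tertiary pathgroups stay within the structural bounds", {
  set.seed(13)
  for (rep in 1:6) {
    g0 <- random_genome(200L, 4L)
    gs <- lapply(1:3, function(j) apply_rearrangements(g0, 40L))
    m <- solve_median(gs[[1L]], gs[[2L]], gs[[3L]], scheme = "refined")
    expect_lte(m$stats$max_secondary, 4)
    expect_lte(m$stats$max_tertiary, 8)
  }
})

test_that("greedy median total is bounded below by the exhaustive optimum", {
  set.seed(17)
  spaces <- list()
  for (rep in 1:12) {
    n <- if (rep %% 2L) 3L else 4L
    key <- as.character(n)
    if (is.null(spaces[[key]])) spaces[[key]] <- all_linear_genomes(n)
    gs <- lapply(1:3, function(j) genome(rand_chroms(n, 2L), n = n))
    opt <- exhaustive_median_total(gs[[1L]], gs[[2L]], gs[[3L]],
                                   spaces[[key]], n)
    for (sch in c("basic", "refined", "lookahead2")) {
      m <- solve_median(gs[[1L]], gs[[2L]], gs[[3L]], scheme = sch)
      expect_gte(m$total, opt)
    }
  }
})

test_that("when two inputs coincide the median is exact", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(3:6, 1L)
    g1 <- genome(rand_chroms(n, 2L), n = n)
    g3 <- genome(rand_chroms(n, 2L), n = n)
    m <- solve_median(g1, g1, g3)
    expect_equal(m$total, dcj_distance(g1, g3)$d)
    expect_true(genome_equal(m$ancestor, g1))
  }
})

test_that("solver is deterministic", {
  g0 <- random_genome(80L, 3L, seed = 5L)
  gs <- lapply(1:3, function(j) apply_rearrangements(g0, 15L, seed = j))
  for (sch in c("basic", "refined", "lookahead2")) {
    m1 <- solve_median(gs[[1L]], gs[[2L]], gs[[3L]], scheme = sch)
    m2 <- solve_median(gs[[1L]], gs[[2L]], gs[[3L]], scheme = sch)
    expect_identical(m1$ancestor$chromosomes, m2$ancestor$chromosomes)
    expect_identical(m1$total, m2$total)
  }
})

test_that("solve time grows far slower than quadratically in genome size", {
  elapsed <- sapply(c(1000L, 4000L), function(n) {
    g0 <- random_genome(n, 10L, seed = 1L)
    gs <- lapply(1:3, function(j)
      apply_rearrangements(g0, n %/% 10L, seed = j))
    system.time(for (i in 1:3)
      solve_median(gs[[1L]], gs[[2L]], gs[[3L]], scheme = "refined")
    )[["elapsed"]]
  })
  # a quadratic engine would take ~16x longer at 4x the genes; allow wide
  # slack for machine noise around the expected ~4x
  expect_lt(elapsed[2L], 12 * elapsed[1L] + 1)
})
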