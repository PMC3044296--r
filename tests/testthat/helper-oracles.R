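# Independent oracles for small genomes, used to validate the DCJ distance
# and the greedy median against brute force.
#
# The BFS oracle works on adjacency sets represented as partner vectors
# over extremities 1..2n (partner[v] = extremity adjacent to v, 0 = v is a
# telomere).  A partner vector identifies a genome exactly (it is
# invariant under chromosome order and whole-chromosome flips), and it
# represents circular chromosomes just as well as linear ones — the DCJ
# metric reaches some linear genomes only through circular intermediate
# states, so the search space must include them even though start and goal
# are always linear.

# canonical chromosome list (linear genomes only)
chrom_canon <- function(chroms) {
  chroms <- lapply(chroms, function(ch) {
    m <- length(ch)
    if (m == 1L) abs(ch)
    else if (abs(ch[1L]) > abs(ch[m])) -rev(ch)
    else ch
  })
  ord <- order(vapply(chroms, function(ch) abs(ch[1L]), integer(1)))
  chroms[ord]
}

# partner vector of a linear chromosome list
chroms_partner <- function(chroms, n) {
  partner <- integer(2L * n)
  for (ch in chroms) {
    ext <- unlist(lapply(ch, function(g)
      if (g > 0L) c(2L * g - 1L, 2L * g) else c(2L * abs(g), 2L * abs(g) - 1L)))
    m <- length(ext)
    if (m > 2L)
      for (i in seq(2L, m - 1L, by = 2L)) {
        partner[ext[i]] <- ext[i + 1L]
        partner[ext[i + 1L]] <- ext[i]
      }
  }
  partner
}

partner_key <- function(p) paste(p, collapse = ",")

# all distinct linear genomes over genes 1..n (any chromosome count);
# named list: partner key -> canonical chromosome list
all_linear_genomes <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  out <- new.env(parent = emptyenv())
  for (p in perms(seq_len(n))) {
    for (s in seq_len(nrow(signs))) {
      signed <- p * signs[s, ]
      for (cutmask in seq_len(2^(n - 1)) - 1L) {
        cuts <- which(bitwAnd(cutmask, 2^(seq_len(n - 1) - 1L)) > 0L)
        bounds <- c(0L, cuts, n)
        chroms <- lapply(seq_len(length(bounds) - 1L), function(i)
          signed[(bounds[i] + 1L):bounds[i + 1L]])
        key <- partner_key(chroms_partner(chroms, n))
        if (is.null(out[[key]])) out[[key]] <- chrom_canon(chroms)
      }
    }
  }
  as.list(out)
}

# every adjacency set reachable by one DCJ operation (circular products
# included: they are legitimate intermediate states of the metric)
dcj_neighbour_keys <- function(partner) {
  adjs <- lapply(which(seq_along(partner) < partner), function(v) c(v, partner[v]))
  tels <- which(partner == 0L)
  out <- character(0)
  swap <- function(p, a, b, cc, dd) {
    # replace {a,b},{cc,dd} by {a,cc},{b,dd}; 0 means "no partner"
    ends <- c(a, b, cc, dd); p[ends[ends > 0L]] <- 0L
    if (a > 0L && cc > 0L) { p[a] <- cc; p[cc] <- a }
    if (b > 0L && dd > 0L) { p[b] <- dd; p[dd] <- b }
    p
  }
  na <- length(adjs)
  if (na >= 2L)
    for (i in seq_len(na - 1L)) for (j in (i + 1L):na) {
      a <- adjs[[i]][1L]; b <- adjs[[i]][2L]
      cc <- adjs[[j]][1L]; dd <- adjs[[j]][2L]
      out <- c(out, partner_key(swap(partner, a, b, cc, dd)),
               partner_key(swap(partner, a, b, dd, cc)))
    }
  for (i in seq_along(adjs)) {
    a <- adjs[[i]][1L]; b <- adjs[[i]][2L]
    for (t in tels)
      out <- c(out, partner_key(swap(partner, a, b, t, 0L)),
               partner_key(swap(partner, b, a, t, 0L)))
    p <- partner; p[a] <- 0L; p[b] <- 0L      # cut into two telomeres
    out <- c(out, partner_key(p))
  }
  nt <- length(tels)
  if (nt >= 2L)
    for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {   # join two telomeres
      p <- partner; p[tels[i]] <- tels[j]; p[tels[j]] <- tels[i]
      out <- c(out, partner_key(p))
    }
  unique(out)
}

key_to_partner <- function(key) as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])

# BFS distances (number of DCJ operations) from one linear genome to every
# reachable adjacency set; returns environment key -> distance
bfs_distances <- function(chroms, n) {
  dist <- new.env(parent = emptyenv())
  key0 <- partner_key(chroms_partner(chroms, n))
  dist[[key0]] <- 0L
  frontier <- key0
  level <- 0L
  while (length(frontier)) {
    level <- level + 1L
    nxt <- character(0)
    for (key in frontier) {
      for (nb in dcj_neighbour_keys(key_to_partner(key))) {
        if (is.null(dist[[nb]])) {
          dist[[nb]] <- level
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# exhaustive optimal median total over a genome space (linear candidates,
# as the reconstruction problem demands)
exhaustive_median_total <- function(g1, g2, g3, space, n) {
  best <- Inf
  for (ch in space) {
    m <- genome(ch, n = n)
    tot <- dcj_distance(m, g1)$d + dcj_distance(m, g2)$d + dcj_distance(m, g3)$d
    if (tot < best) best <- tot
  }
  best
}

# random chromosome list for property tests
rand_chroms <- function(n, max_chroms = 2L) {
  k <- sample.int(min(max_chroms, n), 1L)
  perm <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
  cuts <- if (k > 1L) sort(sample.int(n - 1L, k - 1L)) else integer(0)
  bounds <- c(0L, cuts, n)
  lapply(seq_len(k), function(i) perm[(bounds[i] + 1L):bounds[i + 1L]])
}
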