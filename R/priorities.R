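#' Priority levels of a greedy scheme
#'
#' Enumerates the distinct comparison classes (priority levels) of the
#' chosen scheme's priority key, by mapping the key domain through the
#' same level function the greedy engine uses. The key is compared
#' lexicographically: cycles creatable now (1-3; a pathgroup whose every
#' completion would close a circular chromosome gets no priority at all),
#' then the best cycle count creatable in any affected pathgroup at the
#' next step (1-3), then - for the refined and two-step schemes - the net
#' change in potential cycles over all affected pathgroups (saturating at
#' -4..+4; a step touches at most four secondary pathgroups, each
#' typically shifting by at most one potential cycle), and finally - for
#' the two-step scheme - the best cycle count two steps ahead (1-3).
#' A three-cycle pathgroup is already optimal for its step, so its class
#' is not subdivided by the next-step fields (the two-step scheme still
#' subdivides it by its second-step field).
#'
#' The basic scheme yields 7 levels, the refined 55, the two-step
#' look-ahead 165.
#'
#' @param scheme `"basic"`, `"refined"` or `"lookahead2"`.
#' @return a data frame with columns `level` (0 = highest priority),
#'   `cycles`, `best_next`, `net_delta`, `second_step` (fields not used by
#'   the scheme are `NA`), one row per distinct level, ordered by
#'   decreasing priority.
#' @examples
#' nrow(priority_levels("basic"))      # 7
#' nrow(priority_levels("refined"))    # 55
#' nrow(priority_levels("lookahead2")) # 165
#' @export
priority_levels <- function(scheme = c("basic", "refined", "lookahead2")) {
  scheme <- match.arg(scheme)
  code <- scheme_code(scheme)
  # probe beyond the saturation bounds so that clamping is part of what is
  # being enumerated rather than assumed
  grid <- expand.grid(cycles = 1:3, best_next = 0:4, net_delta = -6:6,
                      second_step = 0:4)
  lev <- pg_level_of_cpp(code, grid$cycles, grid$best_next,
                         grid$net_delta, grid$second_step)
  grid$level <- lev
  keep <- !duplicated(grid$level)
  out <- grid[keep, c("level", "cycles", "best_next", "net_delta", "second_step")]
  # report the representative key of each class in its canonical
  # (clamped) form
  out$best_next <- pmin(pmax(out$best_next, 1L), 3L)
  out$net_delta <- pmin(pmax(out$net_delta, -4L), 4L)
  out$second_step <- pmin(pmax(out$second_step, 1L), 3L)
  if (code < 2L) out$second_step <- NA_integer_
  if (code < 1L) out$net_delta <- NA_integer_
  out$best_next[out$cycles == 3L] <- NA_integer_
  out$net_delta[out$cycles == 3L] <- NA_integer_
  out <- out[!duplicated(out$level), ]
  out <- out[order(out$level), ]
  rownames(out) <- NULL
  stopifnot(nrow(out) == pg_n_levels_cpp(code))
  out
}
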