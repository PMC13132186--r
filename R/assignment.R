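# Minimum-cost bipartite assignment (Hungarian / Jonker-Volgenant style
# shortest augmenting paths with dual potentials, O(n^2 m)). Used both for
# frame-to-frame data association and for ground-truth matching in the
# evaluation metrics.

BIG_COST <- 1e8 # stands in for +Inf (unmatchable pair) in the dual updates

#' Solve a rectangular min-cost assignment problem
#'
#' @param cost numeric matrix; `Inf` marks forbidden pairs.
#' @return Integer vector of length `nrow(cost)`: `assignment[i]` is the
#'   column assigned to row `i` (every row is assigned when
#'   `nrow <= ncol`, otherwise the cheapest `ncol` rows are). Forbidden pairs
#'   may appear in the raw assignment; callers filter them (see
#'   [hungarian_match()]).
#' @keywords internal
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(0))
  transposed <- n > m
  a <- if (transposed) t(cost) else cost
  a[!is.finite(a)] <- BIG_COST
  nr <- nrow(a); nc <- ncol(a)

  u <- numeric(nr + 1); v <- numeric(nc + 1)
  p <- integer(nc + 1)       # p[j+1] = row assigned to column j (0 = none)
  way <- integer(nc + 1)
  for (i in seq_len(nr)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, nc)
    used <- rep(FALSE, nc + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- a[i0, free] - u[i0 + 1] - v[free + 1]
      improved <- cur < minv[free]
      minv[free[improved]] <- cur[improved]
      way[free[improved] + 1] <- j0
      delta_j <- free[which.min(minv[free])]
      delta <- minv[delta_j]
      usedj <- which(used) - 1L
      u[p[usedj + 1] + 1] <- u[p[usedj + 1] + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[free] <- minv[free] - delta
      j0 <- delta_j
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assigned <- rep(NA_integer_, nr)
  for (j in seq_len(nc)) if (p[j + 1] > 0L) assigned[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, n)
    for (r in seq_len(nr)) if (!is.na(assigned[r])) out[assigned[r]] <- r
    out
  } else {
    assigned
  }
}

#' Hungarian matching with a cost ceiling
#'
#' Computes the minimum-total-cost assignment between rows (tracks) and
#' columns (detections), then demotes any assigned pair whose cost exceeds
#' `match_threshold` back to unmatched. The three outputs partition all row
#' and column indices.
#'
#' @param cost numeric cost matrix in `[0, 1]` (use `Inf` for unmatchable
#'   pairs, e.g. mismatched classes).
#' @param match_threshold pairs costlier than this are not matched.
#' @return List with `matches` (two-column matrix of row/col index pairs),
#'   `unmatched_rows`, `unmatched_cols`.
#' @export
#' @examples
#' hungarian_match(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2), 0.8)
hungarian_match <- function(cost, match_threshold = Inf) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) {
    return(list(matches = matrix(integer(0), 0, 2,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m)))
  }
  assigned <- solve_assignment(cost)
  rows <- integer(0); cols <- integer(0)
  for (i in seq_len(n)) {
    j <- assigned[i]
    if (!is.na(j) && is.finite(cost[i, j]) && cost[i, j] <= match_threshold) {
      rows <- c(rows, i); cols <- c(cols, j)
    }
  }
  list(matches = cbind(row = rows, col = cols),
       unmatched_rows = setdiff(seq_len(n), rows),
       unmatched_cols = setdiff(seq_len(m), cols))
}
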