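## Minimum-cost bipartite assignment (Jonker-Volgenant style shortest
## augmenting path, O(n^3)). Square matrices only; callers pad.
## Index shift: position 1 in p/v/way/minv/used is the virtual column 0,
## position 1 in u is the virtual row 0.
.lapSolve <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop("cost matrix must be finite")
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[-1L])          # real columns not yet visited
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      k <- which.min(minv[free + 1L])
      delta <- minv[free[k] + 1L]
      j1 <- free[k] + 1L
      uIdx <- which(used)
      u[p[uIdx] + 1L] <- u[p[uIdx] + 1L] + delta
      v[uIdx] <- v[uIdx] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) ans[p[j + 1L]] <- j
  ans
}

#' Globally optimal assignment between two sets
#'
#' Solves the rectangular linear assignment problem: given an n x m cost
#' matrix, finds the matching of rows to columns of minimum total cost in
#' which every row and column is used at most once and min(n, m) pairs are
#' formed. Pairs whose cost is not below \code{forbidden} are dropped from
#' the returned matching, so callers can mark ineligible pairs with a large
#' sentinel cost.
#'
#' @param cost Numeric n x m cost matrix (finite entries).
#' @param forbidden Costs >= this value mark ineligible pairs
#'   (default \code{1e6}); such pairs never appear in the result.
#' @return A two-column integer matrix with columns \code{row} and
#'   \code{col}, one matched pair per line, ordered by row.
#' @examples
#' solveAssignment(matrix(c(1, 2, 2, 1), 2, 2))
#' @export
solveAssignment <- function(cost, forbidden = 1e6) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L)
    return(matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("row", "col"))))
  s <- max(n, m)
  padded <- matrix(0, s, s)
  padded[seq_len(n), seq_len(m)] <- cost
  assign <- .lapSolve(padded)
  rows <- seq_len(n)
  cols <- assign[rows]
  keep <- cols <= m
  keep[keep] <- cost[cbind(rows[keep], cols[keep])] < forbidden
  out <- cbind(row = rows[keep], col = cols[keep])
  out[order(out[, 1L]), , drop = FALSE]
}
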