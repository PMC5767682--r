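#' Minimum-cost linear assignment
#'
#' Solves the rectangular linear sum assignment problem by the shortest
#' augmenting path method (Jonker-Volgenant style, O(n^2 m)). Every row is
#' assigned to a distinct column; the number of rows must not exceed the
#' number of columns. This is the optimizer behind the symmetry-corrected
#' ligand RMSD ([hungarian_rmsd()]).
#'
#' @param cost numeric matrix of finite costs, `nrow(cost) <= ncol(cost)`.
#' @return list with `assignment` (column index per row) and `cost`
#'   (total cost of the optimal assignment).
#' @examples
#' solve_assignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3))
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) abort("empty cost matrix")
  if (n > m) abort("cost matrix must have nrow <= ncol")
  if (!all(is.finite(cost))) abort("cost matrix must be finite")

  # columns are indexed 1..m; index m+1 is the virtual start column
  J0 <- m + 1L
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # p[j] = row currently assigned to column j (0 = free)

  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    way <- integer(m)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used[seq_len(m)])
      cur <- cost[i0, free_j] - u[i0] - v[free_j]
      better <- cur < minv[free_j]
      if (any(better)) {
        bj <- free_j[better]
        minv[bj] <- cur[better]
        way[bj] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_j <- which(used)
      u[p[used_j]] <- u[p[used_j]] + delta
      v[used_j] <- v[used_j] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    # augment along the alternating path back to the virtual column
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == J0) i else p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }

  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assignment[p[j]] <- j
  list(assignment = assignment,
       cost = sum(cost[cbind(seq_len(n), assignment)]))
}
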