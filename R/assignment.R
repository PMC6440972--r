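## Exact solver for the rectangular linear assignment problem
## (potentials + shortest augmenting path, O(n^3)). Used by the tracker to
## resolve frame-to-frame links when detection counts or nearest neighbours
## conflict. Costs may contain Inf for forbidden pairs.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(0))
  transposed <- FALSE
  if (n > m) {
    cost <- t(cost)
    n <- nrow(cost)
    m <- ncol(cost)
    transposed <- TRUE
  }
  big <- max(cost[is.finite(cost)], 0) * (n + m) + 1
  cost[!is.finite(cost)] <- big

  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j+1]: row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1] > 0) assign_row[p[j + 1]] <- j
  }
  if (transposed) {
    out <- rep(NA_integer_, m)
    out[assign_row] <- seq_len(n)
    out
  } else {
    assign_row
  }
}

## assignment with a per-link cap: rows/columns may stay unmatched at cost
## `unlink_cost` each (standard birth/death augmentation). Returns, for each
## row, the matched column or NA.
solve_assignment_capped <- function(cost, unlink_cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (m == 0) return(rep(NA_integer_, n))
  full <- matrix(Inf, n + m, m + n)
  full[seq_len(n), seq_len(m)] <- cost
  full[cbind(seq_len(n), m + seq_len(n))] <- unlink_cost
  full[cbind(n + seq_len(m), seq_len(m))] <- unlink_cost
  full[n + seq_len(m), m + seq_len(n)] <- 0
  a <- solve_assignment(full)
  out <- a[seq_len(n)]
  out[out > m] <- NA_integer_
  out
}
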