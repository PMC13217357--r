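# Hungarian (Kuhn-Munkres) solver for the linear assignment problem.
# O(n^3) potentials + augmenting-path formulation; minimizes total cost of a
# perfect matching on a square matrix. Rectangular inputs are padded.

#' Minimum-cost assignment
#'
#' @param cost numeric matrix (rows = agents, cols = tasks); may be
#'   rectangular. Infinite entries are allowed (forbidden pairs) as long as a
#'   finite-cost assignment of min(nrow, ncol) pairs exists after padding.
#' @return integer vector `a` of length nrow(cost): `a[i]` = assigned column
#'   for row i, or NA for rows left unassigned (padding).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n0 <- nrow(cost); m0 <- ncol(cost)
  if (n0 == 0L || m0 == 0L) return(rep(NA_integer_, n0))
  n <- max(n0, m0)
  big <- max(abs(cost[is.finite(cost)]), 1) * n * 4 + 1
  a <- matrix(big, n, n)
  cf <- cost
  cf[!is.finite(cf)] <- big
  a[seq_len(n0), seq_len(m0)] <- cf
  # JV-style shortest augmenting path with potentials (1-based R port)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      js <- which(!used[-1L])           # candidate columns (1..n)
      if (length(js)) {
        cur <- a[i0, js] - u[i0 + 1L] - v[js + 1L]
        upd <- cur < minv[js + 1L]
        minv[js[upd] + 1L] <- cur[upd]
        way[js[upd] + 1L] <- j0
        j1 <- js[which.min(minv[js + 1L])]
        delta <- minv[j1 + 1L]
      }
      touched <- which(used)
      u[p[touched] + 1L] <- u[p[touched] + 1L] + delta
      v[touched] <- v[touched] - delta
      nt <- which(!used[-1L])
      minv[nt + 1L] <- minv[nt + 1L] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_col <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) assign_col[p[j + 1L]] <- j
  out <- rep(NA_integer_, n0)
  for (i in seq_len(n0)) {
    j <- assign_col[i]
    if (j >= 1L && j <= m0) out[i] <- j
  }
  out
}

# maximize total score one-to-one; entries <= threshold are excluded.
# Returns 2-col matrix (row, col) of kept pairs.
max_score_matching <- function(score, threshold = -Inf) {
  n <- nrow(score); m <- ncol(score)
  if (n == 0L || m == 0L) return(matrix(integer(0), ncol = 2L))
  s <- score
  s[!is.finite(s) | s <= threshold] <- 0
  asn <- solve_assignment(-s)
  keep <- which(!is.na(asn))
  keep <- keep[score[cbind(keep, asn[keep])] > threshold &
                 is.finite(score[cbind(keep, asn[keep])])]
  cbind(row = keep, col = asn[keep])
}
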