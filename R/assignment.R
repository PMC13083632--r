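# Maximum-weight one-to-one assignment used for bipartite reranking.

# O(n^3) Hungarian algorithm (Jonker-Volgenant potentials) for a square cost
# matrix; returns, per row, the assigned column index of a minimum-cost
# perfect matching.
.hungarianMin <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n)           # row potentials, indexed by row
  v <- numeric(n + 1)       # column potentials, index 1 = virtual column 0
  p <- integer(n + 1)       # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
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
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Maximum-total-similarity one-to-one assignment
#'
#' Solves the maximum-weight bipartite assignment over a rectangular
#' similarity matrix (rows: source attributes, columns: candidate target
#' attributes). The matrix is square-padded with zeros; rows whose optimal
#' partner is a padding column fall back to their top-scoring real candidate.
#' Among equal-cost optima the assignment preferring, for earlier rows,
#' lexicographically smaller column names is returned (column names taken
#' from \code{colnames}, or column index order when absent).
#'
#' @param scoreMatrix Numeric matrix with entries in \eqn{[0, 1]}.
#' @return Integer vector: for each row, the assigned column index (after the
#'   fallback). The strict one-to-one assignment, with \code{NA} for rows the
#'   padding left unassigned, is attached as attribute \code{"assignment"}.
#' @examples
#' bipartiteRerank(diag(3))
#' @export
bipartiteRerank <- function(scoreMatrix) {
  scoreMatrix <- as.matrix(scoreMatrix)
  stopifnot(all(scoreMatrix >= 0 & scoreMatrix <= 1))
  nr <- nrow(scoreMatrix)
  nc <- ncol(scoreMatrix)
  n <- max(nr, nc)
  padded <- matrix(0, n, n)
  padded[seq_len(nr), seq_len(nc)] <- scoreMatrix
  # Lexicographic tie-break among equal-cost optima: add a secondary
  # preference, scaled far below any genuine score difference, that rewards
  # earlier rows taking lexicographically smaller column names.
  cn <- colnames(scoreMatrix)
  colRank <- if (is.null(cn)) seq_len(nc) else rank(cn, ties.method = "first")
  pref <- matrix(0, n, n)
  base <- nc + 1
  for (i in seq_len(nr)) {
    pref[i, seq_len(nc)] <- base^(nr - i) * (nc - colRank + 1)
  }
  eta <- 1e-9 / max(pref[pref > 0], 1)
  assignment <- .hungarianMin(-(padded + eta * pref))
  raw <- integer(nr)
  out <- integer(nr)
  for (i in seq_len(nr)) {
    j <- assignment[i]
    raw[i] <- if (j > nc) NA_integer_ else j
    if (j > nc) {
      # padded column: unassigned, fall back to the top real candidate
      j <- which.max(scoreMatrix[i, ] + eta * pref[i, seq_len(nc)])
    }
    out[i] <- j
  }
  # the strict one-to-one assignment (NA where a row was left unassigned by
  # padding), before the fallback is applied
  attr(out, "assignment") <- raw
  out
}
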