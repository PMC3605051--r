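# Independent brute-force oracles used to pin down expected values.

# All monotone pairings of k rows against k columns (k = 0..min(n, m)):
# enumerate row subsets and column subsets of equal size; order matching is
# then forced. Scores a pairing under affine gap costs charged per maximal
# gap run (open + extend * (run_len - 1)), including terminal gaps, which is
# the cost structure of a global alignment path.
brute_force_dp <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  gap_cost <- function(len) if (len > 0) gap_open + gap_extend * (len - 1) else 0
  score_pairs <- function(ia, ib) {
    k <- length(ia)
    if (k == 0L) {
      # pure gap alignment: one run in A and one in B (they can be adjacent)
      return(gap_cost(n) + gap_cost(m))
    }
    s <- sum(S[cbind(ia, ib)])
    s <- s + gap_cost(ia[1] - 1) + gap_cost(ib[1] - 1)
    s <- s + gap_cost(n - ia[k]) + gap_cost(m - ib[k])
    if (k > 1) {
      for (t in seq_len(k - 1)) {
        s <- s + gap_cost(ia[t + 1] - ia[t] - 1) + gap_cost(ib[t + 1] - ib[t] - 1)
      }
    }
    s
  }
  best <- -Inf
  for (k in 0:min(n, m)) {
    rows <- if (k == 0) list(integer()) else asplit(combn(n, k), 2)
    cols <- if (k == 0) list(integer()) else asplit(combn(m, k), 2)
    for (ia in rows) {
      for (ib in cols) {
        sc <- score_pairs(as.integer(ia), as.integer(ib))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Memoized top-down recursion for the same optimum, feasible to ~30x30.
# Independent formulation: state (i, j, g) where g = 0 none / 1 in-A-gap /
# 2 in-B-gap describes the gap state entering column (i, j).
recursive_dp_score <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, g) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, g)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, S[i, j] + rec(i + 1, j + 1, 0L))
    }
    if (i <= n) {   # gap in B: consume a row of A
      pen <- if (g == 2L) gap_extend else gap_open
      best <- max(best, pen + rec(i + 1, j, 2L))
    }
    if (j <= m) {   # gap in A: consume a column of B
      pen <- if (g == 1L) gap_extend else gap_open
      best <- max(best, pen + rec(i, j + 1, 1L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# Score of a pair matrix under the package's affine convention, for
# comparing dp_align()'s returned pairing against an oracle optimum.
score_pair_matrix <- function(S, pairs, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  gap_cost <- function(len) if (len > 0) gap_open + gap_extend * (len - 1) else 0
  if (nrow(pairs) == 0L) return(gap_cost(n) + gap_cost(m))
  ia <- pairs[, 1]; ib <- pairs[, 2]
  s <- sum(S[cbind(ia, ib)])
  s <- s + gap_cost(ia[1] - 1) + gap_cost(ib[1] - 1)
  k <- length(ia)
  s <- s + gap_cost(n - ia[k]) + gap_cost(m - ib[k])
  if (k > 1) {
    for (t in seq_len(k - 1)) {
      s <- s + gap_cost(ia[t + 1] - ia[t] - 1) + gap_cost(ib[t + 1] - ib[t] - 1)
    }
  }
  s
}

# Exhaustive SSEA optimum over monotone element matchings (<= 6 elements).
brute_force_ssea <- function(ea, eb) {
  n <- nrow(ea); m <- nrow(eb)
  w <- function(i, j) {
    if (ea$type[i] == eb$type[j]) min(ea$length[i], eb$length[j]) else 0
  }
  best <- 0
  for (k in 0:min(n, m)) {
    if (k == 0) next
    rows <- asplit(combn(n, k), 2)
    cols <- asplit(combn(m, k), 2)
    for (ia in rows) for (ib in cols) {
      best <- max(best, sum(mapply(w, ia, ib)))
    }
  }
  100 * 2 * best / (sum(ea$length) + sum(eb$length))
}

# Grid-search + local-refinement superposition oracle: minimize RMSD over
# rotations (Euler angles) and the implied optimal translation.
brute_force_rmsd <- function(A, B) {
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  obj <- function(ang) {
    Bt <- tcrossprod(Bc, rot(ang))
    sqrt(mean(rowSums((Bt - Ac)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  refined <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 5000))
  refined$value
}

# Small synthetic PDB texts used by the IO tests.
write_minimal_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3       8.600   0.000   0.000  1.00  0.00           C",
    "TER", "END"
  )
  writeLines(lines, path)
  path
}

write_altloc_pdb <- function(path) {
  lines <- c(
    "ATOM      1  CA  ALA A   9       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA AVAL A  10       1.000   2.000   3.000  0.40  0.00           C",
    "ATOM      3  CA BVAL A  10       9.000   9.000   9.000  0.60  0.00           C",
    "ATOM      4  CA  LEU A  11       4.000   0.000   0.000  1.00  0.00           C",
    "TER", "END"
  )
  writeLines(lines, path)
  path
}
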