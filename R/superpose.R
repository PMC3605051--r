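# Structural-comparison core: Kabsch superposition, TM-score with the d0
# length scaling, and an iterative DP structural aligner in the TM-align
# style.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of `B` onto
#' `A` over all rigid transforms. The reflection branch of the SVD solution
#' is never accepted (biological chirality). Collinear point sets are
#' rejected because the rotation about the common axis is undetermined.
#'
#' @param A,B numeric N x 3 coordinate matrices (N >= 3, equal N).
#' @return an object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation` (length 3) and `rmsd` (Angstrom). The transform
#'   maps a row-vector `b` to `rotation %*% b + translation`.
#' @export
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' s <- kabsch_superpose(A, A)
#' s$rmsd # 0
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) abort("coordinate sets differ in length", class = "domex_length_mismatch")
  if (nrow(A) < 3L) abort("need at least 3 points to superpose", class = "domex_too_few_points")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  sv_a <- svd(Ac)$d; sv_b <- svd(Bc)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1) || sv_b[2] < 1e-8 * max(sv_b[1], 1)) {
    abort("degenerate (collinear) point set: superposition is not unique",
          class = "domex_degenerate_points")
  }
  H <- crossprod(Bc, Ac)                      # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)    # maps B-frame into A-frame
  t_vec <- as.numeric(cA - R %*% cB)
  Bt <- tcrossprod(Bc, R)                     # rows rotated
  rmsd <- sqrt(mean(rowSums((Bt - Ac)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param sup a `superposition`.
#' @param X numeric N x 3 matrix.
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(sup, X) {
  sweep(tcrossprod(as.matrix(X), sup$rotation), 2, sup$translation, "+")
}

#' TM-score distance scale d0
#'
#' `d0(L) = 1.24 (L - 15)^(1/3) - 1.8` Angstrom, floored at 0.5, the
#' standard length normalization that makes TM-score magnitudes comparable
#' across protein sizes.
#'
#' @param L target length (residues, >= 1).
#' @return d0 in Angstrom.
#' @export
#' @examples
#' tm_d0(135) # 4.3162
tm_d0 <- function(L) {
  if (any(L < 1)) abort("L must be >= 1")
  raw <- ifelse(L > 15, 1.24 * (L - 15)^(1 / 3) - 1.8, 0)
  pmax(raw, 0.5)
}

#' TM-score from aligned-pair distances
#'
#' `(1/L_target) * sum 1 / (1 + (d_i / d0(L_target))^2)` over the aligned
#' residue pairs; unaligned residues contribute zero. The score is in (0, 1]
#' and equals 1 exactly when all `L_target` residues are aligned at zero
#' distance.
#'
#' @param distances numeric vector of aligned-pair distances (Angstrom,
#'   non-negative).
#' @param L_target normalization length (>= number of aligned pairs, >= 1).
#' @return TM-score.
#' @export
tm_score <- function(distances, L_target) {
  if (any(distances < 0)) abort("distances must be non-negative")
  if (L_target < max(length(distances), 1)) {
    abort("L_target must be at least the number of aligned pairs")
  }
  d0 <- tm_d0(L_target)
  sum(1 / (1 + (distances / d0)^2)) / L_target
}

#' Low-level affine-gap DP alignment over a similarity matrix
#'
#' Global dynamic programming maximizing the summed similarity of aligned
#' cells minus affine gap costs, as used inside [align_structures()]. Exposed
#' for testing and for custom seeding schemes.
#'
#' @param S numeric similarity matrix (rows: structure A, columns: B).
#' @param gap_open gap-opening score (default -0.6, the TM-align convention
#'   on the TM-score matrix).
#' @param gap_extend gap-extension score (default 0).
#' @return integer matrix of aligned (row, column) pairs, strictly
#'   increasing in both coordinates.
#' @export
dp_align <- function(S, gap_open = -0.6, gap_extend = 0) {
  dp_align_cpp(as.matrix(S), gap_open, gap_extend)
}

# TM-score of a pair set under a score-maximizing superposition: superpose
# on progressively distance-trimmed subsets and keep the best score, the
# standard refinement used when reporting TM-scores.
tm_refined <- function(coordsA, coordsB, pairs, L_target, d0 = tm_d0(L_target)) {
  sub <- pairs
  best <- list(score = -Inf, sup = NULL, dist = NULL)
  for (cutoff in c(Inf, 8, max(4.5, d0))) {
    if (nrow(sub) < 3L) break
    sup <- kabsch_superpose(coordsA[sub[, 1], , drop = FALSE],
                            coordsB[sub[, 2], , drop = FALSE])
    Bt <- apply_superposition(sup, coordsB[pairs[, 2], , drop = FALSE])
    d <- sqrt(rowSums((Bt - coordsA[pairs[, 1], , drop = FALSE])^2))
    sc <- sum(1 / (1 + (d / d0)^2)) / L_target
    if (sc > best$score) best <- list(score = sc, sup = sup, dist = d)
    sub <- pairs[d < cutoff, , drop = FALSE]
  }
  best
}

# Gapless-threading seed pairs: all diagonal shifts at the given stride,
# scored by the TM-score of the overlap under its own superposition.
threading_seeds <- function(coordsA, coordsB, frag_len, L_min, stride = 2L) {
  nA <- nrow(coordsA); nB <- nrow(coordsB)
  seeds <- list()
  for (s in seq(-(nB - frag_len), nA - frag_len, by = stride)) {
    ia <- max(1L, 1L + s):min(nA, nB + s)
    if (length(ia) < frag_len) next
    ib <- ia - s
    # score on a centred window of frag_len residues within the overlap
    off <- (length(ia) - frag_len) %/% 2
    win <- (off + 1):(off + frag_len)
    sup <- tryCatch(
      kabsch_superpose(coordsA[ia[win], , drop = FALSE], coordsB[ib[win], , drop = FALSE]),
      error = function(e) NULL
    )
    if (is.null(sup)) next
    Bt <- apply_superposition(sup, coordsB[ib, , drop = FALSE])
    d <- sqrt(rowSums((Bt - coordsA[ia, , drop = FALSE])^2))
    seeds[[length(seeds) + 1L]] <- list(
      pairs = cbind(ia, ib),
      score = tm_score(d, L_min)
    )
  }
  seeds
}

#' Align two protein structures (TM-align-style heuristic)
#'
#' Heuristic maximization of the TM-score between two C-alpha traces. Seed
#' alignments come from gapless threading at fragment lengths N, N/2 and N/4
#' (N = shorter chain) and, when secondary-structure strings are supplied,
#' from a DP alignment of the H/E/C strings. Each seed is refined by
#' iterating superposition on the current pairs, rebuilding the TM-score
#' similarity matrix `1 / (1 + d^2 / d0^2)`, and re-aligning by affine-gap
#' global DP (open -0.6, extend 0) until the pair set repeats or `max_iter`
#' rounds. The best alignment by TM-score wins; ties break toward larger
#' aligned length, then smaller RMSD.
#'
#' The reported TM-score is normalized by the shorter chain
#' (`L_target = min(NA, NB)`), which makes shared-domain detection symmetric
#' between chains of very different size; the per-chain normalizations are
#' reported alongside (`tm_score_a`, `tm_score_b`). Reported pairs exclude
#' residues farther apart than `trim_distance` under the final superposition
#' so that spurious long-distance DP pairs outside the shared domain do not
#' contaminate the aligned length and RMSD.
#'
#' @param A,B [protein_structure()] objects with >= 20 residues.
#' @param ss_a,ss_b optional [ss_string()] objects used for an additional
#'   secondary-structure-based seed.
#' @param gap_open,gap_extend DP gap scores on the TM-score matrix.
#' @param max_iter iteration cap per seed (default 30).
#' @param n_seeds number of top-scoring seeds refined (default 6).
#' @param trim_distance distance cutoff (Angstrom) for reported pairs.
#' @return an object of class `structural_alignment`: `pairs` tibble
#'   (`index_a`, `index_b`, `aa_a`, `aa_b`, `dist`), `rmsd`, `tm_score`
#'   (min-length normalization), `tm_score_a`, `tm_score_b`,
#'   `aligned_length`, `seq_identity` (percent of aligned columns with
#'   identical amino acids), `superposition`, and the two chain ids/lengths.
#' @export
align_structures <- function(A, B, ss_a = NULL, ss_b = NULL,
                             gap_open = -0.6, gap_extend = 0,
                             max_iter = 30L, n_seeds = 6L,
                             trim_distance = 8) {
  nA <- structure_length(A); nB <- structure_length(B)
  if (nA < 20L || nB < 20L) {
    abort("structures must have at least 20 residues", class = "domex_too_short")
  }
  coordsA <- structure_coords(A); coordsB <- structure_coords(B)
  L_min <- min(nA, nB)
  d0 <- tm_d0(L_min)
  d0sq <- d0^2

  seeds <- list()
  for (frac in c(1, 2, 4)) {
    frag <- max(5L, L_min %/% frac)
    seeds <- c(seeds, threading_seeds(coordsA, coordsB, frag, L_min,
                                      stride = max(2L, L_min %/% 25L)))
  }
  if (!is.null(ss_a) && !is.null(ss_b)) {
    sa <- strsplit(ss_a$ss, "")[[1]]; sb <- strsplit(ss_b$ss, "")[[1]]
    if (length(sa) == nA && length(sb) == nB) {
      S_ss <- outer(sa, sb, "==") * 1
      p <- dp_align(S_ss, gap_open = -1, gap_extend = 0)
      if (nrow(p) >= 3L) seeds[[length(seeds) + 1L]] <- list(pairs = p, score = 0.01)
    }
  }
  if (length(seeds) == 0L) {
    abort("no seed alignment produced 3 or more pairs", class = "domex_no_seed")
  }
  ord <- order(vapply(seeds, `[[`, 0, "score"), decreasing = TRUE)
  seeds <- seeds[ord[seq_len(min(n_seeds, length(seeds)))]]

  best <- NULL
  for (seed in seeds) {
    pairs <- seed$pairs
    seen <- character()
    for (iter in seq_len(max_iter)) {
      if (nrow(pairs) < 3L) break
      sup <- tryCatch(
        kabsch_superpose(coordsA[pairs[, 1], , drop = FALSE],
                         coordsB[pairs[, 2], , drop = FALSE]),
        error = function(e) NULL
      )
      if (is.null(sup)) break
      Bt <- apply_superposition(sup, coordsB)
      D2 <- outer(rowSums(coordsA^2), rowSums(Bt^2), "+") - 2 * tcrossprod(coordsA, Bt)
      D2[D2 < 0] <- 0
      S <- 1 / (1 + D2 / d0sq)
      new_pairs <- dp_align(S, gap_open, gap_extend)
      ref <- tm_refined(coordsA, coordsB, new_pairs, L_min, d0)
      cand <- list(pairs = new_pairs, score = ref$score, sup = ref$sup, dist = ref$dist)
      if (is.null(best) ||
          cand$score > best$score + 1e-12 ||
          (abs(cand$score - best$score) <= 1e-12 &&
           (nrow(cand$pairs) > nrow(best$pairs) ||
            (nrow(cand$pairs) == nrow(best$pairs) &&
             !is.null(best$dist) && mean(cand$dist^2) < mean(best$dist^2))))) {
        best <- cand
      }
      key <- paste(new_pairs[, 1], new_pairs[, 2], collapse = ",")
      if (key %in% seen) break
      seen <- c(seen, key)
      pairs <- new_pairs
    }
  }
  if (is.null(best)) {
    abort("no seed alignment produced 3 or more pairs", class = "domex_no_seed")
  }

  finalize_alignment(A, B, best$pairs, best$dist, L_min, trim_distance)
}

# Build the reported structural_alignment object from a raw DP pair set and
# its distances under the score-optimal superposition.
finalize_alignment <- function(A, B, pairs, dist, L_min, trim_distance) {
  keep <- dist <= trim_distance
  if (sum(keep) >= 3L) {
    pairs <- pairs[keep, , drop = FALSE]
  }
  coordsA <- structure_coords(A); coordsB <- structure_coords(B)
  sup <- kabsch_superpose(coordsA[pairs[, 1], , drop = FALSE],
                          coordsB[pairs[, 2], , drop = FALSE])
  Bt <- apply_superposition(sup, coordsB[pairs[, 2], , drop = FALSE])
  d_rms <- sqrt(rowSums((Bt - coordsA[pairs[, 1], , drop = FALSE])^2))
  # TM-scores under the score-maximizing superposition of the final pairs
  ref_min <- tm_refined(coordsA, coordsB, pairs, L_min)
  nA <- structure_length(A); nB <- structure_length(B)
  score_with_L <- function(L) {
    sum(1 / (1 + (ref_min$dist / tm_d0(L))^2)) / L
  }
  aa_a <- A$residues$aa[pairs[, 1]]
  aa_b <- B$residues$aa[pairs[, 2]]
  out <- list(
    id_a = A$id, id_b = B$id, n_a = nA, n_b = nB,
    pairs = tibble::tibble(
      index_a = pairs[, 1], index_b = pairs[, 2],
      aa_a = aa_a, aa_b = aa_b, dist = d_rms
    ),
    aligned_length = nrow(pairs),
    rmsd = sup$rmsd,
    tm_score = ref_min$score,
    tm_score_a = score_with_L(nA),
    tm_score_b = score_with_L(nB),
    seq_identity = 100 * mean(aa_a == aa_b),
    superposition = sup
  )
  class(out) <- "structural_alignment"
  out
}

#' @export
print.structural_alignment <- function(x, ...) {
  cat("<structural_alignment> ", x$id_a, " (", x$n_a, ") vs ", x$id_b,
      " (", x$n_b, ")\n", sep = "")
  cat(sprintf("  aligned %d residues, RMSD %.2f A, TM-score %.3f (min; a %.3f, b %.3f), identity %.1f%%\n",
              x$aligned_length, x$rmsd, x$tm_score, x$tm_score_a, x$tm_score_b,
              x$seq_identity))
  invisible(x)
}

#' @rdname tidy_domex
#' @method tidy structural_alignment
#' @export
tidy.structural_alignment <- function(x, ...) x$pairs

#' Tidiers for domex result objects
#'
#' `tidy()` returns the per-unit detail (aligned residue pairs, replicate
#' cutoffs, curve bins); `glance()` a one-row summary.
#'
#' @param x a domex result object.
#' @param ... unused.
#' @return a tibble.
#' @name tidy_domex
NULL

#' @rdname tidy_domex
#' @method glance structural_alignment
#' @export
glance.structural_alignment <- function(x, ...) {
  tibble::tibble(
    id_a = x$id_a, id_b = x$id_b,
    aligned_length = x$aligned_length,
    rmsd = x$rmsd,
    tm_score = x$tm_score,
    tm_score_a = x$tm_score_a,
    tm_score_b = x$tm_score_b,
    seq_identity = x$seq_identity
  )
}
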