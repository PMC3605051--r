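# Membrane-distance geometry and the two-sample rank comparison between
# extramembrane domains with and without soluble counterparts.

# Structure coordinates expressed in the membrane frame (does not modify
# the structure).
membrane_frame_coords <- function(structure, annot) {
  X <- structure_coords(structure)
  sweep(tcrossprod(X, annot$rotation), 2, annot$translation, "+")
}

#' Transform a structure into its membrane frame
#'
#' Applies the annotation's rigid transform so the membrane normal is the
#' z-axis and the bilayer occupies `[z_lower, z_upper]`. The returned
#' structure carries a `frame = "membrane"` attribute; transforming an
#' already-transformed structure is refused (the transform is not
#' idempotent).
#'
#' @param structure a [protein_structure()].
#' @param annot the matching [membrane_annotation()].
#' @return the transformed `protein_structure`.
#' @export
to_membrane_frame <- function(structure, annot) {
  if (identical(attr(structure, "frame"), "membrane")) {
    abort("structure is already in the membrane frame", class = "domex_double_transform")
  }
  validate_annotation(structure, annot)
  M <- membrane_frame_coords(structure, annot)
  out <- structure
  out$residues$x <- M[, 1]; out$residues$y <- M[, 2]; out$residues$z <- M[, 3]
  attr(out, "frame") <- "membrane"
  out
}

#' Membrane distance of an extramembrane domain
#'
#' Distance between the domain centroid (mean of the domain's C-alpha
#' coordinates in the membrane frame) and the nearer bilayer surface, with
#' the side taken from the sign of the centroid's z relative to the slab
#' midplane.
#'
#' @param domain_indices integer ordinal residue indices of the domain (all
#'   must be labelled non-TM).
#' @param structure a [protein_structure()].
#' @param annot the matching [membrane_annotation()].
#' @return one-row tibble: `domain_id`, `distance` (Angstrom, >= 0; zero
#'   iff the centroid lies on a slab surface), `side`, `centroid_z`.
#' @export
domain_membrane_distance <- function(domain_indices, structure, annot) {
  domain_indices <- as.integer(domain_indices)
  if (length(domain_indices) == 0L) {
    abort("empty domain", class = "domex_empty_domain")
  }
  validate_annotation(structure, annot)
  if (any(annot$region[domain_indices] == "TM")) {
    abort("domain contains TM-labelled residues", class = "domex_domain_in_membrane")
  }
  M <- membrane_frame_coords(structure, annot)
  z <- mean(M[domain_indices, 3])
  distance <- min(abs(z - annot$z_lower), abs(z - annot$z_upper))
  side <- if (z >= (annot$z_lower + annot$z_upper) / 2) "outside" else "inside"
  tibble::tibble(domain_id = structure$id, distance = distance,
                 side = side, centroid_z = z)
}

#' Mann-Whitney U test with exact small-sample enumeration
#'
#' Rank-sum comparison of two samples with midrank ties. For
#' `nA + nB <= exact_limit` the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values; otherwise by
#' the normal approximation with tie correction and a 0.5 continuity
#' correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_limit pooled-size limit for exact enumeration (default 12).
#' @return an object of class `mw_test`: `U` (statistic for sample `a`),
#'   `p_value` (two-sided), `method`, sample sizes.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
mann_whitney_u <- function(a, b, exact_limit = 12L) {
  if (length(a) == 0L || length(b) == 0L) {
    abort("both samples must be non-empty", class = "domex_empty_sample")
  }
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)              # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= exact_limit) {
    sets <- combn(n, na)
    u_all <- apply(sets, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    z <- max(0, abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-z))
    method <- "normal approximation (tie and continuity corrected)"
  }
  structure(list(U = U, p_value = p, method = method, n_a = na, n_b = nb),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<mw_test> U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$U, x$n_a, x$n_b, x$p_value, x$method))
  invisible(x)
}

#' @rdname tidy_domex
#' @method glance mw_test
#' @export
glance.mw_test <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
                 method = x$method)
}

#' Compare membrane distances between domain groups
#'
#' Convenience wrapper: takes a per-domain table with a `distance` column
#' and a logical/character `group` column (e.g. with vs without a soluble
#' counterpart) and runs [mann_whitney_u()] between the two groups.
#'
#' @param distances data frame with columns `distance` and `group`.
#' @return an object of class `mw_test` with the group means attached.
#' @export
membrane_distance_test <- function(distances) {
  g <- unique(distances$group)
  if (length(g) != 2L) abort("`group` must have exactly two levels")
  a <- distances$distance[distances$group == g[1]]
  b <- distances$distance[distances$group == g[2]]
  out <- mann_whitney_u(a, b)
  out$groups <- tibble::tibble(group = as.character(g),
                               n = c(length(a), length(b)),
                               mean_distance = c(mean(a), mean(b)))
  out
}
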