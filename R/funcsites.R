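# Functional-site transfer analysis: conserved catalytic residues across a
# structural alignment, first/second shell extraction at 5 Angstrom, and the
# PAM-250 shell-vs-rest similarity statistic.

# PAM-250 substitution matrix (lazy-loaded from Biostrings).
pam250_env <- new.env(parent = emptyenv())
pam250_matrix <- function() {
  if (is.null(pam250_env$m)) {
    e <- new.env()
    utils::data("PAM250", package = "Biostrings", envir = e)
    pam250_env$m <- e$PAM250
  }
  pam250_env$m
}

# Map author seq_num sites onto ordinal residue indices, enforcing the
# amino-acid identity invariant of the site set.
resolve_sites <- function(structure, sites) {
  if (nrow(sites) == 0L) return(integer())
  idx <- match(sites$seq_num, structure$residues$seq_num)
  if (anyNA(idx)) {
    abort(paste0("site residue(s) not found in ", structure$id, ": ",
                 paste(sites$seq_num[is.na(idx)], collapse = ", ")),
          class = "domex_site_not_found")
  }
  found <- structure$residues$aa[idx]
  if (any(found != sites$aa)) {
    bad <- which(found != sites$aa)
    abort(paste0("site amino acid mismatch at seq_num ",
                 paste(sites$seq_num[bad], collapse = ", ")),
          class = "domex_site_mismatch")
  }
  idx
}

#' Conserved functional residues across a structural alignment
#'
#' A site pair is conserved when a site of A and a site of B occupy the same
#' aligned column and carry the identical amino acid. A site aligned to a
#' gap (or to a non-site residue) cannot be conserved.
#'
#' @param aln a `structural_alignment` from [align_structures()].
#' @param sites_a,sites_b [functional_sites()] of the two structures.
#' @param A,B the corresponding [protein_structure()] objects (needed to
#'   resolve author numbering).
#' @return tibble of matched site pairs: `seq_num_a`, `seq_num_b`, `aa`,
#'   `index_a`, `index_b`. Zero rows when nothing is conserved.
#' @export
conserved_functional_residues <- function(aln, sites_a, sites_b, A, B) {
  ia <- resolve_sites(A, sites_a)
  ib <- resolve_sites(B, sites_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    return(tibble::tibble(seq_num_a = integer(), seq_num_b = integer(),
                          aa = character(), index_a = integer(),
                          index_b = integer()))
  }
  hit <- aln$pairs |>
    dplyr::filter(.data$index_a %in% ia, .data$index_b %in% ib,
                  .data$aa_a == .data$aa_b)
  tibble::tibble(
    seq_num_a = A$residues$seq_num[hit$index_a],
    seq_num_b = B$residues$seq_num[hit$index_b],
    aa = hit$aa_a,
    index_a = hit$index_a,
    index_b = hit$index_b
  )
}

#' First/second shell partition around functional sites
#'
#' First-shell residues lie within `radius` (default 5 Angstrom, C-alpha to
#' C-alpha) of any site residue; second-shell residues within `radius` of
#' any first-shell residue. Sites are never shell members and the four sets
#' (sites, first, second, rest) partition the chain.
#'
#' @param structure a [protein_structure()].
#' @param sites [functional_sites()] (non-empty) or an integer vector of
#'   ordinal residue indices.
#' @param radius shell radius in Angstrom.
#' @return an object of class `shell_partition`: list of integer index sets
#'   `site_residues`, `first_shell`, `second_shell`, `rest`.
#' @export
shells <- function(structure, sites, radius = 5) {
  idx <- if (is.numeric(sites)) as.integer(sites) else resolve_sites(structure, sites)
  if (length(idx) == 0L) abort("site set is empty", class = "domex_empty_sites")
  D <- as.matrix(dist(structure_coords(structure)))
  n <- structure_length(structure)
  all_idx <- seq_len(n)
  near <- function(targets) {
    cand <- all_idx[apply(D[, targets, drop = FALSE] <= radius, 1, any)]
    cand
  }
  first <- setdiff(near(idx), idx)
  second <- setdiff(near(first), c(idx, first))
  rest <- setdiff(all_idx, c(idx, first, second))
  structure(list(site_residues = sort(idx), first_shell = sort(first),
                 second_shell = sort(second), rest = sort(rest)),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat("<shell_partition> sites ", length(x$site_residues),
      ", first shell ", length(x$first_shell),
      ", second shell ", length(x$second_shell),
      ", rest ", length(x$rest), "\n", sep = "")
  invisible(x)
}

#' PAM-250 similarity score of aligned columns
#'
#' Sums the PAM-250 entry over residue-residue columns and charges -11 for
#' every gap-containing column (linear gap costing, one published number, no
#' affine extension). A (gap, gap) column is illegal.
#'
#' @param columns data frame (or tibble) with character columns `aa_a` and
#'   `aa_b`; `NA` marks a gap.
#' @param gap gap penalty per gap-containing column (default -11).
#' @return numeric score.
#' @export
#' @examples
#' pam250_score(data.frame(aa_a = c("W", NA), aa_b = c("W", "K"))) # 17 - 11
pam250_score <- function(columns, gap = -11) {
  if (nrow(columns) == 0L) return(0)
  a <- columns$aa_a; b <- columns$aa_b
  if (any(is.na(a) & is.na(b))) abort("a column cannot be gap against gap")
  gapped <- is.na(a) | is.na(b)
  m <- pam250_matrix()
  known <- rownames(m)
  res <- c(a[!gapped], b[!gapped])
  if (!all(res %in% known)) {
    abort(paste0("unknown residue letter(s): ",
                 paste(setdiff(unique(res), known), collapse = ", ")),
          class = "domex_bad_residue")
  }
  sum(m[cbind(a[!gapped], b[!gapped])]) + gap * sum(gapped)
}

# Expand a structural alignment into explicit columns including internal
# gaps (between the first and last aligned pair on each chain). NA marks a
# gapped side.
alignment_columns <- function(aln, A, B) {
  p <- aln$pairs
  cols <- list()
  for (k in seq_len(nrow(p))) {
    if (k > 1L) {
      ga <- (p$index_a[k - 1] + 1L):(p$index_a[k] - 1L)
      if (p$index_a[k] - p$index_a[k - 1] > 1L) {
        cols[[length(cols) + 1L]] <- tibble::tibble(
          index_a = ga, index_b = NA_integer_,
          aa_a = A$residues$aa[ga], aa_b = NA_character_
        )
      }
      gb <- (p$index_b[k - 1] + 1L):(p$index_b[k] - 1L)
      if (p$index_b[k] - p$index_b[k - 1] > 1L) {
        cols[[length(cols) + 1L]] <- tibble::tibble(
          index_a = NA_integer_, index_b = gb,
          aa_a = NA_character_, aa_b = B$residues$aa[gb]
        )
      }
    }
    cols[[length(cols) + 1L]] <- tibble::tibble(
      index_a = p$index_a[k], index_b = p$index_b[k],
      aa_a = p$aa_a[k], aa_b = p$aa_b[k]
    )
  }
  dplyr::bind_rows(cols)
}

#' Shell-vs-rest sequence similarity of an aligned pair
#'
#' Tests whether the neighborhood of the shared functional sites is better
#' conserved than the remainder of the aligned region. Alignment columns
#' (including internal gap columns) are partitioned by whether the
#' membrane-side residue belongs to the first or second shell of the common
#' functional sites (site columns count as shell; columns with no
#' membrane-side residue fall to rest), and each part is scored with
#' [pam250_score()]. By construction `shell_score + rest_score` equals the
#' whole-alignment score.
#'
#' @param aln a `structural_alignment`.
#' @param sites_a,sites_b [functional_sites()] of the two structures.
#' @param A,B the two [protein_structure()] objects; `A` is the
#'   membrane-side structure whose shells are used.
#' @param radius shell radius in Angstrom (default 5).
#' @param gap gap penalty (default -11).
#' @return an object of class `shell_similarity`: `shell_score`,
#'   `rest_score`, per-column means, column counts, the conserved site
#'   table, and a per-column audit tibble.
#' @export
shell_vs_rest <- function(aln, sites_a, sites_b, A, B, radius = 5, gap = -11) {
  conserved <- conserved_functional_residues(aln, sites_a, sites_b, A, B)
  if (nrow(conserved) == 0L) {
    abort("no conserved functional residues: shells undefined",
          class = "domex_no_conserved_sites")
  }
  part <- shells(A, conserved$index_a, radius = radius)
  shell_idx <- c(part$site_residues, part$first_shell, part$second_shell)
  cols <- alignment_columns(aln, A, B) |>
    dplyr::mutate(in_shell = !is.na(.data$index_a) & .data$index_a %in% shell_idx)
  shell_cols <- dplyr::filter(cols, .data$in_shell)
  rest_cols <- dplyr::filter(cols, !.data$in_shell)
  shell_score <- pam250_score(shell_cols, gap = gap)
  rest_score <- pam250_score(rest_cols, gap = gap)
  structure(list(
    shell_score = shell_score,
    rest_score = rest_score,
    shell_columns = nrow(shell_cols),
    rest_columns = nrow(rest_cols),
    shell_per_column = if (nrow(shell_cols)) shell_score / nrow(shell_cols) else NA_real_,
    rest_per_column = if (nrow(rest_cols)) rest_score / nrow(rest_cols) else NA_real_,
    conserved_sites = conserved,
    partition = part,
    columns = cols
  ), class = "shell_similarity")
}

#' @export
print.shell_similarity <- function(x, ...) {
  cat(sprintf(
    "<shell_similarity> shell %0.1f over %d columns (%.2f/col) vs rest %0.1f over %d columns (%.2f/col); %d conserved site(s)\n",
    x$shell_score, x$shell_columns, x$shell_per_column,
    x$rest_score, x$rest_columns, x$rest_per_column,
    nrow(x$conserved_sites)))
  invisible(x)
}

#' @rdname tidy_domex
#' @method glance shell_similarity
#' @export
glance.shell_similarity <- function(x, ...) {
  tibble::tibble(
    shell_score = x$shell_score, rest_score = x$rest_score,
    shell_columns = x$shell_columns, rest_columns = x$rest_columns,
    shell_per_column = x$shell_per_column, rest_per_column = x$rest_per_column,
    n_conserved_sites = nrow(x$conserved_sites)
  )
}
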