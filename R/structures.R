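#' Protein structure objects
#'
#' A `protein_structure` holds one chain's C-alpha trace: an ordered residue
#' table with a 1-based ordinal `index`, the author residue number
#' (`seq_num`, carried only for reporting and functional-site matching), the
#' one-letter amino acid (`aa`, `X` for unknown) and the C-alpha coordinates
#' in Angstrom. All geometry in the package works on the ordinal index, so
#' gaps or insertion codes in author numbering never affect computation.
#'
#' @param id chain identifier, e.g. `"1PNT_A"`.
#' @param sequence one-letter amino acid string or character vector.
#' @param coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param seq_num optional integer author numbering (strictly increasing);
#'   defaults to `1:N`.
#'
#' @return an object of class `protein_structure` with fields `id` and
#'   `residues` (a tibble with columns `index`, `seq_num`, `aa`, `x`, `y`,
#'   `z`).
#' @export
#' @examples
#' helix <- make_helix(12)
#' ps <- protein_structure("toy_A", strrep("A", 12), helix$coords)
#' ps
protein_structure <- function(id, sequence, coords, seq_num = NULL) {
  if (is.character(sequence) && length(sequence) == 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  coords <- as.matrix(coords)
  n <- length(sequence)
  if (n < 1L) abort("a protein structure needs at least one residue", class = "domex_empty_structure")
  if (!is.numeric(coords) || ncol(coords) != 3L || nrow(coords) != n) {
    abort("`coords` must be a numeric N x 3 matrix matching the sequence length")
  }
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  bad <- setdiff(unique(sequence), c(AA_LETTERS, "X"))
  if (length(bad) > 0) {
    abort(paste0("unknown amino acid letter(s): ", paste(bad, collapse = ", ")),
          class = "domex_bad_residue")
  }
  seq_num <- seq_num %||% seq_len(n)
  if (length(seq_num) != n || any(diff(seq_num) <= 0)) {
    abort("`seq_num` must be strictly increasing and match the residue count")
  }
  residues <- tibble::tibble(
    index = seq_len(n),
    seq_num = as.integer(seq_num),
    aa = as.character(sequence),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  structure(list(id = id, residues = residues), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, ": ", nrow(x$residues), " residues\n", sep = "")
  cat("  sequence: ", abbreviate_seq(structure_sequence(x)), "\n", sep = "")
  invisible(x)
}

abbreviate_seq <- function(s, width = 50) {
  if (nchar(s) <= width) s else paste0(substr(s, 1, width - 3), "...")
}

#' Accessors for protein structures
#'
#' `structure_sequence()` returns the one-letter sequence,
#' `structure_coords()` the N x 3 C-alpha coordinate matrix,
#' `structure_length()` the residue count.
#'
#' @param x a `protein_structure`.
#' @return a string, matrix, or integer respectively.
#' @export
structure_sequence <- function(x) paste(x$residues$aa, collapse = "")

#' @rdname structure_sequence
#' @export
structure_coords <- function(x) {
  m <- as.matrix(x$residues[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' @rdname structure_sequence
#' @export
structure_length <- function(x) nrow(x$residues)

#' Membrane annotation (slab geometry plus residue topology)
#'
#' Describes the membrane frame of one membrane-protein chain, emulating what
#' PDBTM and TMHMM provide: a rigid transform into the membrane frame (the
#' membrane normal is the z-axis after transformation), the two slab surfaces
#' `z_lower < z_upper`, and a per-residue region label in
#' `c("TM", "inside", "outside")` aligned with the structure's ordinal index.
#'
#' @param rotation 3 x 3 proper orthonormal matrix mapping structure
#'   coordinates into the membrane frame.
#' @param translation length-3 numeric, Angstrom.
#' @param z_lower,z_upper slab surfaces in the membrane frame, Angstrom.
#' @param region character vector of per-residue labels.
#' @return an object of class `membrane_annotation`.
#' @export
membrane_annotation <- function(rotation, translation, z_lower, z_upper, region) {
  rotation <- as.matrix(rotation)
  if (!is_proper_rotation(rotation, tol = 1e-6)) {
    abort("`rotation` must be proper orthonormal (det +1)", class = "domex_bad_rotation")
  }
  rotation <- orthonormalize_rotation(rotation)
  if (length(translation) != 3L || !all(is.finite(translation))) {
    abort("`translation` must be a finite 3-vector")
  }
  if (!(z_lower < z_upper)) abort("`z_lower` must be below `z_upper`")
  region <- as.character(region)
  bad <- setdiff(unique(region), c("TM", "inside", "outside"))
  if (length(bad) > 0) abort("region labels must be TM, inside or outside")
  structure(
    list(rotation = rotation, translation = as.numeric(translation),
         z_lower = z_lower, z_upper = z_upper, region = region),
    class = "membrane_annotation"
  )
}

#' @export
print.membrane_annotation <- function(x, ...) {
  tab <- table(factor(x$region, levels = c("TM", "inside", "outside")))
  cat("<membrane_annotation> slab [", x$z_lower, ", ", x$z_upper, "] A; ",
      length(x$region), " residues (TM ", tab[["TM"]], ", inside ",
      tab[["inside"]], ", outside ", tab[["outside"]], ")\n", sep = "")
  invisible(x)
}

# Check an annotation against a structure: length match and the TM z-range
# invariant (TM C-alpha within the slab plus a 3 A tolerance for helix ends).
validate_annotation <- function(structure, annot, tol = 3) {
  n <- structure_length(structure)
  if (length(annot$region) != n) {
    abort("annotation region length does not match residue count",
          class = "domex_annotation_mismatch")
  }
  z <- membrane_frame_coords(structure, annot)[, 3]
  tm <- annot$region == "TM"
  if (any(tm) &&
      (min(z[tm]) < annot$z_lower - tol || max(z[tm]) > annot$z_upper + tol)) {
    abort("a TM-labelled residue lies outside the membrane slab (+/- 3 A)",
          class = "domex_annotation_mismatch")
  }
  invisible(TRUE)
}

#' Functional site set (catalytic residues)
#'
#' Catalytic residues of one structure in the two-column form used by the
#' Catalytic Site Atlas: author residue number plus one-letter amino acid.
#'
#' @param structure_id chain identifier the sites belong to.
#' @param seq_num integer author residue numbers.
#' @param aa one-letter amino acids, same length.
#' @return an object of class `functional_sites` (a tibble with columns
#'   `seq_num`, `aa` and a `structure_id` attribute).
#' @export
#' @examples
#' functional_sites("1PNT_A", c(12, 17), c("C", "C"))
functional_sites <- function(structure_id, seq_num = integer(), aa = character()) {
  if (length(seq_num) != length(aa)) abort("`seq_num` and `aa` lengths differ")
  bad <- setdiff(unique(aa), c(AA_LETTERS, "X"))
  if (length(bad) > 0) {
    abort(paste0("unknown amino acid letter(s): ", paste(bad, collapse = ", ")),
          class = "domex_bad_residue")
  }
  out <- tibble::tibble(seq_num = as.integer(seq_num), aa = as.character(aa))
  attr(out, "structure_id") <- structure_id
  class(out) <- c("functional_sites", class(out))
  out
}

#' Secondary-structure string
#'
#' A per-residue H/E/C string (helix / strand / coil), e.g. PSIPRED output
#' reduced to three states, tied to a structure id.
#'
#' @param structure_id identifier of the source chain (or sequence).
#' @param ss character string over `H`, `E`, `C`.
#' @return an object of class `ss_string`.
#' @export
ss_string <- function(structure_id, ss) {
  if (!is.character(ss) || length(ss) != 1L || nchar(ss) < 1L) {
    abort("`ss` must be a non-empty string")
  }
  bad <- setdiff(unique(strsplit(ss, "")[[1]]), c("H", "E", "C"))
  if (length(bad) > 0) {
    abort(paste0("illegal secondary-structure character(s): ",
                 paste(bad, collapse = ", ")), class = "domex_bad_ss")
  }
  structure(list(structure_id = structure_id, ss = ss), class = "ss_string")
}

#' @export
print.ss_string <- function(x, ...) {
  cat("<ss_string> ", x$structure_id, ": ", abbreviate_seq(x$ss), " (",
      nchar(x$ss), " residues)\n", sep = "")
  invisible(x)
}
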