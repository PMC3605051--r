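# IO for all external representations: PDB coordinates, membrane-annotation
# JSON sidecars, CSA-style site lists, H/E/C secondary-structure files and
# TSV reports.

# Three-letter -> one-letter translation, MSE read as M (selenomethionine).
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

#' Read one chain of a PDB coordinate file as a C-alpha trace
#'
#' Parses ATOM records (plus HETATM records for MSE, read as methionine) of
#' the requested chain, first model only. Alternate locations are resolved
#' to the highest occupancy (ties: first in file order); residues lacking a
#' C-alpha atom are skipped with a warning. Residues are kept in author
#' order; insertion-coded residues stay in file order and share renumbered
#' internal ordinals.
#'
#' @param path PDB file path.
#' @param chain single chain identifier (e.g. `"A"`).
#' @return a [protein_structure()].
#' @export
read_pdb_chain <- function(path, chain) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "domex_missing_file")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  if (!chain %in% unique(at$chain)) {
    abort(paste0("chain '", chain, "' not present in ", path),
          class = "domex_missing_chain")
  }
  at <- at[at$chain == chain & at$elety == "CA" &
             (at$type == "ATOM" | (at$type == "HETATM" & at$resid == "MSE")), ,
           drop = FALSE]
  if (nrow(at) == 0L) {
    abort(paste0("chain '", chain, "' has no C-alpha residues"),
          class = "domex_no_calpha")
  }
  # resolve altlocs per residue (resno + insert): highest occupancy, ties first
  ins <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  key <- paste(at$resno, ins, sep = "_")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
                        function(i) {
                          occ <- at$o[i]
                          occ[is.na(occ)] <- 1
                          i[which.max(occ)]
                        }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  aa <- unname(AA3TO1[at$resid])
  unknown <- is.na(aa)
  if (any(unknown)) {
    warn(paste0("residue(s) with non-standard type read as X: ",
                paste(unique(at$resid[unknown]), collapse = ", ")))
    aa[unknown] <- "X"
  }
  # author numbering must be non-decreasing for the internal seq_num to stay
  # strictly increasing; insertion codes share the author number so we
  # renumber duplicates by file order offset into a strictly increasing key.
  seq_num <- at$resno
  if (anyDuplicated(seq_num)) {
    # insertion codes duplicate the author number; re-rank in file order so
    # the internal numbering stays strictly increasing and deterministic
    seq_num <- rank(seq_num, ties.method = "first") + min(at$resno) - 1L
  }
  protein_structure(
    id = paste0(sub("\\.pdb$", "", basename(path)), "_", chain),
    sequence = aa,
    coords = cbind(at$x, at$y, at$z),
    seq_num = seq_num
  )
}

#' Write a C-alpha trace as a PDB coordinate file
#'
#' Serializes a [protein_structure()] as single-chain ATOM records (one CA
#' atom per residue, occupancy 1.00). Coordinates are written at the PDB's
#' fixed 3-decimal precision.
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @param chain chain identifier to write (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(structure, path, chain = "A") {
  res <- structure$residues
  aa3 <- names(AA3TO1)[match(res$aa, AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    res$index, aa3, chain, res$seq_num, res$x, res$y, res$z
  )
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read and write membrane-annotation JSON sidecars
#'
#' The sidecar is a small JSON document with keys `rotation` (3 x 3,
#' row-major), `translation`, `z_lower`, `z_upper` and `region`, standing in
#' for the PDBTM membrane frame plus TMHMM-style topology labels. Rotations
#' within 1e-6 of orthonormal are re-orthonormalized; anything further off
#' is rejected.
#'
#' @param path JSON file path.
#' @return `read_membrane_annotation()` returns a [membrane_annotation()];
#'   `write_membrane_annotation()` returns `path` invisibly.
#' @export
read_membrane_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("annotation file not found: ", path), class = "domex_missing_file")
  }
  doc <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) abort(paste0("malformed JSON: ", conditionMessage(e)),
                                            class = "domex_bad_json"))
  need <- c("rotation", "translation", "z_lower", "z_upper", "region")
  missing <- setdiff(need, names(doc))
  if (length(missing) > 0) {
    abort(paste0("annotation JSON lacks key(s): ", paste(missing, collapse = ", ")),
          class = "domex_bad_json")
  }
  rot <- doc$rotation
  rot <- if (is.matrix(rot)) rot else matrix(unlist(rot), 3, 3, byrow = TRUE)
  membrane_annotation(
    rotation = rot,
    translation = doc$translation,
    z_lower = doc$z_lower, z_upper = doc$z_upper,
    region = doc$region
  )
}

#' @rdname read_membrane_annotation
#' @param annot a `membrane_annotation`.
#' @export
write_membrane_annotation <- function(annot, path) {
  doc <- list(
    rotation = unname(lapply(seq_len(3), function(i) annot$rotation[i, ])),
    translation = annot$translation,
    z_lower = annot$z_lower, z_upper = annot$z_upper,
    region = annot$region
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CSA-style functional-site list
#'
#' Two-column tab-separated text: author residue number and one-letter amino
#' acid, one site per line. An empty file yields an empty (legal) site set.
#'
#' @param path TSV file path.
#' @param structure_id identifier recorded on the site set (default: file
#'   stem).
#' @return a [functional_sites()] object.
#' @export
read_sites <- function(path, structure_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) {
    abort(paste0("site file not found: ", path), class = "domex_missing_file")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(functional_sites(structure_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) abort("site lines must be 'seq_num<TAB>aa'")
  functional_sites(
    structure_id,
    seq_num = as.integer(vapply(parts, `[[`, "", 1L)),
    aa = vapply(parts, `[[`, "", 2L)
  )
}

#' @rdname read_sites
#' @param sites a `functional_sites` object.
#' @export
write_sites <- function(sites, path) {
  writeLines(sprintf("%d\t%s", sites$seq_num, sites$aa), path)
  invisible(path)
}

#' Read and write H/E/C secondary-structure files
#'
#' FASTA-like text: an optional `>` header carrying the structure id,
#' followed by the H/E/C body on one or more lines.
#'
#' @param path file path.
#' @return `read_ss()` returns an [ss_string()].
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("secondary-structure file not found: ", path),
          class = "domex_missing_file")
  }
  lines <- readLines(path)
  id <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) > 0 && startsWith(lines[1], ">")) {
    id <- trimws(sub("^>", "", lines[1]))
    lines <- lines[-1]
  }
  ss_string(id, paste(trimws(lines), collapse = ""))
}

#' @rdname read_ss
#' @param ss an `ss_string` object.
#' @export
write_ss <- function(ss, path) {
  writeLines(c(paste0(">", ss$structure_id), ss$ss), path)
  invisible(path)
}

#' Write and read TSV reports
#'
#' All pipeline reports are tab-separated tables with a header row. Numeric
#' fields round-trip losslessly at full double precision.
#'
#' @param rows a data frame.
#' @param path output TSV path.
#' @return `write_report()` returns `path` invisibly; `read_report()` a
#'   tibble.
#' @export
write_report <- function(rows, path) {
  readr::write_tsv(tibble::as_tibble(rows), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
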