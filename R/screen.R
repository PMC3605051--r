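# Selection pipeline: similarity thresholds, transmembrane-overlap removal,
# disconnected-loop removal, topology side assignment, redundancy reduction
# at 30% identity, and the 90% domain-coverage annotation rule.

#' Default screening thresholds
#'
#' The similarity thresholds are the published selection cutoffs (RMSD
#' < 5 Angstrom, aligned length > 100 residues, TM-score > 0.5, all strict).
#' `min_extramembrane` (retain pairs whose aligned membrane-protein residues
#' are >= 90% non-TM) and `dominant_segment` (a pair is "disconnected" when
#' no single extramembrane segment holds >= 80% of the aligned residues) are
#' this package's operationalization of the published removal rules and are
#' configurable.
#'
#' @param rmsd,min_length,min_tm similarity thresholds.
#' @param min_extramembrane minimum non-TM fraction of aligned residues.
#' @param dominant_segment minimum dominant-segment fraction.
#' @param redundancy percent-identity threshold for redundancy reduction.
#' @param coverage domain-coverage fraction for annotation transfer.
#' @return a named list of thresholds.
#' @export
screen_config <- function(rmsd = 5.0, min_length = 100L, min_tm = 0.5,
                          min_extramembrane = 0.9, dominant_segment = 0.8,
                          redundancy = 30, coverage = 0.9) {
  stopifnot(rmsd > 0, min_length > 0, min_tm > 0,
            min_extramembrane > 0, min_extramembrane <= 1,
            dominant_segment > 0, dominant_segment <= 1,
            redundancy > 0, coverage > 0, coverage <= 1)
  list(rmsd = rmsd, min_length = min_length, min_tm = min_tm,
       min_extramembrane = min_extramembrane,
       dominant_segment = dominant_segment,
       redundancy = redundancy, coverage = coverage)
}

#' Similarity filter on alignment statistics
#'
#' A pair passes when RMSD < 5 Angstrom AND aligned length > 100 residues
#' AND TM-score > 0.5, all inequalities strict as printed. Works on a
#' [align_structures()] result or anything with `rmsd`, `aligned_length`
#' and `tm_score` fields.
#'
#' @param aln a `structural_alignment` (or list with the three fields).
#' @param config thresholds from [screen_config()].
#' @return list with `passed` (logical) and `reasons` (character subset of
#'   `c("rmsd", "length", "tmscore")`, empty iff passed).
#' @export
passes_similarity_filter <- function(aln, config = screen_config()) {
  reasons <- character()
  if (!(aln$rmsd < config$rmsd)) reasons <- c(reasons, "rmsd")
  if (!(aln$aligned_length > config$min_length)) reasons <- c(reasons, "length")
  if (!(aln$tm_score > config$min_tm)) reasons <- c(reasons, "tmscore")
  list(passed = length(reasons) == 0L, reasons = reasons)
}

# Region labels of the membrane-side residues of an alignment.
aligned_regions <- function(aln, annot, membrane_side = c("a", "b")) {
  membrane_side <- match.arg(membrane_side)
  n <- if (membrane_side == "a") aln$n_a else aln$n_b
  if (length(annot$region) != n) {
    abort("annotation region length does not match the membrane-side chain",
          class = "domex_annotation_mismatch")
  }
  idx <- if (membrane_side == "a") aln$pairs$index_a else aln$pairs$index_b
  list(idx = idx, region = annot$region[idx])
}

#' Fraction of aligned membrane-protein residues outside the membrane
#'
#' Structure pairs whose shared region lies within the transmembrane segment
#' are artifacts of the bilayer-spanning architecture, not shared domains;
#' pairs are removed downstream when this fraction falls below
#' `min_extramembrane` (default 0.9).
#'
#' @param aln a `structural_alignment`.
#' @param annot [membrane_annotation()] of the membrane-side structure.
#' @param membrane_side which side of the alignment is the membrane protein.
#' @return fraction in 0-1 of aligned membrane residues labelled non-TM.
#' @export
extramembrane_fraction <- function(aln, annot, membrane_side = "a") {
  ar <- aligned_regions(aln, annot, membrane_side)
  mean(ar$region != "TM")
}

#' Disconnected-loop test
#'
#' Aligned extramembrane residues are grouped into maximal chain runs
#' separated by TM segments. The pair is flagged disconnected (and removed)
#' when no single run contains at least `dominant_segment` (default 80%) of
#' the aligned extramembrane residues: several short loops cannot act as one
#' independent domain.
#'
#' @inheritParams extramembrane_fraction
#' @param dominant_segment dominance threshold in 0-1.
#' @return `TRUE` when the pair should be removed.
#' @export
is_disconnected <- function(aln, annot, membrane_side = "a",
                            dominant_segment = 0.8) {
  ar <- aligned_regions(aln, annot, membrane_side)
  keep <- ar$region != "TM"
  if (!any(keep)) return(TRUE)
  # extramembrane segment id per chain position: runs of non-TM labels
  r <- rle(annot$region == "TM")
  seg_id <- rep(cumsum(!r$values) * (!r$values), r$lengths)
  counts <- table(seg_id[ar$idx[keep]])
  max(counts) / sum(counts) < dominant_segment
}

#' Topology side of the shared domain
#'
#' Majority inside/outside label among the aligned non-TM membrane-protein
#' residues; ties resolve to "outside" with a warning.
#'
#' @inheritParams extramembrane_fraction
#' @return `"inside"` or `"outside"`.
#' @export
assign_side <- function(aln, annot, membrane_side = "a") {
  ar <- aligned_regions(aln, annot, membrane_side)
  lab <- ar$region[ar$region != "TM"]
  if (length(lab) == 0L) {
    abort("no aligned extramembrane residues: side undefined",
          class = "domex_no_extramembrane")
  }
  n_in <- sum(lab == "inside"); n_out <- sum(lab == "outside")
  if (n_in == n_out) {
    warn("inside/outside tie; assigning 'outside'")
    return("outside")
  }
  if (n_in > n_out) "inside" else "outside"
}

#' Full screening decision for one aligned pair
#'
#' Applies the similarity filter, the TM-overlap rule and the
#' disconnected-loop rule, and assigns the topology side for passing pairs.
#'
#' @inheritParams extramembrane_fraction
#' @param config thresholds from [screen_config()].
#' @return one-row tibble: `id_a`, `id_b`, `passed`, `reasons`
#'   (comma-separated rule ids from rmsd/length/tmscore/tm_overlap/
#'   disconnected, empty iff passed), `side` (NA unless passed),
#'   `extramembrane_fraction`, plus the alignment statistics.
#' @export
screen_pair <- function(aln, annot, membrane_side = "a",
                        config = screen_config()) {
  sim <- passes_similarity_filter(aln, config)
  reasons <- sim$reasons
  emf <- extramembrane_fraction(aln, annot, membrane_side)
  if (emf < config$min_extramembrane) reasons <- c(reasons, "tm_overlap")
  if (is_disconnected(aln, annot, membrane_side, config$dominant_segment)) {
    reasons <- c(reasons, "disconnected")
  }
  passed <- length(reasons) == 0L
  side <- if (passed) assign_side(aln, annot, membrane_side) else NA_character_
  tibble::tibble(
    id_a = aln$id_a, id_b = aln$id_b,
    passed = passed,
    reasons = paste(reasons, collapse = ","),
    side = side,
    extramembrane_fraction = emf,
    aligned_length = aln$aligned_length,
    rmsd = aln$rmsd,
    tm_score = aln$tm_score,
    seq_identity = aln$seq_identity
  )
}

#' Pairwise global sequence identity (PAM-250, linear gap -11)
#'
#' Global alignment under the same scoring convention used for the
#' shell-conservation statistic; identity is identical positions over
#' alignment columns.
#'
#' @param seq_a,seq_b one-letter sequences (strings).
#' @return percent identity in 0-100.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = pam250_matrix(), type = "global",
    gapOpening = 0, gapExtension = 11
  )
  Biostrings::pid(aln, type = "PID1")
}

#' Greedy redundancy reduction at a sequence-identity threshold
#'
#' Structures are sorted by length (descending; ties by id) and assigned
#' greedily: a sequence joins the first existing representative to which its
#' global-alignment identity strictly exceeds `threshold` percent, otherwise
#' it founds a new representative. Mirrors the role of a PISCES-style
#' culling at 30% identity without reproducing its PSI-BLAST machinery.
#'
#' @param structures list of [protein_structure()] objects (or a named
#'   character vector of sequences).
#' @param threshold percent identity (default 30; strictly greater merges).
#' @return tibble with columns `id`, `representative`, `identity` (identity
#'   to the representative; `NA` for representatives themselves).
#' @export
reduce_redundancy <- function(structures, threshold = 30) {
  if (length(structures) == 0L) abort("need at least one structure")
  if (is.character(structures)) {
    ids <- names(structures) %||% paste0("seq", seq_along(structures))
    seqs <- unname(structures)
  } else {
    ids <- vapply(structures, function(s) s$id, "")
    seqs <- vapply(structures, structure_sequence, "")
  }
  ord <- order(-nchar(seqs), ids)
  reps <- integer()
  out_rep <- character(length(seqs)); out_id <- numeric(length(seqs))
  for (i in ord) {
    assigned <- FALSE
    for (r in reps) {
      idy <- pairwise_identity(seqs[i], seqs[r])
      if (idy > threshold) {
        out_rep[i] <- ids[r]; out_id[i] <- idy
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      out_rep[i] <- ids[i]; out_id[i] <- NA_real_
    }
  }
  tibble::tibble(id = ids, representative = out_rep, identity = out_id)
}

#' Domain annotation by aligned coverage
#'
#' A domain label transfers onto the alignment only when the aligned region
#' covers strictly more than `coverage` (default 90%) of the domain length.
#'
#' @param aligned_indices integer residue indices covered by the alignment
#'   on the annotated structure.
#' @param domains data frame with columns `start`, `end`, `label`
#'   (inclusive ordinal residue ranges).
#' @param n_residues chain length, used for bounds checking.
#' @param coverage coverage threshold in 0-1.
#' @return the input `domains` as a tibble with added `covered` (count),
#'   `coverage` (fraction) and `annotated` (logical).
#' @export
assign_domain_annotation <- function(aligned_indices, domains, n_residues,
                                     coverage = 0.9) {
  domains <- tibble::as_tibble(domains)
  if (any(domains$start > domains$end)) {
    abort("inverted domain range", class = "domex_bad_range")
  }
  if (any(domains$start < 1L) || any(domains$end > n_residues)) {
    abort("domain range outside structure bounds", class = "domex_bad_range")
  }
  aligned_indices <- unique(aligned_indices)
  domains |>
    dplyr::mutate(
      covered = purrr::map2_int(.data$start, .data$end,
                                ~ sum(aligned_indices >= .x & aligned_indices <= .y)),
      coverage = .data$covered / (.data$end - .data$start + 1),
      annotated = .data$coverage > !!coverage
    )
}
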