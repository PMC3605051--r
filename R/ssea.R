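# Secondary structure element alignment (SSEA): element extraction, the
# 0-100 element-alignment score, resampling-based cutoff training, and the
# probability-of-structural-similarity curve.

#' Run-length encode a secondary-structure string
#'
#' Maximal runs of H/E/C become elements `(type, length)` in order.
#'
#' @param ss an [ss_string()] or a plain H/E/C string.
#' @return an object of class `ss_elements`: tibble with columns `type`,
#'   `length`.
#' @export
#' @examples
#' extract_elements("HHHHCCEEE")
extract_elements <- function(ss) {
  s <- if (inherits(ss, "ss_string")) ss$ss else ss
  if (!is.character(s) || length(s) != 1L || nchar(s) < 1L) {
    abort("`ss` must be a non-empty string")
  }
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c("H", "E", "C"))
  if (length(bad) > 0) {
    abort(paste0("illegal secondary-structure character(s): ",
                 paste(bad, collapse = ", ")), class = "domex_bad_ss")
  }
  r <- rle(chars)
  out <- tibble::tibble(type = r$values, length = r$lengths)
  class(out) <- c("ss_elements", class(out))
  out
}

#' Expand elements back to a string
#' @param elements an `ss_elements` tibble.
#' @return the H/E/C string.
#' @export
expand_elements <- function(elements) {
  paste(strrep(elements$type, elements$length), collapse = "")
}

as_elements <- function(x) {
  if (inherits(x, "ss_elements")) x else extract_elements(x)
}

#' SSEA score between two secondary-structure element sequences
#'
#' Global DP over the run-length-encoded element sequences: pairing two
#' elements of the same type contributes the shorter element length; any
#' cross-type pairing or gap contributes zero. The summed match `S` is
#' normalized to `100 * 2 S / (L_A + L_B)` where `L` are the residue
#' counts, giving a percentage-like 0-100 similarity that is 100 exactly
#' for identical strings and 0 when no same-type pairing exists.
#'
#' @param a,b [ss_string()] objects, H/E/C strings, or `ss_elements`.
#' @return numeric score in `[0, 100]`.
#' @export
#' @examples
#' ssea_score("HHHHCCEEE", "HHHHCCEEE") # 100
ssea_score <- function(a, b) {
  ea <- as_elements(a); eb <- as_elements(b)
  if (nrow(ea) == 0L || nrow(eb) == 0L) abort("empty element sequence")
  n <- nrow(ea); m <- nrow(eb)
  W <- outer(seq_len(n), seq_len(m), function(i, j) {
    ifelse(ea$type[i] == eb$type[j], pmin(ea$length[i], eb$length[j]), 0)
  })
  M <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j] + W[i, j], M[i, j + 1], M[i + 1, j])
    }
  }
  100 * 2 * M[n + 1, m + 1] / (sum(ea$length) + sum(eb$length))
}

#' Train the SSEA classification cutoff by resampling
#'
#' Emulates the published protocol: per replicate, `n_sample` pairs are
#' drawn without replacement from the positive set (structurally similar
#' pairs) and from the negative set (dissimilar pairs); integer cutoffs
#' 0-100 are scanned classifying `score >= c` as positive and the smallest
#' cutoff maximizing balanced accuracy is recorded. The final cutoff is the
#' mode of the replicate cutoffs (ties: smallest). The separation p-value is
#' a Mann-Whitney test on the full pooled score sets.
#'
#' @param pos_scores,neg_scores numeric SSEA scores of the positive and
#'   negative training pairs.
#' @param n_sample pairs sampled per set per replicate (default 100).
#' @param reps number of replicates (default 1000).
#' @param seed RNG seed.
#' @return an object of class `ssea_cutoff`: `cutoff`,
#'   `replicate_cutoffs` (length `reps`), `p_value`, `balanced_accuracy`
#'   (at the final cutoff on the full sets), `n_sample`, `reps`.
#' @export
train_ssea_cutoff <- function(pos_scores, neg_scores, n_sample = 100L,
                              reps = 1000L, seed = 1L) {
  if (length(pos_scores) < n_sample || length(neg_scores) < n_sample) {
    abort("both sets need at least `n_sample` scored pairs",
          class = "domex_insufficient_pairs")
  }
  cutoffs <- 0:100
  chosen <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      sp <- sample(pos_scores, n_sample)
      sn <- sample(neg_scores, n_sample)
      sens <- colMeans(outer(sp, cutoffs, ">="))
      spec <- colMeans(outer(sn, cutoffs, "<"))
      ba <- (sens + spec) / 2
      cutoffs[which.max(ba)]       # which.max takes the smallest tie
    }, integer(1))
  })
  tab <- table(chosen)
  final <- as.integer(names(tab)[which.max(tab)])  # ties: smallest label
  mw <- mann_whitney_u(pos_scores, neg_scores)
  ba_final <- (mean(pos_scores >= final) + mean(neg_scores < final)) / 2
  structure(list(cutoff = final, replicate_cutoffs = chosen,
                 p_value = mw$p_value, balanced_accuracy = ba_final,
                 n_sample = n_sample, reps = reps, seed = seed),
            class = "ssea_cutoff")
}

#' @export
print.ssea_cutoff <- function(x, ...) {
  cat(sprintf(
    "<ssea_cutoff> trained cutoff %d (%d reps x %d pairs/set); balanced accuracy %.3f; separation p = %.3g\n",
    x$cutoff, x$reps, x$n_sample, x$balanced_accuracy, x$p_value))
  invisible(x)
}

#' @rdname tidy_domex
#' @method tidy ssea_cutoff
#' @export
tidy.ssea_cutoff <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicate_cutoffs),
                 cutoff = x$replicate_cutoffs)
}

#' @rdname tidy_domex
#' @method glance ssea_cutoff
#' @export
glance.ssea_cutoff <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, p_value = x$p_value,
                 balanced_accuracy = x$balanced_accuracy,
                 n_sample = x$n_sample, reps = x$reps)
}

#' Probability of structural similarity per SSEA score bin
#'
#' Bins scored pairs by SSEA score and reports the empirical probability
#' that a pair in the bin is structurally similar (RMSD below
#' `rmsd_threshold`), together with a Spearman monotone-trend statistic over
#' the occupied bin midpoints. Empty bins are omitted.
#'
#' @param pairs data frame with numeric columns `score` and `rmsd` (or a
#'   logical `similar` column, which takes precedence).
#' @param bin_width score bin width (default 10).
#' @param rmsd_threshold similarity definition (default 5 Angstrom).
#' @return an object of class `ssea_curve`: tibble with `bin_mid`,
#'   `bin_lo`, `bin_hi`, `n`, `probability`; attributes `spearman_rho` and
#'   `bin_width`.
#' @export
probability_curve <- function(pairs, bin_width = 10, rmsd_threshold = 5) {
  similar <- if ("similar" %in% names(pairs)) {
    as.logical(pairs$similar)
  } else {
    pairs$rmsd < rmsd_threshold
  }
  bin <- pmin(floor(pairs$score / bin_width), floor(100 / bin_width) - 1e-9)
  bin <- floor(bin)
  tab <- tibble::tibble(bin = bin, similar = similar) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(), probability = mean(.data$similar),
                     .groups = "drop") |>
    dplyr::mutate(bin_lo = .data$bin * bin_width,
                  bin_hi = (.data$bin + 1) * bin_width,
                  bin_mid = .data$bin_lo + bin_width / 2) |>
    dplyr::select("bin_mid", "bin_lo", "bin_hi", "n", "probability")
  rho <- if (nrow(tab) > 2) {
    suppressWarnings(cor(tab$bin_mid, tab$probability, method = "spearman"))
  } else {
    NA_real_
  }
  attr(tab, "spearman_rho") <- rho
  attr(tab, "bin_width") <- bin_width
  class(tab) <- c("ssea_curve", class(tab))
  tab
}
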