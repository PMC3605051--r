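# In-code fixtures shared by the screening / funcsites tests.

# Minimal structural_alignment stand-in with just the fields the screening
# rules consume.
fake_alignment <- function(index_a, index_b = index_a,
                           aa_a = rep("A", length(index_a)),
                           aa_b = aa_a,
                           rmsd = 2, tm = 0.8, n_a = max(index_a),
                           n_b = max(index_b),
                           id_a = "memX_A", id_b = "solX_A") {
  structure(list(
    id_a = id_a, id_b = id_b, n_a = n_a, n_b = n_b,
    pairs = tibble::tibble(index_a = as.integer(index_a),
                           index_b = as.integer(index_b),
                           aa_a = aa_a, aa_b = aa_b,
                           dist = rep(1, length(index_a))),
    aligned_length = length(index_a),
    rmsd = rmsd, tm_score = tm, tm_score_a = tm, tm_score_b = tm,
    seq_identity = 100 * mean(aa_a == aa_b),
    superposition = NULL
  ), class = "structural_alignment")
}

# Annotation with an explicit region vector and an identity frame.
fake_annotation <- function(region, z_half = 15) {
  membrane_annotation(diag(3), c(0, 0, 0), -z_half, z_half, region)
}

# Straight chain at a fixed C-alpha spacing along x.
straight_chain <- function(n, spacing = 3.8, id = "chain_A",
                           sequence = strrep("A", n)) {
  protein_structure(id, sequence, cbind(spacing * (seq_len(n) - 1), 0, 0))
}
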