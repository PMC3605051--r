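test_that("conserved site detection needs same column and identical residue", {
  A <- straight_chain(30, id = "A_A",
                      sequence = paste(c(rep("A", 11), "C", rep("A", 4), "C",
                                         rep("A", 13)), collapse = ""))
  B <- A; B$id <- "B_A"
  aln <- fake_alignment(1:30, aa_a = A$residues$aa, aa_b = B$residues$aa,
                        id_a = "A_A", id_b = "B_A")
  sites <- functional_sites("A_A", c(12L, 17L), c("C", "C"))
  hits <- conserved_functional_residues(aln, sites, sites, A, B)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$aa, c("C", "C"))

  # empty site set is legal and yields no matches
  none <- functional_sites("A_A")
  expect_equal(nrow(conserved_functional_residues(aln, none, sites, A, B)), 0L)

  # a site aligned to a gap column cannot be conserved
  gappy <- fake_alignment(setdiff(1:30, 12L), aa_a = A$residues$aa[-12],
                          aa_b = B$residues$aa[-12])
  expect_equal(nrow(conserved_functional_residues(gappy, sites, sites, A, B)), 1L)

  # site records must match the structure
  expect_error(resolve_sites(A, functional_sites("A_A", 12L, "W")),
               class = "domex_site_mismatch")
  expect_error(resolve_sites(A, functional_sites("A_A", 99L, "C")),
               class = "domex_site_not_found")
})

test_that("shells on a straight chain match the brute-force distance table", {
  ch <- straight_chain(20)      # 3.8 A spacing: only +/-1 within 5 A
  p <- shells(ch, 10L, radius = 5)
  expect_equal(p$first_shell, c(9L, 11L))
  expect_equal(p$second_shell, c(8L, 12L))
  expect_setequal(p$rest, setdiff(1:20, 8:12))
  # partition property
  expect_equal(sort(c(p$site_residues, p$first_shell, p$second_shell, p$rest)),
               1:20)
  # sites never join shells even when mutually close
  p2 <- shells(ch, c(10L, 11L), radius = 5)
  expect_false(any(c(10L, 11L) %in% c(p2$first_shell, p2$second_shell)))
  # radius monotonicity
  p6 <- shells(ch, 10L, radius = 6)
  expect_true(all(p$first_shell %in% p6$first_shell))
  shell5 <- c(p$first_shell, p$second_shell)
  shell6 <- c(p6$first_shell, p6$second_shell)
  expect_true(all(shell5 %in% c(p6$site_residues, shell6)))
  # isolated site: no first shell
  iso <- straight_chain(5, spacing = 10)
  expect_length(shells(iso, 3L)$first_shell, 0L)
  expect_error(shells(ch, integer()), class = "domex_empty_sites")
})

test_that("PAM-250 column scoring matches the published matrix and gap rule", {
  expect_equal(pam250_score(data.frame(aa_a = "C", aa_b = "C")), 12)
  expect_equal(pam250_score(data.frame(aa_a = character(), aa_b = character())), 0)
  expect_equal(pam250_score(data.frame(aa_a = c("W", NA), aa_b = c("W", "K"))),
               17 - 11)
  expect_error(pam250_score(data.frame(aa_a = NA_character_, aa_b = NA_character_)))
  expect_error(pam250_score(data.frame(aa_a = "U", aa_b = "A")),
               class = "domex_bad_residue")
})

test_that("shell-vs-rest is additive and finds planted shell conservation", {
  mp <- make_membrane_protein(synthetic_spec(seed = 31), sites_at = c(10L, 14L))
  cp <- make_soluble_counterpart(mp, target_rmsd = 1.5, target_identity = 10,
                                 shell_conservation = TRUE, sites = mp$sites,
                                 seed = 32)
  sol_sites <- functional_sites(
    cp$structure$id,
    seq_num = match(resolve_sites(mp$structure, mp$sites), mp$domain_range),
    aa = mp$sites$aa
  )
  aln <- align_structures(mp$structure, cp$structure)
  sv <- shell_vs_rest(aln, mp$sites, sol_sites, mp$structure, cp$structure)
  expect_gt(sv$shell_per_column, sv$rest_per_column)
  # score additivity against the whole-alignment score
  whole <- pam250_score(sv$columns)
  expect_equal(sv$shell_score + sv$rest_score, whole)
  # frozen shell columns are 100% identical under the truth mapping
  frozen <- cp$frozen
  mem_idx <- mp$domain_range[frozen]
  sol_seq <- cp$structure$residues$aa
  mem_seq <- mp$structure$residues$aa
  expect_true(all(mem_seq[mem_idx] == sol_seq[frozen]))

  # self-alignment determinism: shell score equals the self-PAM sum
  self_aln <- align_structures(mp$structure, mp$structure)
  sv_self <- shell_vs_rest(self_aln, mp$sites, mp$sites,
                           mp$structure, mp$structure)
  part <- shells(mp$structure, mp$sites)
  idx <- c(part$site_residues, part$first_shell, part$second_shell)
  aa <- mp$structure$residues$aa[idx]
  expect_equal(sv_self$shell_score,
               pam250_score(data.frame(aa_a = aa, aa_b = aa)))
})
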