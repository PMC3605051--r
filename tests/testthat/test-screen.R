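test_that("the similarity filter applies the printed thresholds strictly", {
  pass <- passes_similarity_filter(list(rmsd = 3.9, aligned_length = 162, tm_score = 0.62))
  expect_true(pass$passed)
  expect_length(pass$reasons, 0)

  # boundary cases: each printed threshold is strict
  r <- passes_similarity_filter(list(rmsd = 4.9, aligned_length = 100, tm_score = 0.6))
  expect_false(r$passed); expect_equal(r$reasons, "length")
  r <- passes_similarity_filter(list(rmsd = 5.0, aligned_length = 150, tm_score = 0.51))
  expect_false(r$passed); expect_equal(r$reasons, "rmsd")
  r <- passes_similarity_filter(list(rmsd = 4.0, aligned_length = 150, tm_score = 0.5))
  expect_false(r$passed); expect_equal(r$reasons, "tmscore")
  r <- passes_similarity_filter(list(rmsd = 5.0, aligned_length = 100, tm_score = 0.5))
  expect_setequal(r$reasons, c("rmsd", "length", "tmscore"))
})

test_that("extramembrane fraction counts aligned non-TM residues", {
  region <- c(rep("outside", 100), rep("TM", 100))
  annot <- fake_annotation(region)
  # all aligned residues outside
  expect_equal(extramembrane_fraction(fake_alignment(1:100, n_a = 200), annot), 1.0)
  # all aligned residues in the membrane
  expect_equal(extramembrane_fraction(fake_alignment(101:200, n_a = 200), annot), 0.0)
  # 95 outside + 5 TM
  expect_equal(extramembrane_fraction(fake_alignment(c(1:95, 101:105), n_a = 200), annot), 0.95)
  # annotation length mismatch is an error
  expect_error(extramembrane_fraction(fake_alignment(1:10, n_a = 10), annot),
               class = "domex_annotation_mismatch")
})

test_that("disconnected-loop removal follows the dominant-segment rule", {
  # loop1 (1:50) TM (51:70) loop2 (71:120)
  region <- c(rep("outside", 50), rep("TM", 20), rep("outside", 50))
  annot <- fake_annotation(region)
  # one segment holds everything -> keep
  expect_false(is_disconnected(fake_alignment(1:50, n_a = 120), annot))
  # 50/50 split across two loops -> remove
  expect_true(is_disconnected(fake_alignment(c(1:50, 71:120), n_a = 120), annot))
  # 85/15 split -> dominant segment rule keeps it
  expect_false(is_disconnected(fake_alignment(c(1:45, 71:78), n_a = 120), annot))
})

test_that("topology side assignment is by majority with ties to outside", {
  region <- c(rep("inside", 60), rep("TM", 20), rep("outside", 70))
  annot <- fake_annotation(region)
  expect_equal(assign_side(fake_alignment(81:150, n_a = 150), annot), "outside")
  expect_equal(assign_side(fake_alignment(c(1:30, 81:150), n_a = 150), annot), "outside")
  expect_equal(assign_side(fake_alignment(c(1:60, 81:120), n_a = 150), annot), "inside")
  expect_warning(side <- assign_side(fake_alignment(c(1:30, 81:110), n_a = 150), annot))
  expect_equal(side, "outside")
  expect_error(assign_side(fake_alignment(61:80, n_a = 150), annot),
               class = "domex_no_extramembrane")
})

test_that("screening decisions are consistent and idempotent", {
  region <- c(rep("outside", 150), rep("TM", 20))
  annot <- fake_annotation(region)
  good <- fake_alignment(1:120, rmsd = 3.9, tm = 0.62, n_a = 170)
  dec <- screen_pair(good, annot)
  expect_true(dec$passed)
  expect_equal(dec$reasons, "")
  expect_equal(dec$side, "outside")
  # passed <=> no reasons, on a grid of synthetic decisions
  for (rmsd in c(3, 5.5)) for (tm in c(0.4, 0.7)) {
    d <- screen_pair(fake_alignment(1:120, rmsd = rmsd, tm = tm, n_a = 170), annot)
    expect_identical(d$passed, !nzchar(d$reasons))
  }
  # idempotence: re-screening the surviving pair set changes nothing
  alns <- list(good, fake_alignment(1:90, rmsd = 3, tm = 0.7, n_a = 170),
               fake_alignment(1:120, rmsd = 6, tm = 0.7, n_a = 170))
  first <- purrr::map_dfr(alns, screen_pair, annot = annot)
  survivors <- alns[first$passed]
  second <- purrr::map_dfr(survivors, screen_pair, annot = annot)
  expect_true(all(second$passed))
  expect_equal(second, first[first$passed, ])
})

test_that("redundancy reduction merges strictly above the identity threshold", {
  # identical sequences collapse to one representative
  s <- c(a = "ACDEFGHIKLMNPQRSTVWY", b = "ACDEFGHIKLMNPQRSTVWY")
  red <- reduce_redundancy(s)
  expect_equal(length(unique(red$representative)), 1L)

  # constructed family: b is 90% identical to a; c/d unrelated randoms
  set.seed(21)
  base <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                       40, replace = TRUE), collapse = "")
  mutate_seq <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), k)
    for (i in at) ch[i] <- sample(setdiff(c("M", "N", "P", "Q", "R"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  fam <- c(a = base, b = mutate_seq(base, 4),
           c = paste(rep("W", 40), collapse = ""),
           d = paste(rep(c("S", "T"), 20), collapse = ""))
  red <- reduce_redundancy(fam)
  expect_equal(red$representative[red$id == "b"], red$representative[red$id == "a"])
  reps <- unique(red$representative)
  expect_true(all(c("c", "d") %in% reps))
  # no representative pair exceeds the threshold (brute-force check)
  for (i in reps) for (j in reps) {
    if (i < j) expect_lte(pairwise_identity(fam[[i]], fam[[j]]), 30)
  }

  # identity exactly at the threshold must NOT merge
  e <- c(x = "AAAAAAAAAA", y = "AAACCCCCCC")  # 30% identical, same length
  expect_equal(pairwise_identity(e[["x"]], e[["y"]]), 30)
  red2 <- reduce_redundancy(e)
  expect_equal(length(unique(red2$representative)), 2L)
})

test_that("domain annotation requires strictly more than 90% coverage", {
  doms <- tibble::tibble(start = c(50L, 201L, 301L), end = c(149L, 300L, 400L),
                         label = c("full", "ninety", "ninetyone"))
  aligned <- c(1:200, 201:290, 301:391)
  out <- assign_domain_annotation(aligned, doms, n_residues = 450)
  expect_equal(out$coverage, c(1.0, 0.90, 0.91), tolerance = 1e-12)
  expect_equal(out$annotated, c(TRUE, FALSE, TRUE))
  expect_error(
    assign_domain_annotation(1:10, tibble::tibble(start = 5L, end = 2L, label = "x"), 10),
    class = "domex_bad_range"
  )
})
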