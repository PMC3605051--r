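test_that("element extraction run-length encodes and round-trips", {
  e <- extract_elements("HHHHCCEEE")
  expect_equal(e$type, c("H", "C", "E"))
  expect_equal(e$length, c(4L, 2L, 3L))
  expect_equal(extract_elements("H")$length, 1L)
  expect_error(extract_elements("HHXC"), class = "domex_bad_ss")

  set.seed(8)
  s <- paste(sample(c("H", "E", "C"), 200, replace = TRUE), collapse = "")
  expect_equal(expand_elements(extract_elements(s)), s)
  # adjacent elements always differ in type and lengths sum to the input
  e2 <- extract_elements(s)
  expect_true(all(e2$type[-1] != e2$type[-nrow(e2)]))
  expect_equal(sum(e2$length), 200L)
})

test_that("SSEA scores match hand values, bounds and symmetry", {
  expect_equal(ssea_score("HHHHCCEEE", "HHHHCCEEE"), 100)
  expect_equal(ssea_score(strrep("H", 12), strrep("E", 12)), 0)
  # worked instance: min-overlap 8 + 5 + 8 over lengths 23 + 23
  a <- paste0(strrep("H", 10), strrep("C", 5), strrep("E", 8))
  b <- paste0(strrep("H", 8), strrep("C", 5), strrep("E", 10))
  expect_equal(ssea_score(a, b), 100 * 2 * 21 / 46, tolerance = 1e-9)
  expect_equal(ssea_score(a, b), 91.304, tolerance = 1e-3)

  set.seed(12)
  for (rep in 1:20) {
    sa <- paste(sample(c("H", "E", "C"), sample(5:40, 1), replace = TRUE),
                collapse = "")
    sb <- paste(sample(c("H", "E", "C"), sample(5:40, 1), replace = TRUE),
                collapse = "")
    s1 <- ssea_score(sa, sb)
    expect_equal(s1, ssea_score(sb, sa), tolerance = 1e-9)
    expect_gte(s1, 0); expect_lte(s1, 100)
    if (s1 == 100) expect_identical(sa, sb)
  }
})

test_that("SSEA DP equals exhaustive enumeration for small element counts", {
  set.seed(13)
  for (rep in 1:12) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    mk <- function(k) {
      types <- character(k); types[1] <- sample(c("H", "E", "C"), 1)
      for (i in seq_len(k - 1)) {
        types[i + 1] <- sample(setdiff(c("H", "E", "C"), types[i]), 1)
      }
      out <- tibble::tibble(type = types, length = sample(1:9, k, replace = TRUE))
      class(out) <- c("ss_elements", class(out))
      out
    }
    ea <- mk(na); eb <- mk(nb)
    expect_equal(ssea_score(ea, eb), brute_force_ssea(ea, eb), tolerance = 1e-9)
  }
})

test_that("cutoff training handles the degenerate and null score models", {
  co <- make_pair_cohort(200, 200, "degenerate", seed = 1)
  fit <- train_ssea_cutoff(co$score[co$label == "pos"],
                           co$score[co$label == "neg"],
                           n_sample = 100, reps = 50, seed = 1)
  # scores 80 vs 20: every cutoff in 21..80 is perfect; smallest tie -> 21
  expect_true(all(fit$replicate_cutoffs == 21L))
  expect_equal(fit$cutoff, 21L)

  # identically distributed sets: no separation
  set.seed(2)
  null_scores <- runif(400, 0, 100)
  hits <- vapply(1:10, function(s) {
    f <- train_ssea_cutoff(null_scores[1:200], null_scores[201:400],
                           n_sample = 100, reps = 20, seed = s)
    c(f$balanced_accuracy, f$p_value)
  }, numeric(2))
  expect_lt(mean(abs(hits[1, ] - 0.5)), 0.1)

  expect_error(train_ssea_cutoff(1:10, 1:10, n_sample = 100),
               class = "domex_insufficient_pairs")
})

test_that("training is deterministic under a fixed seed", {
  co <- make_pair_cohort(400, 400, "crossing50", seed = 5)
  f1 <- train_ssea_cutoff(co$score[co$label == "pos"],
                          co$score[co$label == "neg"], reps = 100, seed = 7)
  f2 <- train_ssea_cutoff(co$score[co$label == "pos"],
                          co$score[co$label == "neg"], reps = 100, seed = 7)
  expect_identical(f1$replicate_cutoffs, f2$replicate_cutoffs)
  expect_identical(f1$cutoff, f2$cutoff)
  expect_length(f1$replicate_cutoffs, 100L)
})

test_that("the probability curve recovers a logistic generating model", {
  # all pairs similar -> probability 1 in every occupied bin
  allsim <- tibble::tibble(score = runif(50, 0, 100), rmsd = runif(50, 1, 4))
  curve <- probability_curve(allsim)
  expect_true(all(curve$probability == 1))

  # single similar pair
  one <- probability_curve(tibble::tibble(score = 72, rmsd = 3))
  expect_equal(nrow(one), 1L)
  expect_equal(one$probability, 1)

  # logistic model at the published sampling depth
  co <- make_pair_cohort(5000, 5000, "logistic", seed = 9)
  curve <- probability_curve(co, bin_width = 10)
  expected <- stats::plogis((curve$bin_mid - 50) / 8)
  expect_lt(max(abs(curve$probability - expected)), 0.05)
  expect_gte(attr(curve, "spearman_rho"), 0.99)
})
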