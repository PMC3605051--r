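test_that("membrane-frame transforms behave and refuse double application", {
  # identity annotation leaves coordinates unchanged
  ch <- straight_chain(10)
  ident <- membrane_annotation(diag(3), c(0, 0, 0), -15, 15,
                               rep("outside", 10))
  expect_equal(structure_coords(to_membrane_frame(ch, ident)),
               structure_coords(ch))

  # a real membrane frame: TM residues land inside the slab, and the
  # transform refuses to run twice
  mp <- make_membrane_protein(synthetic_spec(seed = 41))
  st <- to_membrane_frame(mp$structure, mp$annotation)
  z_tm <- structure_coords(st)[mp$annotation$region == "TM", 3]
  expect_true(all(z_tm >= mp$annotation$z_lower - 3 &
                    z_tm <= mp$annotation$z_upper + 3))
  expect_error(to_membrane_frame(st, mp$annotation),
               class = "domex_double_transform")

  # hand-rotated case: membrane normal along x, point (30, 0, 0) gets
  # membrane-frame z = 30
  R <- matrix(c(0, 0, -1,
                0, 1, 0,
                1, 0, 0), 3, 3, byrow = TRUE)  # maps x onto z
  one <- protein_structure("p_A", "AAA",
                           rbind(c(30, 0, 0), c(33.8, 0, 0), c(37.6, 0, 0)))
  an <- membrane_annotation(R, c(0, 0, 0), -15, 15, rep("outside", 3))
  tr <- to_membrane_frame(one, an)
  expect_equal(tr$residues$z[1], 30, tolerance = 1e-9)
})

test_that("domain membrane distance is the centroid gap to the nearer surface", {
  region <- c(rep("TM", 20), rep("outside", 10))
  mk <- function(z) {
    coords <- rbind(cbind(0, 0, seq(-14, 14, length.out = 20)),
                    cbind(seq(1, 10), 2, z))
    protein_structure("m_A", strrep("A", 30), coords)
  }
  annot <- membrane_annotation(diag(3), c(0, 0, 0), -15, 15, region)
  # centroid exactly on the upper surface
  expect_equal(domain_membrane_distance(21:30, mk(15), annot)$distance, 0)
  # slab [-15, 15], centroid z = 40 -> 25, outside
  d <- domain_membrane_distance(21:30, mk(40), annot)
  expect_equal(d$distance, 25)
  expect_equal(d$side, "outside")
  # centroid z = -40 -> 25, inside
  d2 <- domain_membrane_distance(21:30, mk(-40), annot)
  expect_equal(d2$distance, 25)
  expect_equal(d2$side, "inside")
  expect_error(domain_membrane_distance(integer(), mk(40), annot),
               class = "domex_empty_domain")
  expect_error(domain_membrane_distance(1:5, mk(40), annot),
               class = "domex_domain_in_membrane")
})

test_that("membrane distance is invariant under joint rigid motions", {
  mp <- make_membrane_protein(synthetic_spec(seed = 42))
  base <- domain_membrane_distance(mp$domain_range, mp$structure, mp$annotation)
  set.seed(5)
  for (rep in 1:3) {
    g <- domex:::random_rotation()
    t_vec <- rnorm(3, sd = 15)
    moved <- mp$structure
    X <- sweep(tcrossprod(structure_coords(moved), g), 2, t_vec, "+")
    moved$residues$x <- X[, 1]; moved$residues$y <- X[, 2]; moved$residues$z <- X[, 3]
    # compose the annotation with the inverse motion
    annot2 <- membrane_annotation(
      mp$annotation$rotation %*% t(g),
      as.numeric(mp$annotation$translation -
                   mp$annotation$rotation %*% t(g) %*% t_vec),
      mp$annotation$z_lower, mp$annotation$z_upper, mp$annotation$region
    )
    d <- domain_membrane_distance(mp$domain_range, moved, annot2)
    expect_equal(d$distance, base$distance, tolerance = 1e-9)
    expect_equal(d$side, base$side)
  }
})

test_that("Mann-Whitney matches enumeration, midrank ties, and wilcox.test", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)   # 2 of the 20 assignments are as extreme

  same <- mann_whitney_u(rep(2, 4), rep(2, 4))
  expect_equal(same$p_value, 1)

  expect_error(mann_whitney_u(numeric(), 1:3), class = "domex_empty_sample")

  # exact branch against wilcox.test on tie-free samples
  set.seed(9)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(6)
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large-sample branch against wilcox.test's normal approximation
  set.seed(10)
  a <- rnorm(40); b <- rnorm(35, mean = 0.5)
  ours <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the test is calibrated under the null", {
  set.seed(77)
  p <- replicate(1000, {
    mann_whitney_u(rnorm(50), rnorm(50))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("group comparison detects the planted membrane-distance shift", {
  set.seed(3)
  tbl <- tibble::tibble(
    distance = c(rnorm(504, 25.9, 8), rnorm(102, 20.7, 8)),
    group = rep(c("with", "without"), c(504, 102))
  )
  res <- membrane_distance_test(tbl)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$groups$n, c(504L, 102L))
})
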