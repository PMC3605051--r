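test_that("Kabsch recovers exact rigid motions and rejects degenerate input", {
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  s0 <- kabsch_superpose(cube, cube)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_lt(max(abs(s0$rotation - diag(3))), 1e-9)

  th <- pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  B <- sweep(tcrossprod(cube, R), 2, c(1, 2, 3), "+")
  s <- kabsch_superpose(cube, B)
  expect_lt(s$rmsd, 1e-9)
  expect_lt(max(abs(s$rotation %*% R - diag(3))), 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(cube, cube[1:4, ]), class = "domex_length_mismatch")
  expect_error(kabsch_superpose(cube[1:2, ], cube[1:2, ]),
               class = "domex_too_few_points")
  line <- cbind(0:5, 0, 0)
  expect_error(kabsch_superpose(line, line), class = "domex_degenerate_points")
})

test_that("Kabsch RMSD matches a rotation-grid oracle on a non-trivial case", {
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 0))
  B <- A; B[4, 3] <- 1.0   # lift one planar point by 1 A
  expect_equal(kabsch_superpose(A, B)$rmsd, brute_force_rmsd(A, B),
               tolerance = 1e-3)
})

test_that("Kabsch agrees with the bio3d superposition on random point sets", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rnorm(45), 15, 3)
    B <- A + matrix(rnorm(45, sd = 0.8), 15, 3)
    ours <- kabsch_superpose(A, B)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(A)), as.numeric(t(B)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)
  }
})

test_that("the d0 length scaling follows the closed form with its floor", {
  expect_equal(tm_d0(135), 1.24 * 120^(1 / 3) - 1.8, tolerance = 1e-9)
  expect_equal(tm_d0(135), 4.3162, tolerance = 1e-4)
  expect_equal(tm_d0(15), 0.5)   # cube-root term vanishes
  expect_equal(tm_d0(21), 0.5)   # 1.24 * 6^(1/3) - 1.8 = 0.4537, floored
})

test_that("TM-score boundary values and partial alignments match direct summation", {
  expect_equal(tm_score(rep(0, 100), 100), 1.0)
  expect_equal(tm_score(rep(tm_d0(100), 100), 100), 0.5)
  d <- rep(2.0, 80)
  expect_equal(tm_score(d, 100), 80 / (1 + (2 / tm_d0(100))^2) / 100,
               tolerance = 1e-9)
  expect_error(tm_score(c(-1, 2), 10))
  expect_error(tm_score(rep(1, 20), 10))
})

test_that("DP alignment equals brute-force enumeration on small matrices", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(3:7, 1); m <- sample(3:8, 1)
    S <- matrix(runif(n * m), n, m)
    go <- -0.6; ge <- 0
    pairs <- dp_align(S, go, ge)
    expect_equal(score_pair_matrix(S, pairs, go, ge),
                 brute_force_dp(S, go, ge), tolerance = 1e-9)
  }
  # and with a non-zero extension penalty
  S <- matrix(runif(30), 5, 6)
  expect_equal(score_pair_matrix(S, dp_align(S, -1, -0.2), -1, -0.2),
               brute_force_dp(S, -1, -0.2), tolerance = 1e-9)
})

test_that("DP alignment equals an independent memoized recursion at 30 residues", {
  set.seed(11)
  a <- make_coil(30, seed = 1)$coords
  b <- make_coil(30, seed = 2)$coords
  D2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  S <- 1 / (1 + pmax(D2, 0) / tm_d0(30)^2)
  pairs <- dp_align(S, -0.6, 0)
  expect_equal(score_pair_matrix(S, pairs, -0.6, 0),
               recursive_dp_score(S, -0.6, 0), tolerance = 1e-9)
})

test_that("self-alignment is perfect and too-short structures are rejected", {
  mp <- make_membrane_protein(synthetic_spec(domain_size = 60, seed = 2))
  aln <- align_structures(mp$structure, mp$structure)
  expect_equal(aln$aligned_length, structure_length(mp$structure))
  expect_lt(aln$rmsd, 1e-6)
  expect_gt(aln$tm_score, 0.999)
  expect_equal(aln$seq_identity, 100)

  short <- protein_structure("tiny_A", strrep("A", 10),
                             make_helix(10)$coords)
  expect_error(align_structures(short, short), class = "domex_too_short")
})

test_that("alignment recovers a planted correspondence at 2 A noise", {
  mp <- make_membrane_protein(synthetic_spec(seed = 3))
  cp <- make_soluble_counterpart(mp, target_rmsd = 2, target_identity = 10,
                                 seed = 7)
  aln <- align_structures(mp$structure, cp$structure)
  truth <- setNames(cp$mapping$index_sol, cp$mapping$index_mem)
  hit <- truth[as.character(aln$pairs$index_a)] == aln$pairs$index_b
  expect_gte(mean(hit, na.rm = TRUE), 0.95)
  expect_gte(aln$rmsd, 1.5)
  expect_lte(aln$rmsd, 2.5)
})

test_that("alignments are invariant under rigid motions of either argument", {
  mp <- make_membrane_protein(synthetic_spec(seed = 4))
  cp <- make_soluble_counterpart(mp, target_rmsd = 1.5, target_identity = 20,
                                 seed = 9)
  base <- align_structures(mp$structure, cp$structure)
  set.seed(123)
  for (rep in 1:3) {
    R <- domex:::random_rotation()
    t_vec <- rnorm(3, sd = 30)
    moved <- cp$structure
    X <- sweep(tcrossprod(structure_coords(moved), R), 2, t_vec, "+")
    moved$residues$x <- X[, 1]; moved$residues$y <- X[, 2]; moved$residues$z <- X[, 3]
    aln <- align_structures(mp$structure, moved)
    expect_equal(aln$pairs$index_a, base$pairs$index_a)
    expect_equal(aln$pairs$index_b, base$pairs$index_b)
    expect_equal(aln$rmsd, base$rmsd, tolerance = 1e-6)
    expect_equal(aln$tm_score, base$tm_score, tolerance = 1e-6)
  }
})

test_that("rmsd rises and TM-score falls monotonically with planted noise", {
  mp <- make_membrane_protein(synthetic_spec(domain_size = 80, seed = 6))
  levels <- seq(0.4, 4.2, length.out = 20)
  res <- vapply(seq_along(levels), function(i) {
    cp <- make_soluble_counterpart(mp, target_rmsd = levels[i],
                                   target_identity = 30, seed = 100 + i)
    aln <- align_structures(mp$structure, cp$structure)
    c(aln$rmsd, aln$tm_score)
  }, numeric(2))
  expect_gte(cor(levels, res[1, ], method = "spearman"), 0.95)
  expect_lte(cor(levels, res[2, ], method = "spearman"), -0.95)
})
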