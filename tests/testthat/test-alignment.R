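test_that("spearman alignment matches rank-formula results", {
  expect_equal(spearman_alignment(1:10, 1:10), 1)
  expect_equal(spearman_alignment(10:1, 1:10), -1)
  # hand computation: ranks are the values, d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rho = 1 - 6*4 / (5 * 24) = 0.8
  expect_equal(spearman_alignment(c(2, 1, 4, 3, 5), 1:5), 0.8)
  set.seed(1)
  x <- rnorm(20)
  y <- rnorm(20)
  expect_equal(spearman_alignment(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  expect_error(spearman_alignment(rep(1, 5), 1:5), "constant")
  expect_error(spearman_alignment(1:4, 1:5), "equal length")
})

test_that("spin ensembles are seeded, hemisphere-consistent, and sane", {
  p <- make_parcellation(80, 5, seed = 2)
  e1 <- generate_spins(p, n_perm = 30, seed = 5)
  e2 <- generate_spins(p, n_perm = 30, seed = 5)
  expect_identical(e1$assignment, e2$assignment)
  right <- p$hemisphere == "right"
  # assignments never cross hemispheres
  expect_true(all(p$hemisphere[e1$assignment[right, ]] == "right"))
  expect_true(all(p$hemisphere[e1$assignment[!right, ]] == "left"))
  # mirrored rotations give identical assignment patterns for homologues
  ar <- e1$assignment[right, ]
  al <- e1$assignment[!right, ] - sum(right)
  expect_identical(unname(ar), unname(al))
})

test_that("rotation sampling is uniform over the rotation group", {
  p <- make_parcellation(20, 2, seed = 3)
  e <- generate_spins(p, n_perm = 1000, seed = 7)
  # closed-form mean rotation angle under the Haar measure: pi/2 + 2/pi
  expect_equal(mean(e$angles), pi / 2 + 2 / pi, tolerance = 0.05)
})

test_that("spin p-values behave at the degenerate and extreme ends", {
  p <- make_parcellation(100, 5, seed = 4)
  # identity-only ensemble: assignment is the identity map, p = 1
  e <- generate_spins(p, n_perm = 1, seed = 1)
  e$assignment[, 1] <- seq_len(100)
  res <- spin_pvalue(rnorm(100), p$sa_rank, e)
  expect_equal(res$p_spin, 1)

  # perfect alignment reaches the permutation floor
  e2 <- generate_spins(p, n_perm = 200, seed = 2)
  res2 <- spin_pvalue(as.numeric(p$sa_rank), p$sa_rank, e2)
  expect_equal(res2$rho, 1)
  expect_lte(res2$p_spin, 5 / 201)
  expect_gte(res2$p_spin, 1 / 201)
})

test_that("spin p-values are invariant to monotone transforms of the map", {
  p <- make_parcellation(60, 4, seed = 5)
  e <- generate_spins(p, n_perm = 100, seed = 3)
  set.seed(6)
  m <- random_smooth_map(p)
  r1 <- spin_pvalue(m, p$sa_rank, e)
  r2 <- spin_pvalue(exp(2 * m), p$sa_rank, e)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p_spin, r2$p_spin)
})

test_that("spin_pvalue validates parcellation compatibility", {
  p <- make_parcellation(40, 3, seed = 6)
  e <- generate_spins(p, n_perm = 10, seed = 1)
  expect_error(spin_pvalue(rnorm(20), seq_len(20), e), "different parcellation")
})

test_that("spinning the data map instead of the SA axis is supported", {
  p <- make_parcellation(60, 4, seed = 7)
  e <- generate_spins(p, n_perm = 200, seed = 4)
  set.seed(8)
  m <- random_smooth_map(p)
  r_sa <- spin_pvalue(m, p$sa_rank, e)
  r_map <- spin_pvalue(m, p$sa_rank, e, spin_map = TRUE)
  expect_equal(r_sa$rho, r_map$rho)
  expect_true(r_map$p_spin > 0 && r_map$p_spin <= 1)
})
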