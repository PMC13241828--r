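cfg_small <- function(...) {
  simulation_config(n_subjects = 6, n_nodes = 40, n_modules = 5, seed = 11, ...)
}

test_that("session matrices are symmetric unit-diagonal correlations", {
  cfg <- cfg_small()
  coh <- simulate_cohort(cfg)
  for (s in coh$sessions[1:3]) {
    m <- s$matrix
    expect_equal(m, t(m), tolerance = 1e-12)
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    expect_true(all(m >= -1 & m <= 1))
  }
})

test_that("ages are strictly increasing within subject and inside the range", {
  cfg <- simulation_config(n_subjects = 30, n_nodes = 20, n_modules = 3, seed = 2)
  coh <- simulate_cohort(cfg)
  ph <- coh$phenotypes
  for (sub in unique(ph$subject)) {
    a <- ph$age[ph$subject == sub]
    expect_true(all(diff(a) > 0))
  }
  expect_true(all(ph$age >= 12 & ph$age <= 18))
})

test_that("cohort generation is deterministic and counts sessions correctly", {
  cfg <- cfg_small()
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$sessions, c2$sessions)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_equal(length(c1$sessions), 6 * 3)
})

test_that("dropout removes sessions at the configured MCAR rate", {
  cfg <- simulation_config(
    n_subjects = 125, n_timepoints = 3, n_nodes = 10,
    n_modules = 2, dropout = 0.1, seed = 21
  )
  coh <- simulate_cohort(cfg)
  n <- length(coh$sessions)
  # binomial(375, 0.9): mean 337.5, sd ~5.8; allow 4 sd (plus kept-first rule)
  expect_gt(n, 337.5 - 4 * 5.8)
  expect_lt(n, 337.5 + 4 * 5.8)
})

test_that("planted positive gradient is monotone along the SA axis", {
  coh <- simulate_cohort(cfg_small())
  gt <- coh$ground_truth
  expect_equal(cor(gt$pos_slope, gt$sa_rank, method = "spearman"), -1)
})

test_that("no-effect configuration yields identical matrices across ages", {
  cfg <- simulation_config(
    n_subjects = 2, n_nodes = 30, n_modules = 3,
    pos_age_effect = list(max = 0, min = 0), neg_age_effect = 0,
    noise_sd = 0, seed = 3
  )
  parc <- make_parcellation(30, 3, seed = 3)
  blocks <- calibrate_blocks(parc, cfg)
  blocks$edge_offsets <- matrix(0, 30, 30)
  covs <- list(sex = 1, alcohol = 0, cannabis = 0, fd = 0.13)
  m1 <- simulate_session_matrix(parc, 0, 13, covs, cfg, blocks)
  m2 <- simulate_session_matrix(parc, 0, 17, covs, cfg, blocks)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("ages outside the configured range are rejected", {
  cfg <- cfg_small()
  parc <- make_parcellation(40, 5, seed = 11)
  covs <- list(sex = 0, alcohol = 0, cannabis = 0, fd = 0.13)
  expect_error(simulate_session_matrix(parc, 0, 20, covs, cfg), "outside")
})

test_that("realized negative-edge fraction hits the calibrated target", {
  cfg <- simulation_config(n_subjects = 2, n_nodes = 80, n_modules = 13, seed = 31)
  parc <- make_parcellation(80, 13, seed = 31)
  blocks <- calibrate_blocks(parc, cfg)
  covs <- list(sex = 0, alcohol = 0, cannabis = 0, fd = 0.13)
  set.seed(31)
  fr <- replicate(200, {
    blocks$edge_offsets <- NULL # fresh offsets each draw: marginal fraction
    m <- simulate_session_matrix(parc, 0, 15, covs, cfg, blocks)
    mean(m[upper.tri(m)] < 0)
  })
  expect_gt(mean(fr), 0.11)
  expect_lt(mean(fr), 0.21)
})

test_that("negative blocks concentrate between association modules", {
  cfg <- simulation_config(n_subjects = 2, n_nodes = 120, n_modules = 13, seed = 5)
  parc <- make_parcellation(120, 13, seed = 5)
  blocks <- calibrate_blocks(parc, cfg)
  cat3 <- blocks$category == 3
  # mean SA rank of nodes touching negative blocks exceeds the overall mean
  touched <- apply(cat3, 1, any)
  expect_gt(mean(parc$sa_rank[touched]), mean(parc$sa_rank))
  # negative category lives only between modules
  same_mod <- outer(parc$module, parc$module, "==")
  expect_false(any(cat3 & same_mod))
})

test_that("time-series mode converges to the latent correlation", {
  cfg_direct <- simulation_config(n_subjects = 2, n_nodes = 12, n_modules = 2, noise_sd = 0, seed = 9)
  cfg_ts <- simulation_config(
    n_subjects = 2, n_nodes = 12, n_modules = 2, noise_sd = 0,
    ts_length = 10000, seed = 9
  )
  parc <- make_parcellation(12, 2, seed = 9)
  blocks <- calibrate_blocks(parc, cfg_direct)
  blocks$edge_offsets <- draw_edge_offsets_for_test(12)
  covs <- list(sex = 0, alcohol = 0, cannabis = 0, fd = 0.13)
  set.seed(42)
  latent <- simulate_session_matrix(parc, 0, 15, covs, cfg_direct, blocks)
  set.seed(42)
  fc <- simulate_session_matrix(parc, 0, 15, covs, cfg_ts, blocks)
  off <- upper.tri(latent)
  expect_lt(max(abs(fc[off] - latent[off])), 0.05)
})

test_that("metric-panel generator validates and reproduces under seed", {
  expect_error(simulate_metric_panel(partial_r2 = 1.2), "partial_r2")
  p1 <- simulate_metric_panel(n_subjects = 10, n_nodes = 3, partial_r2 = 0.1, seed = 1)
  p2 <- simulate_metric_panel(n_subjects = 10, n_nodes = 3, partial_r2 = 0.1, seed = 1)
  expect_identical(p1$values, p2$values)
  expect_equal(nrow(p1$values), 30)
})
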