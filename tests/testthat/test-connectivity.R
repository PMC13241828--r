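test_that("pearson_fc reproduces hand-computed correlations", {
  ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(2, 4, 6, 8), d = -c(1, 2, 3, 4))
  fc <- pearson_fc(ts)
  expect_equal(fc$values["a", "b"], 0.6) # hand: sum dxdy = 3, sum dx2 = sum dy2 = 5
  expect_equal(fc$values["a", "c"], 1) # affine copy
  expect_equal(fc$values["a", "d"], -1) # negation
  expect_true(all(is.na(diag(fc$values))))
  expect_equal(fc$values, t(fc$values))
})

test_that("pearson_fc is invariant to affine rescaling of a column", {
  set.seed(1)
  ts <- matrix(rnorm(40), ncol = 4)
  ts2 <- ts
  ts2[, 2] <- 5 * ts2[, 2] - 7
  expect_equal(pearson_fc(ts)$values, pearson_fc(ts2)$values, tolerance = 1e-12)
})

test_that("pearson_fc rejects degenerate input naming the offender", {
  ts <- cbind(a = rnorm(5), b = rep(2, 5))
  expect_error(pearson_fc(ts), "b")
  expect_error(pearson_fc(matrix(rnorm(4), 2, 2)), "3 frames")
})

test_that("fisher_z is atanh with sign symmetry and clipping", {
  m <- matrix(c(NA, 0.5, 0.5, NA), 2, 2)
  z <- fisher_z(structure(list(values = m, scale = "pearson_r"), class = "fc_matrix"))
  expect_equal(z$values[1, 2], 0.549306144, tolerance = 1e-8) # atanh(1/2)
  expect_equal(z$scale, "fisher_z")
  expect_equal(fisher_z(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(fisher_z(matrix(-0.5, 2, 2)), -fisher_z(matrix(0.5, 2, 2)))
  expect_warning(zz <- fisher_z(matrix(c(0, 1, 1, 0), 2, 2)), "clipped")
  expect_true(all(is.finite(zz)))
  # strictly monotone on a grid
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_true(all(diff(fisher_z(matrix(r, 1))[1, ]) > 0))
})

test_that("node strength decomposes into positive and negative parts", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.5
  W[1, 3] <- W[3, 1] <- -0.3
  W[2, 3] <- W[3, 2] <- 0.2
  expect_equal(node_strength(W, "positive")[1], 0.5)
  expect_equal(node_strength(W, "negative")[1], 0.3)
  expect_equal(node_strength(W, "absolute")[1], 0.8)
  expect_equal(node_strength(matrix(0, 4, 4), "absolute"), rep(0, 4))

  set.seed(2)
  R <- random_weighted_graph(8, 0.6, signed = TRUE)
  mask <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(.8, .2)), 8)
  mask <- mask & t(mask)
  expect_equal(
    node_strength(R, "absolute", mask = mask),
    node_strength(R, "positive", mask = mask) + node_strength(R, "negative", mask = mask),
    tolerance = 1e-10
  )
})

test_that("mean strength divides by the retained-edge count", {
  W <- matrix(0.4, 3, 3)
  diag(W) <- 0
  expect_equal(node_strength(W, "positive", mean_strength = TRUE), rep(0.4, 3))
  expect_error(node_strength(matrix(c(0, 1, 2, 0), 2, 2), "positive"), "symmetric")
})
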