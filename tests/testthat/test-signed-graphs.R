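test_that("distance exclusion masks exactly the close pairs", {
  p <- make_parcellation(60, 4, seed = 8)
  W <- matrix(0.5, 60, 60)
  diag(W) <- 0
  ex <- apply_distance_exclusion(W, p, 30)
  d <- as.matrix(dist(as.matrix(p[, c("vx", "vy", "vz")])))
  brute <- d >= 30
  diag(brute) <- FALSE
  expect_identical(ex$mask, brute)
  expect_true(all(is.na(ex$values[!brute])))

  # identity case
  ex0 <- apply_distance_exclusion(W, p, 0)
  off <- !diag(60)
  expect_true(all(ex0$mask[off]))
  expect_equal(ex0$values[off], W[off])

  # a deliberately close pair is absent downstream
  p2 <- p
  p2[2, c("vx", "vy", "vz")] <- p2[1, c("vx", "vy", "vz")] + c(5, 0, 0)
  ex2 <- apply_distance_exclusion(W, p2, 30)
  expect_false(ex2$mask[1, 2])
  expect_error(apply_distance_exclusion(W, p[, 1:4], 30), "coordinates")
})

test_that("edge-sign treatments transform weights as defined", {
  expect_equal(construct_network(matrix(-0.4, 2, 2), "absolute")[1, 2], 0.4)
  expect_equal(construct_network(matrix(-0.4, 2, 2), "positive_only")[1, 2], 0)
  set.seed(3)
  W <- random_weighted_graph(10, 0.5, signed = TRUE)
  expect_equal(construct_network(abs(W), "absolute"), construct_network(abs(W), "positive_only"))
  expect_true(all(construct_network(W, "positive_only") <= construct_network(W, "absolute") + 1e-15))
})

test_that("proportional threshold retains exactly the top-weight edges", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- c(6, 5, 4, 3, 2, 1) / 10
  W <- W + t(W)
  net <- proportional_threshold(W, 0.5)
  expect_equal(net$n_retained, 3)
  expect_equal(sort(net$weights[upper.tri(net$weights)][net$weights[upper.tri(W)] > 0]),
    c(0.4, 0.5, 0.6),
    tolerance = 1e-12
  )
  expect_equal(proportional_threshold(W, 1)$weights, W)
  expect_error(proportional_threshold(W, 0.01), "zero retained")
  expect_error(proportional_threshold(W - 1, 0.5), "nonnegative")
})

test_that("threshold retention matches the sort-and-cut oracle with masks", {
  set.seed(4)
  for (rep in 1:10) {
    W <- abs(random_weighted_graph(50, 0.9))
    W[sample(2500, 200)] <- NA
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
    diag(W) <- NA
    net <- proportional_threshold(W, 0.25)
    kept <- which(net$weights != 0 & upper.tri(W), arr.ind = TRUE)
    oracle <- oracle_threshold_edges(W, 0.25)
    expect_equal(kept[order(kept[, 1], kept[, 2]), , drop = FALSE],
      oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE],
      ignore_attr = TRUE
    )
  }
})

test_that("clustering matches closed forms", {
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(clustering_coefficient(tri), rep(1, 3))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 0.7
  expect_equal(clustering_coefficient(star), rep(0, 5))
})

test_that("local efficiency matches closed forms", {
  tri <- matrix(1, 3, 3)
  diag(tri) <- 0
  expect_equal(local_efficiency(tri), rep(1, 3))
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(local_efficiency(path)[2], 0) # neighbors of the center are disconnected
})

test_that("participation matches closed forms for even splits", {
  for (M in 2:13) {
    n <- M + 1
    W <- matrix(0, n, n)
    W[1, 2:n] <- W[2:n, 1] <- 0.5
    modules <- c("hub", paste0("m", rep(1:M, length.out = n - 1)))
    pc <- participation_coefficient(W, modules)
    expect_equal(pc[1], 1 - 1 / M, tolerance = 1e-12)
  }
  # all strength within own module
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  expect_equal(participation_coefficient(W, c("a", "a", "b", "b"))[1], 0)
  expect_equal(participation_coefficient(W, c("a", "a", "b", "b"))[3], 0) # zero strength
  expect_error(participation_coefficient(W, c("a", "a")), "length")
  expect_error(participation_coefficient(W, c("a", "a", NA, "b")), "module")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    W <- abs(random_weighted_graph(n, runif(1, 0.3, 0.9)))
    modules <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(clustering_coefficient(W), oracle_clustering(W), tolerance = 1e-10)
    expect_equal(local_efficiency(W), oracle_local_efficiency(W), tolerance = 1e-10)
    expect_equal(participation_coefficient(W, modules), oracle_participation(W, modules),
      tolerance = 1e-10
    )
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(6)
  W <- abs(random_weighted_graph(9, 0.5))
  modules <- sample(letters[1:3], 9, replace = TRUE)
  perm <- sample(9)
  Wp <- W[perm, perm]
  expect_equal(clustering_coefficient(Wp), clustering_coefficient(W)[perm], tolerance = 1e-12)
  expect_equal(local_efficiency(Wp), local_efficiency(W)[perm], tolerance = 1e-12)
  expect_equal(participation_coefficient(Wp, modules[perm]),
    participation_coefficient(W, modules)[perm],
    tolerance = 1e-12
  )
})

test_that("scale invariance holds where the metric construction implies it", {
  set.seed(7)
  W <- abs(random_weighted_graph(10, 0.6))
  modules <- sample(letters[1:4], 10, replace = TRUE)
  expect_equal(clustering_coefficient(3 * W), clustering_coefficient(W), tolerance = 1e-12)
  expect_equal(participation_coefficient(3 * W, modules),
    participation_coefficient(W, modules),
    tolerance = 1e-12
  )
  # local efficiency with default per-graph normalization is scale invariant,
  # but with a fixed external w_max it scales monotonically
  expect_equal(local_efficiency(3 * W), local_efficiency(W), tolerance = 1e-12)
  le1 <- local_efficiency(W, w_max = 1)
  le2 <- local_efficiency(2 * W, w_max = 1)
  expect_true(all(le2 >= le1 - 1e-12))
})
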