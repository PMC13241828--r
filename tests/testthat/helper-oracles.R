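# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (no igraph, no matrix products): triple loops and
# Floyd-Warshall only, so metric tests compare two independent routes.

oracle_clustering <- function(W, w_max = max(W)) {
  diag(W) <- 0
  if (w_max > 0) W <- W / w_max
  P <- nrow(W)
  out <- numeric(P)
  for (i in seq_len(P)) {
    k <- sum(W[i, ] > 0)
    if (k <= 1) next
    acc <- 0
    for (j in seq_len(P)) {
      for (h in seq_len(P)) {
        acc <- acc + (W[i, j] * W[j, h] * W[h, i])^(1 / 3)
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_floyd_warshall <- function(L) {
  P <- nrow(L)
  D <- L
  D[D == 0] <- Inf
  diag(D) <- 0
  for (k in seq_len(P)) {
    for (i in seq_len(P)) {
      for (j in seq_len(P)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_local_efficiency <- function(W, w_max = max(W)) {
  diag(W) <- 0
  if (w_max > 0) W <- W / w_max
  P <- nrow(W)
  out <- numeric(P)
  for (i in seq_len(P)) {
    nb <- which(W[i, ] > 0)
    n <- length(nb)
    if (n < 2) next
    sub <- W[nb, nb, drop = FALSE]
    L <- ifelse(sub > 0, 1 / sub, 0)
    D <- oracle_floyd_warshall(L)
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != h && is.finite(D[j, h])) acc <- acc + 1 / D[j, h]
      }
    }
    out[i] <- acc / (n * (n - 1))
  }
  out
}

oracle_participation <- function(W, modules) {
  diag(W) <- 0
  P <- nrow(W)
  out <- numeric(P)
  for (i in seq_len(P)) {
    ki <- sum(W[i, ])
    if (ki == 0) next
    acc <- 0
    for (m in unique(modules)) {
      kim <- sum(W[i, modules == m])
      acc <- acc + (kim / ki)^2
    }
    out[i] <- 1 - acc
  }
  out
}

oracle_threshold_edges <- function(W, density) {
  P <- nrow(W)
  rows <- c()
  cols <- c()
  w <- c()
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      if (!is.na(W[i, j])) {
        rows <- c(rows, i)
        cols <- c(cols, j)
        w <- c(w, W[i, j])
      }
    }
  }
  k <- floor(density * length(w))
  ord <- order(-w, rows, cols)
  keep <- ord[seq_len(k)]
  cbind(i = rows[keep], j = cols[keep])
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

draw_edge_offsets_for_test <- function(P, sd = 0.1) {
  o <- matrix(0, P, P)
  up <- upper.tri(o)
  o[up] <- stats::rnorm(sum(up), sd = sd)
  o + t(o)
}

# random connected-ish weighted graph on n nodes at a given edge density
random_weighted_graph <- function(n, density, signed = FALSE) {
  W <- matrix(0, n, n)
  up <- which(upper.tri(W))
  m <- max(1, round(density * length(up)))
  sel <- sample(up, m)
  W[sel] <- stats::runif(m, 0.05, 1)
  if (signed) W[sel] <- W[sel] * sample(c(-1, 1), m, replace = TRUE)
  W + t(W)
}
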