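#' Exclude short-range node pairs by Euclidean distance
#'
#' Masks out edges between node pairs closer than `min_dist_mm` in volume
#' coordinates, the standard guard against short-range signal-leakage
#' correlations. Masked pairs are absent from all downstream sums,
#' thresholds and metrics.
#'
#' @param matrix symmetric numeric P x P matrix.
#' @param parcellation a [make_parcellation()]-style table with `vx, vy, vz`.
#' @param min_dist_mm exclusion radius in mm (default 30).
#' @return list with `values` (matrix with excluded entries set `NA`) and
#'   `mask` (logical P x P, `TRUE` = retained off-diagonal pair).
#' @export
apply_distance_exclusion <- function(matrix, parcellation, min_dist_mm = 30) {
  if (!all(c("vx", "vy", "vz") %in% names(parcellation))) {
    stop("parcellation lacks volume coordinates vx, vy, vz")
  }
  W <- as.matrix(matrix)
  P <- nrow(W)
  stopifnot(nrow(parcellation) == P)
  xyz <- as.matrix(parcellation[, c("vx", "vy", "vz")])
  d <- as.matrix(stats::dist(xyz))
  mask <- d >= min_dist_mm
  diag(mask) <- FALSE
  W[!mask] <- NA_real_
  diag(W) <- NA_real_
  list(values = W, mask = mask)
}

#' Apply an edge-sign treatment to a (masked) weight matrix
#'
#' `absolute` takes |w| on every retained edge; `positive_only` zeroes
#' negative correlations before any thresholding, keeping only edges that
#' originated from positive coupling.
#'
#' @param matrix symmetric P x P matrix, possibly with `NA` masked entries.
#' @param treatment `"absolute"` or `"positive_only"`.
#' @return nonnegative symmetric matrix (masked entries stay `NA`).
#' @export
construct_network <- function(matrix, treatment = c("absolute", "positive_only")) {
  treatment <- match.arg(treatment)
  W <- as.matrix(matrix)
  out <- switch(treatment,
    absolute = abs(W),
    positive_only = pmax(W, 0)
  )
  out
}

#' Proportional thresholding to a fixed graph density
#'
#' Retains the `floor(density * n_eligible)` largest-weight eligible edges
#' (off-diagonal, non-masked upper-triangle pairs) and zeroes the rest,
#' keeping retained weights unchanged (weighted graphs, not binarized).
#' Ties at the cut are broken by a stable sort on (weight descending,
#' node-pair lexicographic), so results are reproducible.
#'
#' @param weights nonnegative symmetric matrix; `NA` entries are treated as
#'   excluded (ineligible) pairs.
#' @param density target fraction of eligible pairs to retain, in (0, 1].
#' @param module_map optional character/factor vector of node module labels,
#'   stored for participation-coefficient use.
#' @param treatment label recorded on the result.
#' @return list of class `"signed_network"`: `weights` (nonnegative, zero
#'   diagonal, zeroed non-retained), `density` (realized), `n_retained`,
#'   `n_eligible`, `treatment`, `module_map`.
#' @export
proportional_threshold <- function(weights, density = 0.25, module_map = NULL,
                                   treatment = NA_character_) {
  if (!(density > 0 && density <= 1)) stop("density must lie in (0, 1]")
  W <- as.matrix(weights)
  P <- nrow(W)
  diag(W) <- NA_real_
  if (min(W, na.rm = TRUE) < 0) stop("weights must be nonnegative (apply construct_network first)")

  up <- which(upper.tri(W) & !is.na(W), arr.ind = TRUE)
  w <- W[up]
  n_eligible <- length(w)
  k <- floor(density * n_eligible)
  if (k == 0) stop("density yields zero retained edges")

  ord <- order(-w, up[, 1], up[, 2])
  keep_idx <- ord[seq_len(k)]

  out <- matrix(0, P, P)
  ik <- up[keep_idx, , drop = FALSE]
  out[ik] <- w[keep_idx]
  out <- out + t(out)
  dimnames(out) <- dimnames(weights)

  structure(
    list(
      weights = out, density = k / n_eligible, n_retained = k,
      n_eligible = n_eligible, treatment = treatment, module_map = module_map
    ),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf(
    "Signed network: %d nodes, %d/%d edges retained (density %.3f), treatment %s\n",
    nrow(x$weights), x$n_retained, x$n_eligible, x$density, x$treatment
  ))
  invisible(x)
}

net_weights <- function(network) {
  if (inherits(network, "signed_network")) network$weights else as.matrix(network)
}

#' Onnela weighted clustering coefficient
#'
#' For each node i, `C_i = (1 / (k_i (k_i - 1))) * sum_{j,k} (w_ij w_jk w_ki)^{1/3}`
#' with weights first max-normalized to \[0, 1\] by the largest retained
#' weight, and `k_i` the binary degree over retained edges (the Onnela
#' convention). Nodes with degree <= 1 get 0.
#'
#' @param network a `"signed_network"` or nonnegative symmetric matrix with
#'   zero diagonal.
#' @param w_max normalizing weight; default is the graph's own maximum
#'   retained weight. When comparing many sessions longitudinally pass a
#'   shared constant (e.g. the cohort-wide maximum) so per-node trajectories
#'   are not coupled to each session's single largest edge.
#' @return numeric per-node vector in \[0, 1\].
#' @export
clustering_coefficient <- function(network, w_max = NULL) {
  W <- net_weights(network)
  diag(W) <- 0
  mx <- if (is.null(w_max)) max(W) else w_max
  if (mx > 0) W <- W / mx
  Wc <- W^(1 / 3)
  num <- diag(Wc %*% Wc %*% Wc)
  k <- rowSums(W > 0)
  out <- ifelse(k > 1, num / (k * (k - 1)), 0)
  unname(out)
}

#' Weighted local efficiency
#'
#' For each node i with at least two neighbors, the mean over ordered
#' neighbor pairs (j, k) of `1 / d_jk`, where `d_jk` is the weighted shortest
#' path between j and k in the subgraph induced by the neighbors of i (node i
#' removed), with edge length `1 / w` on max-normalized weights. Unreachable
#' pairs contribute 0; nodes with fewer than two neighbors get 0.
#'
#' @inheritParams clustering_coefficient
#' @return numeric per-node vector, >= 0.
#' @export
local_efficiency <- function(network, w_max = NULL) {
  W <- net_weights(network)
  diag(W) <- 0
  mx <- if (is.null(w_max)) max(W) else w_max
  if (mx > 0) W <- W / mx
  P <- nrow(W)
  out <- numeric(P)
  for (i in seq_len(P)) {
    nb <- which(W[i, ] > 0)
    n <- length(nb)
    if (n < 2) next
    sub <- W[nb, nb, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected", weighted = TRUE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    out[i] <- sum(inv) / (n * (n - 1))
  }
  out
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_i` is node i's weighted
#' strength over retained edges and `k_im` the strength of its connections
#' into module m. Nodes with zero strength get 0.
#'
#' @param network a `"signed_network"` (module map taken from it if present)
#'   or nonnegative symmetric matrix.
#' @param module_map character/factor vector of module labels per node;
#'   required when not carried by `network`.
#' @return numeric per-node vector in \[0, 1\].
#' @export
participation_coefficient <- function(network, module_map = NULL) {
  W <- net_weights(network)
  if (is.null(module_map) && inherits(network, "signed_network")) {
    module_map <- network$module_map
  }
  if (is.null(module_map)) stop("module_map required")
  if (length(module_map) != nrow(W)) stop("module_map length must equal node count")
  if (anyNA(module_map)) stop("every node needs a module label")
  diag(W) <- 0
  mods <- factor(module_map)
  ## k_im for all nodes at once: W %*% indicator(module)
  M <- vapply(levels(mods), function(l) as.numeric(mods == l), numeric(length(mods)))
  kim <- W %*% M
  ki <- rowSums(W)
  frac2 <- (kim / ifelse(ki > 0, ki, 1))^2
  out <- ifelse(ki > 0, 1 - rowSums(frac2), 0)
  unname(out)
}
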