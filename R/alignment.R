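#' Spearman alignment of a node map with the SA axis
#'
#' Spearman rank correlation with average-rank tie handling between a
#' per-node map (typically delta R^2) and the sensorimotor-association
#' ranks.
#'
#' @param map numeric per-node vector.
#' @param sa_ranks numeric per-node vector (1 = most sensorimotor).
#' @return scalar rho in \[-1, 1\].
#' @export
spearman_alignment <- function(map, sa_ranks) {
  if (length(map) != length(sa_ranks)) stop("map and sa_ranks must have equal length")
  if (length(map) < 3) stop("need at least 3 nodes")
  if (stats::sd(map) == 0 || stats::sd(sa_ranks) == 0) {
    stop("constant vector: Spearman correlation undefined")
  }
  stats::cor(map, sa_ranks, method = "spearman")
}

## uniform random rotation matrices (Haar measure on SO(3)) via QR of a
## Gaussian matrix with sign fix (Stewart/Mezzadri) and det +1 correction
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qrd)
  R <- qr.R(qrd)
  Q <- Q %*% diag(sign(diag(R)))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' Generate a hemisphere-symmetric spin-permutation ensemble
#'
#' Samples `n_perm` rotations uniform over the rotation group, applies each
#' to the right-hemisphere sphere coordinates and its x-mirrored version to
#' the left hemisphere, and maps every node to the nearest original node of
#' the same hemisphere (parcel-spin convention: the assignment may contain
#' duplicates). Spinning a node map `v` under permutation `g` yields
#' `v[assignment[, g]]`.
#'
#' @param parcellation a [make_parcellation()] result (hemispheres must be
#'   x-mirror-symmetric on the sphere).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return list of class `"spin_ensemble"`: `assignment` (P x n_perm integer
#'   matrix of source-node indices), `angles` (rotation angle per spin,
#'   radians), `n_perm`, `seed`.
#' @export
generate_spins <- function(parcellation, n_perm = 10000L, seed = 1L) {
  if (!all(c("left", "right") %in% parcellation$hemisphere)) {
    stop("parcellation lacks hemisphere labels")
  }
  set.seed(seed)
  right <- which(parcellation$hemisphere == "right")
  left <- which(parcellation$hemisphere == "left")
  XR <- as.matrix(parcellation[right, c("sx", "sy", "sz")])
  XL <- as.matrix(parcellation[left, c("sx", "sy", "sz")])
  Mir <- diag(c(-1, 1, 1))
  P <- nrow(parcellation)

  assignment <- matrix(NA_integer_, P, n_perm)
  angles <- numeric(n_perm)
  for (g in seq_len(n_perm)) {
    R <- random_rotation()
    angles[g] <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
    RL <- Mir %*% R %*% Mir
    ## nearest original node to each rotated node = max cosine similarity
    simR <- (XR %*% t(R)) %*% t(XR)
    simL <- (XL %*% t(RL)) %*% t(XL)
    assignment[right, g] <- right[max.col(simR, ties.method = "first")]
    assignment[left, g] <- left[max.col(simL, ties.method = "first")]
  }
  structure(
    list(assignment = assignment, angles = angles, n_perm = n_perm, seed = seed),
    class = "spin_ensemble"
  )
}

#' Ranked spin-reassigned SA vectors
#'
#' Applies every spin in the ensemble to `sa_ranks` and re-ranks the result
#' (parcel spins duplicate values, so ranks must be recomputed). Useful for
#' vectorizing many alignment tests against one ensemble.
#'
#' @param ensemble a [generate_spins()] result.
#' @param sa_ranks per-node SA ranks.
#' @return P x n_perm matrix of ranked spun SA values.
#' @export
spun_sa_ranks <- function(ensemble, sa_ranks) {
  apply(ensemble$assignment, 2, function(a) rank(sa_ranks[a]))
}

#' Spin-permutation p-value for SA-axis alignment
#'
#' Computes the observed Spearman rho between a node map and the SA ranks,
#' then a null distribution by correlating the map with spin-reassigned SA
#' ranks, and a two-sided permutation p-value with the +1 correction:
#' `p = (1 + #|rho_null| >= |rho_obs|) / (n_perm + 1)`.
#'
#' @param map numeric per-node vector (e.g. delta R^2).
#' @param sa_ranks per-node SA ranks.
#' @param ensemble a [generate_spins()] result on the same parcellation.
#' @param spin_map if `TRUE`, spin the data map instead of the SA ranks.
#' @return list of class `"alignment_result"`: `rho`, `p_spin`, `n_perm`,
#'   `null_mean`, `null_sd`, `null_quantiles` (2.5/50/97.5%).
#' @export
spin_pvalue <- function(map, sa_ranks, ensemble, spin_map = FALSE) {
  stopifnot(inherits(ensemble, "spin_ensemble"))
  P <- length(map)
  if (length(sa_ranks) != P) stop("map and sa_ranks must have equal length")
  if (nrow(ensemble$assignment) != P) {
    stop("spin ensemble was generated on a different parcellation")
  }
  rho <- spearman_alignment(map, sa_ranks)

  rmap <- rank(map)
  rsa <- rank(sa_ranks)
  if (spin_map) {
    spun <- apply(ensemble$assignment, 2, function(a) rank(map[a]))
    null_rho <- as.vector(stats::cor(rsa, spun))
  } else {
    spun <- spun_sa_ranks(ensemble, sa_ranks)
    null_rho <- as.vector(stats::cor(rmap, spun))
  }

  p <- (1 + sum(abs(null_rho) >= abs(rho))) / (ensemble$n_perm + 1)
  structure(
    list(
      rho = rho, p_spin = p, n_perm = ensemble$n_perm,
      null_mean = mean(null_rho), null_sd = stats::sd(null_rho),
      null_quantiles = stats::quantile(null_rho, c(0.025, 0.5, 0.975))
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "SA-axis alignment: rho = %+.3f, p_spin = %.4g (%d spins; null %.3f +/- %.3f)\n",
    x$rho, x$p_spin, x$n_perm, x$null_mean, x$null_sd
  ))
  invisible(x)
}
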