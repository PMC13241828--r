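#' Generate a synthetic spherical parcellation
#'
#' Builds a cortical-style parcellation of `n_nodes` regions split evenly
#' across two hemispheres. Each hemisphere is represented as a full unit
#' sphere (the usual inflated-surface convention for spin permutation tests);
#' left-hemisphere nodes are the x-mirror images of the right-hemisphere
#' nodes, so hemisphere-symmetric spins are exact by construction.
#'
#' Modules are spatially contiguous patches obtained by k-means on the
#' right-hemisphere sphere coordinates, copied to the homologous left nodes.
#' The sensorimotor-association (SA) rank is the rank of a smooth function of
#' position (projection on a fixed axis plus a weaker seeded random axis, both
#' orthogonal to the mirror plane), giving a spatially autocorrelated axis so
#' a spin null is non-degenerate. Volume coordinates are `100 *` the sphere
#' coordinates, placing nodes on a 100 mm sphere so a 30 mm short-range
#' exclusion radius is meaningful.
#'
#' @param n_nodes even number of regions (split across hemispheres).
#' @param n_modules number of modules (>= 2, <= nodes per hemisphere).
#' @param seed integer seed; identical seeds give identical parcellations.
#' @return A `data.frame` of class `"parcellation"` with columns `node_id`,
#'   `hemisphere` ("left"/"right"), unit-sphere coordinates `sx, sy, sz`,
#'   volume coordinates in mm `vx, vy, vz`, `sa_rank` (1 = most sensorimotor),
#'   and `module`.
#' @examples
#' p <- make_parcellation(100, 13, seed = 1)
#' table(p$hemisphere)
#' @export
make_parcellation <- function(n_nodes, n_modules, seed = 1L) {
  if (n_nodes %% 2 != 0) stop("n_nodes must be even (split across hemispheres)")
  m <- n_nodes / 2L
  if (n_modules < 2) stop("n_modules must be >= 2")
  if (n_modules > m) stop("n_modules cannot exceed nodes per hemisphere")

  set.seed(seed)
  ## right-hemisphere points uniform on the unit sphere
  xyz <- matrix(stats::rnorm(3 * m), ncol = 3)
  xyz <- xyz / sqrt(rowSums(xyz^2))

  ## contiguous modules: k-means patches on the sphere
  km <- stats::kmeans(xyz, centers = n_modules, nstart = 10, iter.max = 50)
  module_right <- km$cluster

  ## smooth SA field: fixed main axis + weaker random axis, both in the
  ## mirror plane (zero x-component) so homologous nodes share field values
  ax2 <- c(0, stats::rnorm(2))
  ax2 <- ax2 / sqrt(sum(ax2^2))
  field_right <- xyz[, 3] + 0.35 * drop(xyz %*% ax2)

  left <- xyz
  left[, 1] <- -left[, 1]
  coords <- rbind(xyz, left)
  hemisphere <- rep(c("right", "left"), each = m)
  module <- sprintf("module_%02d", c(module_right, module_right))
  field <- c(field_right, field_right)

  ## rank 1 = most sensorimotor; ties (homologue pairs) broken by node id
  sa_rank <- rank(field, ties.method = "first")

  out <- data.frame(
    node_id = seq_len(n_nodes),
    hemisphere = hemisphere,
    sx = coords[, 1], sy = coords[, 2], sz = coords[, 3],
    vx = 100 * coords[, 1], vy = 100 * coords[, 2], vz = 100 * coords[, 3],
    sa_rank = as.integer(sa_rank),
    module = module,
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "Parcellation: %d nodes, %d per hemisphere, %d modules\n",
    nrow(x), nrow(x) / 2L, length(unique(x$module))
  ))
  NextMethod()
}

#' Write / read a parcellation table as TSV
#'
#' @param parcellation a `parcellation` object.
#' @param path file path.
#' @return `read_parcellation` returns a `parcellation`.
#' @export
write_parcellation <- function(parcellation, path) {
  utils::write.table(as.data.frame(parcellation), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

## sphere coordinate matrix for one hemisphere, in node order
hemi_coords <- function(parcellation, hemisphere) {
  sel <- parcellation$hemisphere == hemisphere
  as.matrix(parcellation[sel, c("sx", "sy", "sz")])
}

#' Random spatially autocorrelated node map
#'
#' Draws a smooth hemisphere-symmetric map over the parcellation: on the
#' right hemisphere, a sum of first-order (gradient) and second-order
#' (quadratic) projections onto axes drawn uniformly on the sphere; the
#' field is copied to homologous left nodes and white noise is added per
#' node. Such maps share the spatial autocorrelation and mirror symmetry of
#' real cortical maps while being independent of the SA axis by
#' construction — the null family a hemisphere-symmetric spin test is
#' calibrated against (and a naive value shuffle is not). Drawing the axes
#' uniformly over the full sphere makes the generating process closed under
#' the mirrored-rotation group, which the spin test's exchangeability
#' argument requires.
#'
#' @param parcellation a [make_parcellation()] result (left nodes must be
#'   the in-order homologues of right nodes, as [make_parcellation()]
#'   constructs them).
#' @param n_gradients number of first-order axis terms (default 3).
#' @param n_quadratics number of second-order axis terms (default 2).
#' @param noise_sd white-noise sd relative to the unit-scaled smooth field.
#' @return numeric per-node vector (uses the current RNG state).
#' @export
random_smooth_map <- function(parcellation, n_gradients = 3, n_quadratics = 2,
                              noise_sd = 0.2) {
  right <- which(parcellation$hemisphere == "right")
  left <- which(parcellation$hemisphere == "left")
  XR <- as.matrix(parcellation[right, c("sx", "sy", "sz")])
  v <- numeric(length(right))
  for (k in seq_len(n_gradients)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    v <- v + stats::rnorm(1) * drop(XR %*% ax)
  }
  for (k in seq_len(n_quadratics)) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    v <- v + stats::rnorm(1) * drop(XR %*% ax)^2
  }
  v <- v / stats::sd(v)
  out <- numeric(nrow(parcellation))
  out[right] <- v
  out[left] <- v
  out + stats::rnorm(nrow(parcellation), sd = noise_sd)
}
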