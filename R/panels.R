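#' Node-strength panel for a cohort
#'
#' For every session: Fisher z-transform of the correlation matrix, distance
#' exclusion, and sign-resolved node strength. Strength is computed on the
#' full (unthresholded) masked matrix by default — thresholding belongs to
#' graph construction, not strength — with an optional thresholded variant
#' for sensitivity checks.
#'
#' @param cohort an [simulate_cohort()] result (or compatible list).
#' @param variant `"positive"`, `"negative"`, or `"absolute"`.
#' @param min_dist_mm short-range exclusion radius (default 30).
#' @param mean_strength divide by each node's retained-edge count.
#' @param thresholded if `TRUE`, apply `construct_network("absolute")` +
#'   [proportional_threshold()] at `density` before summing.
#' @param density density for the thresholded variant.
#' @return a [metric_panel()].
#' @export
strength_panel <- function(cohort, variant = c("positive", "negative", "absolute"),
                           min_dist_mm = 30, mean_strength = FALSE,
                           thresholded = FALSE, density = 0.25) {
  variant <- match.arg(variant)
  parc <- cohort$parcellation
  P <- nrow(parc)
  template <- matrix(0, P, P)
  mask <- apply_distance_exclusion(template, parc, min_dist_mm)$mask

  vals <- t(vapply(cohort$sessions, function(s) {
    z <- fisher_z(strip_diag(s$matrix))
    if (thresholded) {
      masked <- z
      masked[!mask] <- NA_real_
      net <- proportional_threshold(construct_network(masked, "absolute"), density)
      w <- net$weights * sign(z)
      node_strength(w, variant)
    } else {
      node_strength(z, variant, mask = mask, mean_strength = mean_strength)
    }
  }, numeric(P)))
  metric_panel(vals, cohort$phenotypes,
    metric = paste0("strength_", variant), treatment = "signed"
  )
}

strip_diag <- function(m) {
  diag(m) <- NA_real_
  m
}

#' Graph-metric panel for a cohort
#'
#' For every session: Fisher z-transform, distance exclusion, edge-sign
#' treatment, proportional thresholding to the target density, and one of
#' the three node metrics.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param metric `"clustering"`, `"local_efficiency"`, or `"participation"`.
#' @param treatment `"absolute"` or `"positive_only"`.
#' @param density target graph density (default 0.25).
#' @param min_dist_mm short-range exclusion radius (default 30).
#' @return a [metric_panel()].
#' @export
graph_metric_panel <- function(cohort,
                               metric = c("clustering", "local_efficiency", "participation"),
                               treatment = c("absolute", "positive_only"),
                               density = 0.25, min_dist_mm = 30) {
  metric <- match.arg(metric)
  treatment <- match.arg(treatment)
  parc <- cohort$parcellation
  P <- nrow(parc)
  modules <- parc$module
  mask <- apply_distance_exclusion(matrix(0, P, P), parc, min_dist_mm)$mask

  nets <- lapply(cohort$sessions, function(s) {
    z <- fisher_z(strip_diag(s$matrix))
    z[!mask] <- NA_real_
    w <- construct_network(z, treatment)
    proportional_threshold(w, density, module_map = modules, treatment = treatment)
  })
  ## cohort-wide normalizing weight: keeps clustering/efficiency in [0, 1]
  ## without tying each session's metrics to its own single largest edge
  w_max <- max(vapply(nets, function(n) max(n$weights), 0))

  vals <- t(vapply(nets, function(net) {
    switch(metric,
      clustering = clustering_coefficient(net, w_max = w_max),
      local_efficiency = local_efficiency(net, w_max = w_max),
      participation = participation_coefficient(net)
    )
  }, numeric(P)))
  metric_panel(vals, cohort$phenotypes, metric = metric, treatment = treatment)
}

#' Observed negative-edge fraction of a cohort
#'
#' Mean over sessions of the fraction of negative off-diagonal entries in
#' the session correlation matrices (before masking or thresholding).
#'
#' @param cohort an [simulate_cohort()] result.
#' @return scalar in \[0, 1\].
#' @export
negative_edge_fraction <- function(cohort) {
  mean(vapply(cohort$sessions, function(s) {
    m <- s$matrix
    off <- m[upper.tri(m)]
    mean(off < 0)
  }, 0))
}

#' Write a metric panel as long-format TSV
#'
#' Columns: subject, session, node_id, metric, treatment, value.
#'
#' @param panel a [metric_panel()].
#' @param path file path.
#' @param header_comment optional `# `-prefixed provenance line.
#' @export
write_panel_tsv <- function(panel, path, header_comment = NULL) {
  S <- nrow(panel$values)
  P <- ncol(panel$values)
  long <- data.frame(
    subject = rep(panel$phenotypes$subject, P),
    session = rep(panel$phenotypes$session, P),
    node_id = rep(seq_len(P), each = S),
    metric = panel$metric,
    treatment = panel$treatment,
    value = as.vector(panel$values)
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
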