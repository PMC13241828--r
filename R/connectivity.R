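#' Pearson functional-connectivity matrix from regional time series
#'
#' Columns are z-score normalized internally (a no-op for the correlation
#' itself, which is affine-invariant) and all pairwise Pearson coefficients
#' are computed. Diagonal entries are set to `NA` (removed).
#'
#' @param timeseries numeric T x P matrix or data.frame, frames by nodes;
#'   column names, if present, are kept as node labels.
#' @return list of class `"fc_matrix"` with `values` (P x P, `NA` diagonal)
#'   and `scale = "pearson_r"`.
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' pearson_fc(ts)$values["a", "b"] # 0.6
#' @export
pearson_fc <- function(timeseries) {
  X <- as.matrix(timeseries)
  if (nrow(X) < 3) stop("need at least 3 frames to correlate")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("constant time series for node(s): ", paste(bad, collapse = ", "))
  }
  Z <- scale(X)
  r <- stats::cor(Z)
  diag(r) <- NA_real_
  structure(list(values = r, scale = "pearson_r"), class = "fc_matrix")
}

#' Fisher z-transform of a correlation matrix
#'
#' Entrywise `atanh`, preserving sign and monotonicity. Off-diagonal values
#' at or beyond |r| = 1 are clipped to 1 - 1e-7 in magnitude first, with a
#' warning, so the transform stays finite.
#'
#' @param fc an `"fc_matrix"` on the `pearson_r` scale, or a plain numeric
#'   matrix of correlations.
#' @return same container with `scale = "fisher_z"`.
#' @export
fisher_z <- function(fc) {
  plain <- !inherits(fc, "fc_matrix")
  vals <- if (plain) as.matrix(fc) else fc$values
  if (!plain && fc$scale != "pearson_r") stop("fisher_z expects pearson_r scale")
  lim <- 1 - 1e-7
  over <- abs(vals) > lim & !is.na(vals)
  if (any(over)) {
    warning(sprintf("clipped %d correlation(s) at |r| = 1 - 1e-7 before atanh", sum(over)))
    vals[over] <- sign(vals[over]) * lim
  }
  z <- atanh(vals)
  if (plain) {
    return(z)
  }
  structure(list(values = z, scale = "fisher_z"), class = "fc_matrix")
}

#' Sign-resolved node strength
#'
#' Sums, for each node, its positive edges, the magnitudes of its negative
#' edges, or the absolute values of all edges. Diagonal, `NA`, and
#' distance-masked entries contribute zero, so the decomposition
#' `absolute = positive + negative` holds on any masked matrix. Negative
#' strength is reported as a magnitude (a nonnegative number) so "stronger
#' negative connectivity" reads monotonically.
#'
#' @param matrix symmetric numeric P x P matrix (any weight scale).
#' @param variant one of `"positive"`, `"negative"`, `"absolute"`.
#' @param mask optional logical P x P matrix, `TRUE` = edge retained (e.g.
#'   from [apply_distance_exclusion()]).
#' @param mean_strength if `TRUE`, divide each node's sum by its number of
#'   contributing (retained, non-diagonal) entries.
#' @return numeric length-P vector, nonnegative.
#' @export
node_strength <- function(matrix, variant = c("positive", "negative", "absolute"),
                          mask = NULL, mean_strength = FALSE) {
  variant <- match.arg(variant)
  W <- as.matrix(matrix)
  if (max(abs(W - t(W)), na.rm = TRUE) > 1e-12) stop("matrix must be symmetric")
  diag(W) <- NA_real_
  if (!is.null(mask)) W[!mask] <- NA_real_
  contrib <- switch(variant,
    positive = pmax(W, 0),
    negative = pmax(-W, 0),
    absolute = abs(W)
  )
  s <- rowSums(contrib, na.rm = TRUE)
  if (mean_strength) {
    n_eff <- rowSums(!is.na(W))
    s <- ifelse(n_eff > 0, s / n_eff, 0)
  }
  unname(s)
}
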