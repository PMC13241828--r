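#' Container for node-by-session metric values
#'
#' @param values numeric S x P matrix, sessions by nodes.
#' @param phenotypes data.frame with one row per session: `subject`,
#'   `session`, `age`, `sex`, `alcohol`, `cannabis`, `fd`.
#' @param metric,treatment labels carried through to maps and reports.
#' @return list of class `"metric_panel"`.
#' @export
metric_panel <- function(values, phenotypes, metric = "metric", treatment = NA_character_) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(phenotypes))
  need <- c("subject", "age", "sex", "alcohol", "cannabis", "fd")
  if (!all(need %in% names(phenotypes))) {
    stop("phenotypes needs columns: ", paste(need, collapse = ", "))
  }
  structure(
    list(values = values, phenotypes = phenotypes, metric = metric, treatment = treatment),
    class = "metric_panel"
  )
}

#' Specification of the per-node longitudinal age model
#'
#' The full model is
#' `metric ~ s(age, bs, k) + sex + alcohol + cannabis + fd + (1 | subject)`,
#' a penalized thin-plate regression spline for age, fixed covariates, and a
#' subject random intercept (fitted as a random-effect smooth). The null
#' model drops the age smooth and keeps everything else. Substance scores
#' are standardized before fitting.
#'
#' @param k spline basis dimension (default 5: with three visit waves larger
#'   bases are unidentifiable).
#' @param bs mgcv smooth basis code (default `"tp"`, thin plate).
#' @param engine `"bam"` (fast restricted-likelihood fitting with covariate
#'   discretization; the default) or `"gam"` (exact REML).
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(k = 5, bs = "tp", engine = c("bam", "gam")) {
  engine <- match.arg(engine)
  structure(list(k = k, bs = bs, engine = engine), class = "model_spec")
}

fit_engine <- function(spec, form, df) {
  if (spec$engine == "bam") {
    mgcv::bam(form, data = df, method = "fREML", discrete = TRUE)
  } else {
    mgcv::gam(form, data = df, method = "REML")
  }
}

## standardize a column, tolerating zero variance
std_col <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
}

build_model_frame <- function(y, phenotypes) {
  df <- data.frame(
    y = as.numeric(y),
    age = phenotypes$age,
    sex = as.numeric(phenotypes$sex),
    alcohol = std_col(as.numeric(phenotypes$alcohol)),
    cannabis = std_col(as.numeric(phenotypes$cannabis)),
    fd = as.numeric(phenotypes$fd),
    subject = factor(phenotypes$subject)
  )
  ## rank check on the fixed-effect design, naming collinear columns
  X <- cbind(intercept = 1, as.matrix(df[, c("sex", "alcohol", "cannabis", "fd")]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; collinear column(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Fit one node's longitudinal age model
#'
#' Fits the full (or, with `include_age = FALSE`, the null) penalized-spline
#' mixed model for a single node's metric values and returns the fit plus
#' the marginal adjusted R-squared used for the age-effect size. "Marginal"
#' means the fitted values exclude the subject random-intercept term, and
#' the degrees-of-freedom adjustment counts the intercept, the parametric
#' covariates, and the age smooth's effective degrees of freedom — the
#' subject term appears identically in full and null models, so its
#' contribution cancels in the difference.
#'
#' If smoothing-parameter estimation fails the age smooth is refit with a
#' small fixed-df basis and the fit is flagged.
#'
#' @param y numeric response vector (one node's panel column).
#' @param phenotypes session covariate table (see [metric_panel()]).
#' @param spec a [model_spec()].
#' @param include_age fit the age smooth (full model) or not (null model).
#' @return list with `fit` (a `gam`), `adj_r2`, `edf` (age smooth, 0 for the
#'   null model), `p_smooth` (`NA` for the null model), `converged`,
#'   `fallback`, `n`, and `response_checksum`.
#' @export
fit_node_model <- function(y, phenotypes, spec = model_spec(), include_age = TRUE) {
  df <- build_model_frame(y, phenotypes)
  if (include_age && length(unique(df$age)) < 3) stop("need >= 3 distinct ages for the age smooth")
  form <- if (include_age) {
    stats::as.formula(sprintf(
      "y ~ s(age, bs = '%s', k = %d) + sex + alcohol + cannabis + fd + s(subject, bs = 're')",
      spec$bs, spec$k
    ))
  } else {
    y ~ sex + alcohol + cannabis + fd + s(subject, bs = "re")
  }
  fallback <- FALSE
  fit <- tryCatch(fit_engine(spec, form, df), error = function(e) NULL)
  if ((is.null(fit) || !isTRUE(fit$converged)) && include_age) {
    fallback <- TRUE
    form2 <- stats::as.formula(
      "y ~ s(age, bs = 'tp', k = 3, fx = TRUE) + sex + alcohol + cannabis + fd + s(subject, bs = 're')"
    )
    fit <- tryCatch(fit_engine(spec, form2, df), error = function(e) NULL)
  }
  if (is.null(fit)) {
    return(list(
      fit = NULL, adj_r2 = NA_real_, edf = NA_real_, p_smooth = NA_real_,
      converged = FALSE, fallback = fallback, n = nrow(df),
      response_checksum = sum(df$y)
    ))
  }

  ## marginal fitted values: drop the subject random-intercept column
  tm <- stats::predict(fit, type = "terms")
  re_col <- grep("s(subject)", colnames(tm), fixed = TRUE)
  fitted_marg <- stats::fitted(fit) - tm[, re_col]

  n <- nrow(df)
  rss <- sum((df$y - fitted_marg)^2)
  tss <- sum((df$y - mean(df$y))^2)
  edf_age <- 0
  p_smooth <- NA_real_
  if (include_age) {
    lab <- vapply(fit$smooth, function(s) s$label, "")
    i_age <- which(grepl("age", lab, fixed = TRUE))
    sm <- fit$smooth[[i_age]]
    edf_age <- sum(fit$edf[sm$first.para:sm$last.para])
    st <- summary(fit)$s.table
    p_smooth <- st[grep("age", rownames(st), fixed = TRUE), "p-value"]
  }
  p_fixed <- 5 # intercept + sex + alcohol + cannabis + fd
  p_eff <- p_fixed + edf_age
  adj_r2 <- 1 - (rss / (n - p_eff)) / (tss / (n - 1))

  list(
    fit = fit, adj_r2 = adj_r2, edf = edf_age, p_smooth = as.numeric(p_smooth),
    converged = isTRUE(fit$converged), fallback = fallback, n = n,
    response_checksum = sum(df$y)
  )
}

#' Age-effect size as an adjusted R-squared difference
#'
#' `delta R^2 = adj R^2(full) - adj R^2(null)`: the unique variance in the
#' metric explained by the age smooth after covariates and subject baseline
#' differences. Slightly negative values are possible (the adjustment
#' penalizes the smooth's degrees of freedom) and are retained.
#'
#' @param full_fit,null_fit results of [fit_node_model()] on identical rows.
#' @return scalar.
#' @export
delta_r2 <- function(full_fit, null_fit) {
  if (full_fit$n != null_fit$n ||
    abs(full_fit$response_checksum - null_fit$response_checksum) > 1e-8) {
    stop("full and null fits were not computed on identical rows")
  }
  full_fit$adj_r2 - null_fit$adj_r2
}

#' Benjamini-Hochberg significance flags
#'
#' @param p_values numeric vector in \[0, 1\] (`NA` allowed, returned `NA`).
#' @param q FDR level (default 0.05).
#' @return logical vector: significant at FDR `q`.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Per-node age-effect map for a metric panel
#'
#' Fits the full and null model for every node, computes delta R^2, the age
#' smooth's p-value, and FDR flags across nodes. Nodes whose fits fail are
#' recorded and excluded from the map with a warning; more than 20% failures
#' aborts with diagnostics.
#'
#' @param panel a [metric_panel()].
#' @param spec a [model_spec()].
#' @param q FDR level.
#' @return data.frame of class `"age_effect_map"`: `node_id`, `delta_r2`,
#'   `edf`, `p_smooth`, `fdr_significant`, `converged`; attributes `metric`,
#'   `treatment`, `failed_nodes`.
#' @export
age_effect_map <- function(panel, spec = model_spec(), q = 0.05) {
  stopifnot(inherits(panel, "metric_panel"))
  P <- ncol(panel$values)
  dr2 <- edf <- psm <- rep(NA_real_, P)
  conv <- rep(FALSE, P)
  for (j in seq_len(P)) {
    yj <- panel$values[, j]
    full <- fit_node_model(yj, panel$phenotypes, spec, include_age = TRUE)
    null <- fit_node_model(yj, panel$phenotypes, spec, include_age = FALSE)
    if (full$converged && null$converged) {
      dr2[j] <- delta_r2(full, null)
      edf[j] <- full$edf
      psm[j] <- full$p_smooth
      conv[j] <- TRUE
    }
  }
  failed <- which(!conv)
  if (length(failed) > 0.2 * P) {
    stop(sprintf(
      "age model failed for %d of %d nodes (first failures: %s)",
      length(failed), P, paste(utils::head(failed, 5), collapse = ", ")
    ))
  }
  if (length(failed) > 0) {
    warning(sprintf("excluding %d non-converged node(s) from the map", length(failed)))
  }
  out <- data.frame(
    node_id = seq_len(P), delta_r2 = dr2, edf = edf, p_smooth = psm,
    fdr_significant = fdr_correct(psm, q), converged = conv
  )
  attr(out, "metric") <- panel$metric
  attr(out, "treatment") <- panel$treatment
  attr(out, "failed_nodes") <- failed
  class(out) <- c("age_effect_map", "data.frame")
  out
}
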