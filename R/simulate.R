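#' Configuration for the synthetic longitudinal cohort generator
#'
#' Collects and validates every knob of the generative model for longitudinal
#' signed functional-connectivity cohorts. The generator plants a known
#' developmental structure: positive-edge age effects graded along the
#' sensorimotor-association (SA) axis, spatially uniform negative-edge age
#' effects, negative edges concentrated between association modules, subject
#' random intercepts, and covariate effects — all on the Fisher-z scale of a
#' latent block-structured correlation matrix.
#'
#' @param n_subjects number of subjects.
#' @param n_timepoints scan sessions per subject before dropout (default 3).
#' @param age_range two ascending ages in years (default 12-18).
#' @param n_nodes even number of regions.
#' @param n_modules number of modules (default 13).
#' @param ts_length frames per session; when non-NULL the generator samples
#'   time series from the latent correlation and returns their Pearson matrix
#'   (time-series mode) instead of the latent matrix itself.
#' @param pos_age_effect list with `max` and `min`: per-edge Fisher-z change
#'   per year of age at the most sensorimotor (rank 1) and most association
#'   (rank P) node; the per-node slope is linear in SA rank between them.
#' @param neg_age_effect per-edge Fisher-z magnitude growth per year applied
#'   uniformly to all negative-baseline (association-association) edges.
#' @param neg_edge_fraction target fraction of negative off-diagonal entries,
#'   in (0, 0.5); hit by calibrating the association-block mean (see
#'   [calibrate_blocks()]).
#' @param subject_sd sd of the subject random intercept applied to
#'   positive-baseline edges (Fisher-z units).
#' @param noise_sd sd of i.i.d. edgewise session noise (Fisher-z units).
#' @param edge_het_sd sd of stable per-edge weight offsets (Fisher-z units),
#'   drawn once per cohort: the connectome's fixed backbone of strong and
#'   weak edges. Without it, proportional-threshold edge retention would be
#'   re-randomized by session noise every scan, which swamps planted
#'   longitudinal structure in the graph metrics.
#' @param covariate_betas named vector of Fisher-z shifts per unit of
#'   `sex` (centered at 0.5), `alcohol`, `cannabis`, `fd` (centered at its
#'   median 0.13 mm).
#' @param within_r,between_r,assoc_base_r baseline block correlations:
#'   within-module, between-module, and the (pre-calibration) mean of blocks
#'   linking association modules.
#' @param dropout probability that any given session is missing (MCAR).
#' @param seed integer seed.
#' @return a validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_subjects = 125L,
                              n_timepoints = 3L,
                              age_range = c(12, 18),
                              n_nodes = 100L,
                              n_modules = 13L,
                              ts_length = NULL,
                              pos_age_effect = list(max = 0.006, min = 0),
                              neg_age_effect = 0.002,
                              neg_edge_fraction = 0.16,
                              subject_sd = 0.02,
                              noise_sd = 0.06,
                              edge_het_sd = 0.10,
                              covariate_betas = c(
                                sex = 0.010, alcohol = -0.002,
                                cannabis = -0.002, fd = -0.020
                              ),
                              within_r = 0.35,
                              between_r = 0.15,
                              assoc_base_r = -0.15,
                              dropout = 0,
                              seed = 1L) {
  stopifnot(
    n_subjects >= 1, n_timepoints >= 1,
    length(age_range) == 2, diff(age_range) > 0,
    n_nodes %% 2 == 0, n_modules >= 2,
    is.null(ts_length) || ts_length >= 3,
    dropout >= 0, dropout < 1,
    noise_sd >= 0, subject_sd >= 0
  )
  if (!(neg_edge_fraction > 0 && neg_edge_fraction < 0.5)) {
    stop("neg_edge_fraction must lie in (0, 0.5)")
  }
  if (!all(c("max", "min") %in% names(pos_age_effect))) {
    stop("pos_age_effect needs elements 'max' and 'min'")
  }
  need <- c("sex", "alcohol", "cannabis", "fd")
  if (!all(need %in% names(covariate_betas))) {
    stop("covariate_betas needs names: ", paste(need, collapse = ", "))
  }
  out <- list(
    n_subjects = as.integer(n_subjects), n_timepoints = as.integer(n_timepoints),
    age_range = as.numeric(age_range), n_nodes = as.integer(n_nodes),
    n_modules = as.integer(n_modules), ts_length = ts_length,
    pos_age_effect = pos_age_effect, neg_age_effect = neg_age_effect,
    neg_edge_fraction = neg_edge_fraction, subject_sd = subject_sd,
    noise_sd = noise_sd, edge_het_sd = edge_het_sd,
    covariate_betas = covariate_betas,
    within_r = within_r, between_r = between_r, assoc_base_r = assoc_base_r,
    dropout = dropout, seed = as.integer(seed)
  )
  class(out) <- "sim_config"
  out
}

#' Calibrate the latent block structure to a target negative-edge fraction
#'
#' The latent matrix has within-module mean `within_r`, between-module mean
#' `between_r`, and mean `assoc_base_r` (negative, full strength) on a
#' calibrated set of between-module blocks linking the most
#' association-ranked modules. Under edgewise Gaussian noise of sd
#' `noise_sd` on the Fisher-z scale, the expected fraction of negative
#' off-diagonal entries is a sum of normal tail probabilities over
#' categories; the number of negative pairs is solved so that expectation
#' equals `neg_edge_fraction`. Keeping the negative mean at full strength
#' (rather than shrinking it toward zero) matters: weakly negative entries
#' would flip sign session-to-session and leak negative-edge dynamics into
#' positive-only graphs.
#'
#' Negative pairs are allocated block-by-block down a list of module pairs
#' ordered by combined mean SA rank (most association-like first); the last
#' block is filled partially, highest-rank node pairs first, to hit the
#' calibrated count exactly.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param config a [simulation_config()].
#' @return list with `assoc_modules` (modules touched by negative blocks),
#'   `assoc_z` (negative block mean, Fisher-z), `category` (P x P integer
#'   matrix: 1 within, 2 between-positive, 3 association-negative), and
#'   `expected_neg_fraction`.
#' @export
calibrate_blocks <- function(parcellation, config) {
  mod <- parcellation$module
  P <- nrow(parcellation)
  z_w <- atanh(config$within_r)
  z_b <- atanh(config$between_r)
  z_a <- atanh(config$assoc_base_r)
  het <- if (is.null(config$edge_het_sd)) 0 else config$edge_het_sd
  sigma <- max(sqrt(config$noise_sd^2 + het^2), 1e-8)
  target <- config$neg_edge_fraction

  same <- outer(mod, mod, "==")
  n_pairs <- P * (P - 1) / 2
  f_within <- (sum(same) - P) / 2 / n_pairs
  f_between <- 1 - f_within

  ## expected negative fraction with a fraction fa of pairs in the negative
  ## category (fa carved out of the between-positive pairs)
  p_w <- stats::pnorm(-z_w / sigma)
  p_b <- stats::pnorm(-z_b / sigma)
  p_a <- stats::pnorm(-z_a / sigma) # z_a < 0, so this is large
  base <- f_within * p_w + f_between * p_b
  if (p_a <= p_b) stop("assoc_base_r must be more negative than between_r")
  fa <- (target - base) / (p_a - p_b)
  if (fa < 0) {
    warning("noise alone exceeds the negative-edge target; no negative blocks planted")
    fa <- 0
  }
  if (fa > f_between) {
    warning("negative-edge target unreachable; all between-module pairs made negative")
    fa <- f_between
  }
  n_neg <- round(fa * n_pairs)

  ## order module pairs by combined mean SA rank, most association-like first
  mods <- sort(unique(mod))
  mean_rank <- vapply(mods, function(m) mean(parcellation$sa_rank[mod == m]), 0)
  mp <- utils::combn(seq_along(mods), 2)
  mp_score <- mean_rank[mp[1, ]] + mean_rank[mp[2, ]]
  mp_ord <- order(mp_score, decreasing = TRUE)

  category <- matrix(2L, P, P)
  category[same] <- 1L
  diag(category) <- 0L

  left <- n_neg
  touched <- character(0)
  for (bi in mp_ord) {
    if (left <= 0) break
    m1 <- mods[mp[1, bi]]
    m2 <- mods[mp[2, bi]]
    i1 <- which(mod == m1)
    i2 <- which(mod == m2)
    prs <- expand.grid(i = i1, j = i2)
    if (nrow(prs) <= left) {
      category[cbind(prs$i, prs$j)] <- 3L
      category[cbind(prs$j, prs$i)] <- 3L
      left <- left - nrow(prs)
    } else {
      sc <- parcellation$sa_rank[prs$i] + parcellation$sa_rank[prs$j]
      takes <- order(sc, decreasing = TRUE)[seq_len(left)]
      category[cbind(prs$i[takes], prs$j[takes])] <- 3L
      category[cbind(prs$j[takes], prs$i[takes])] <- 3L
      left <- 0
    }
    touched <- c(touched, m1, m2)
  }

  fa_real <- n_neg / n_pairs
  list(
    assoc_modules = sort(unique(touched)),
    assoc_z = z_a,
    category = category,
    expected_neg_fraction = base + fa_real * (p_a - p_b)
  )
}

## per-node positive-edge age slopes, linear in SA rank (rank 1 strongest)
planted_pos_slopes <- function(parcellation, config) {
  P <- nrow(parcellation)
  a_max <- config$pos_age_effect$max
  a_min <- config$pos_age_effect$min
  a_max - (a_max - a_min) * (parcellation$sa_rank - 1) / (P - 1)
}

#' Simulate one session's functional-connectivity matrix
#'
#' Builds the latent Fisher-z matrix for one scan session — baseline block
#' structure, SA-graded positive-edge age effects, uniform negative-edge age
#' effects, subject intercept, covariate shifts, and edgewise noise — and
#' back-transforms to the correlation scale. In time-series mode
#' (`config$ts_length` set) it instead samples that many frames from the
#' latent correlation (after nearest-correlation repair if it is not positive
#' definite, reported via `message()`) and returns their Pearson matrix.
#'
#' @param parcellation a [make_parcellation()] result.
#' @param subject_effect scalar subject random intercept (Fisher-z units).
#' @param age age in years at scan.
#' @param covariates list or one-row data.frame with `sex`, `alcohol`,
#'   `cannabis`, `fd`.
#' @param config a [simulation_config()].
#' @param blocks optional precomputed [calibrate_blocks()] result.
#' @return symmetric correlation matrix with unit diagonal, entries in
#'   \[-1, 1\].
#' @export
simulate_session_matrix <- function(parcellation, subject_effect, age,
                                    covariates, config, blocks = NULL) {
  rng <- config$age_range
  if (age < rng[1] - 1e-9 || age > rng[2] + 1e-9) {
    stop(sprintf("age %.2f outside configured range [%g, %g]", age, rng[1], rng[2]))
  }
  if (is.null(blocks)) blocks <- calibrate_blocks(parcellation, config)
  P <- nrow(parcellation)
  cat_m <- blocks$category
  age_c <- age - mean(rng)

  base <- matrix(0, P, P)
  base[cat_m == 1L] <- atanh(config$within_r)
  base[cat_m == 2L] <- atanh(config$between_r)
  base[cat_m == 3L] <- blocks$assoc_z

  ## edge strengthens at the rate of its slower (more association-like)
  ## endpoint, concentrating maturation within sensorimotor circuits
  alpha <- planted_pos_slopes(parcellation, config)
  edge_slope <- outer(alpha, alpha, "pmin") * age_c

  b <- config$covariate_betas
  shift <- subject_effect +
    b[["sex"]] * (covariates$sex - 0.5) +
    b[["alcohol"]] * covariates$alcohol +
    b[["cannabis"]] * covariates$cannabis +
    b[["fd"]] * (covariates$fd - 0.13)

  z <- base
  pos <- cat_m == 1L | cat_m == 2L
  z[pos] <- z[pos] + edge_slope[pos] + shift
  neg <- cat_m == 3L
  z[neg] <- z[neg] - config$neg_age_effect * age_c

  offsets <- blocks$edge_offsets
  if (is.null(offsets)) offsets <- draw_edge_offsets(P, config$edge_het_sd)
  noise <- matrix(0, P, P)
  up <- upper.tri(noise)
  noise[up] <- stats::rnorm(sum(up), sd = config$noise_sd)
  noise <- noise + t(noise)
  z <- z + offsets + noise

  r <- tanh(z)
  diag(r) <- 1

  if (!is.null(config$ts_length)) {
    r <- sample_pearson_from_latent(r, config$ts_length)
  }
  r
}

## stable per-edge weight offsets, symmetric, zero diagonal
draw_edge_offsets <- function(P, sd) {
  if (is.null(sd) || sd == 0) return(matrix(0, P, P))
  o <- matrix(0, P, P)
  up <- upper.tri(o)
  o[up] <- stats::rnorm(sum(up), sd = sd)
  o + t(o)
}

## sample ts_length frames from a latent correlation and return Pearson FC;
## repairs non-PD latent matrices with nearest-correlation projection
sample_pearson_from_latent <- function(latent, ts_length) {
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    message("latent correlation not positive definite; applying nearest-correlation repair")
    latent <- as.matrix(Matrix::nearPD(latent, corr = TRUE)$mat)
  }
  L <- chol(latent)
  X <- matrix(stats::rnorm(ts_length * nrow(latent)), nrow = ts_length) %*% L
  r <- pearson_fc(X)$values
  diag(r) <- 1
  unname(r)
}

## longitudinal ages: baseline early in range, last visit late, interior
## visits spread between with per-subject jitter; strictly increasing
draw_subject_ages <- function(n_subjects, n_timepoints, age_range) {
  r1 <- age_range[1]
  r2 <- age_range[2]
  span <- r2 - r1
  b <- stats::runif(n_subjects, r1, r1 + 0.3 * span)
  if (n_timepoints == 1) {
    return(matrix(b, ncol = 1))
  }
  l <- stats::runif(n_subjects, r2 - 0.25 * span, r2)
  frac <- seq(0, 1, length.out = n_timepoints)
  ages <- sapply(seq_len(n_timepoints), function(t) b + (l - b) * frac[t])
  if (n_timepoints > 2) {
    for (t in 2:(n_timepoints - 1)) {
      jit <- stats::runif(n_subjects, -0.08, 0.08) * (l - b)
      ages[, t] <- ages[, t] + jit
    }
    ages <- t(apply(ages, 1, sort))
  }
  ages
}

## session covariates; substance scores zero-inflated and age-increasing
draw_covariates <- function(sex, age) {
  n <- length(age)
  p_alc <- stats::plogis(-7 + 0.45 * age)
  p_can <- stats::plogis(-8 + 0.45 * age)
  alcohol <- ifelse(stats::rbinom(n, 1, p_alc) == 1,
    stats::rpois(n, 0.8 + 0.35 * (age - 12)) + 1, 0
  )
  cannabis <- ifelse(stats::rbinom(n, 1, p_can) == 1,
    stats::rpois(n, 0.6 + 0.3 * (age - 12)) + 1, 0
  )
  fd <- stats::rlnorm(n, log(0.13), 0.35)
  data.frame(sex = sex, alcohol = alcohol, cannabis = cannabis, fd = fd)
}

#' Simulate a longitudinal signed-connectome cohort
#'
#' Generates a parcellation, per-subject visit schedules and covariates, and
#' one functional-connectivity matrix per retained session, with dropout
#' missing completely at random. The planted per-node age-effect slopes are
#' returned as ground truth; by construction the positive-edge slopes are
#' monotone decreasing in SA rank (Spearman rho = -1 against `sa_rank`
#' whenever the planted gradient is non-degenerate), which is asserted at
#' generation time.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"fc_cohort"`: `parcellation`, `sessions` (list of
#'   session records, each with `subject`, `session`, `age`, covariates, and
#'   `matrix`), `phenotypes` (one row per session), `ground_truth`
#'   (`node_id`, `sa_rank`, `pos_slope`, `neg_slope`), `blocks`, `config`.
#' @examples
#' coh <- simulate_cohort(simulation_config(n_subjects = 5, n_nodes = 20, seed = 2))
#' length(coh$sessions)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  parc <- make_parcellation(config$n_nodes, config$n_modules, seed = config$seed)
  set.seed(config$seed + 1L)
  blocks <- calibrate_blocks(parc, config)
  blocks$edge_offsets <- draw_edge_offsets(config$n_nodes, config$edge_het_sd)

  n <- config$n_subjects
  Tn <- config$n_timepoints
  ages <- draw_subject_ages(n, Tn, config$age_range)
  sex <- stats::rbinom(n, 1, 0.5)
  u <- stats::rnorm(n, 0, config$subject_sd)

  keep <- matrix(stats::runif(n * Tn) >= config$dropout, n, Tn)
  none <- rowSums(keep) == 0
  keep[none, 1] <- TRUE

  sessions <- list()
  pheno <- list()
  for (i in seq_len(n)) {
    vis <- which(keep[i, ])
    cov_i <- draw_covariates(rep(sex[i], length(vis)), ages[i, vis])
    for (v in seq_along(vis)) {
      t <- vis[v]
      covs <- cov_i[v, , drop = FALSE]
      m <- simulate_session_matrix(parc, u[i], ages[i, t], covs, config, blocks)
      rec <- list(
        subject = sprintf("sub%04d", i), session = t, age = ages[i, t],
        sex = covs$sex, alcohol = covs$alcohol, cannabis = covs$cannabis,
        fd = covs$fd, matrix = m
      )
      sessions[[length(sessions) + 1L]] <- rec
      pheno[[length(pheno) + 1L]] <- data.frame(
        subject = rec$subject, session = t, age = rec$age, sex = rec$sex,
        alcohol = rec$alcohol, cannabis = rec$cannabis, fd = rec$fd,
        stringsAsFactors = FALSE
      )
    }
  }
  phenotypes <- do.call(rbind, pheno)

  gt <- data.frame(
    node_id = parc$node_id, sa_rank = parc$sa_rank,
    pos_slope = planted_pos_slopes(parc, config),
    neg_slope = config$neg_age_effect
  )
  if (stats::sd(gt$pos_slope) > 0) {
    rho <- stats::cor(gt$pos_slope, gt$sa_rank, method = "spearman")
    stopifnot(abs(rho - (-1)) <= 0.05)
  }

  structure(
    list(
      parcellation = parc, sessions = sessions, phenotypes = phenotypes,
      ground_truth = gt, blocks = blocks, config = config
    ),
    class = "fc_cohort"
  )
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf(
    "Longitudinal FC cohort: %d subjects, %d sessions, %d nodes, %d modules\n",
    length(unique(x$phenotypes$subject)), length(x$sessions),
    nrow(x$parcellation), length(unique(x$parcellation$module))
  ))
  invisible(x)
}

#' Reversal-scenario cohort configuration
#'
#' The study condition in which absolute-value and positive-only network
#' constructions disagree: anticorrelations concentrated between association
#' modules strengthen substantially with age (per-edge Fisher-z magnitude
#' growth 0.03 per year) while positive-edge maturation keeps its default
#' sensorimotor-graded profile. On such cohorts, clustering age effects are
#' association-dominant in absolute-value networks (driven by |w| growth of
#' negative edges) but sensorimotor-dominant in positive-only networks.
#'
#' @param seed integer seed.
#' @param n_subjects,n_nodes cohort shape (defaults 80 subjects, 120 nodes).
#' @param ... further overrides passed to [simulation_config()].
#' @return a [simulation_config()].
#' @export
reversal_scenario_config <- function(seed = 1L, n_subjects = 80L, n_nodes = 120L, ...) {
  simulation_config(
    n_subjects = n_subjects, n_nodes = n_nodes,
    neg_age_effect = 0.03, seed = seed, ...
  )
}

#' Simulate node-metric panels with an exact planted age partial R-squared
#'
#' Direct generator for node-level metric values (bypassing graphs) used for
#' model calibration: each node's response is a linear age trend scaled so
#' the age term explains exactly `partial_r2` of the total variance, plus a
#' per-node subject random intercept (variance 0.3) and residual noise
#' (variance 0.7). Covariates are drawn independently of age and have zero
#' effect on the response — unlike the cohort generator, where substance use
#' rises with age — so "variance explained uniquely by age after covariates"
#' coincides with the planted marginal share and recovery is interpretable.
#'
#' @param n_subjects,n_timepoints cohort shape.
#' @param n_nodes number of nodes (columns of the panel).
#' @param partial_r2 scalar or length-`n_nodes` vector of planted age
#'   variance shares in \[0, 1).
#' @param age_range ages in years.
#' @param seed integer seed.
#' @return a [metric_panel()] whose `phenotypes` carry the session covariates.
#' @export
simulate_metric_panel <- function(n_subjects = 125L, n_timepoints = 3L,
                                  n_nodes = 100L, partial_r2 = 0,
                                  age_range = c(12, 18), seed = 1L) {
  stopifnot(all(partial_r2 >= 0), all(partial_r2 < 1))
  r2 <- rep_len(partial_r2, n_nodes)
  set.seed(seed)
  ages <- draw_subject_ages(n_subjects, n_timepoints, age_range)
  sex <- stats::rbinom(n_subjects, 1, 0.5)
  subj <- rep(seq_len(n_subjects), each = n_timepoints)
  age_v <- as.vector(t(ages))
  ## covariates decoupled from age: draw at a fixed reference age
  covs <- draw_covariates(sex[subj], rep(mean(age_range), length(age_v)))
  phen <- data.frame(
    subject = sprintf("sub%04d", subj),
    session = rep(seq_len(n_timepoints), n_subjects),
    age = age_v, covs, stringsAsFactors = FALSE
  )
  S <- nrow(phen)
  age_c <- age_v - mean(age_v)
  sd_age <- stats::sd(age_c)

  vals <- matrix(NA_real_, S, n_nodes)
  for (j in seq_len(n_nodes)) {
    b <- if (r2[j] > 0) sqrt(r2[j] / (1 - r2[j])) / sd_age else 0
    u <- stats::rnorm(n_subjects, 0, sqrt(0.3))
    vals[, j] <- b * age_c + u[subj] + stats::rnorm(S, 0, sqrt(0.7))
  }
  colnames(vals) <- seq_len(n_nodes)
  metric_panel(vals, phen, metric = "synthetic", treatment = "none")
}
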