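---
title: "Sign-aware developmental connectomics: models, metrics, and nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign-aware developmental connectomics: models, metrics, and nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Resting-state functional connectivity (FC) matures through adolescence, and a
prominent organizing account places that maturation along the
sensorimotor-association (SA) cortical axis: primary sensorimotor regions
change earliest and most strongly, transmodal association cortex latest.
Most connectome studies, however, either discard the sign of FC edges
(absolute-value networks) or mix positive correlations and anticorrelations
into a single weight, although the two edge classes plausibly reflect
different physiology (synchronous coupling vs. competitive or segregating
dynamics). `devconn` implements a longitudinal pipeline that makes the
edge-sign decision explicit at every stage and quantifies how much the
developmental inference depends on it:

1. build FC matrices (Pearson, Fisher z), with sign-resolved node strength;
2. construct weighted graphs under two treatments — absolute value `|r|` and
   positive-only `max(r, 0)` — with 30 mm short-range exclusion and
   proportional thresholding to 25% density;
3. compute three node metrics: Onnela weighted clustering, weighted local
   efficiency (segregation), and the participation coefficient (integration);
4. fit, per node, a penalized-spline mixed model of age and compute
   ΔR² — the adjusted-R² difference between the full model and a null model
   without the age smooth;
5. test whether the ΔR² map aligns with the SA axis (Spearman ρ) against a
   hemisphere-symmetric spin-permutation null.

Because the motivating cohort data are restricted, the package ships a
first-class synthetic cohort generator with planted ground truth, and every
claim the pipeline makes is validated against that ground truth.

## The synthetic cohort generator

Each scan session's FC matrix is generated on the Fisher-z scale as

$$z_{ij} = B_{ij} + H_{ij} + \gamma_{ij}\,(a - \bar a) + u_s\,\mathbb{1}[B_{ij}>0]
        + c^\top x\,\mathbb{1}[B_{ij}>0] + \varepsilon_{ij},$$

then back-transformed with `tanh`. The pieces, and why they are there:

* **Block baseline `B`.** Within-module mean r = 0.35, between-module mean
  r = 0.15, and a calibrated set of between-module blocks linking the most
  association-ranked modules at r = −0.15. The *count* of negative pairs is
  solved analytically (normal tail probabilities given the total edgewise
  dispersion) so the expected fraction of negative entries equals the target
  (default 0.16). Keeping negative blocks at full strength rather than
  shrinking their mean toward zero is deliberate: weakly negative entries
  flip sign from session to session, which leaks negative-edge dynamics into
  positive-only graphs and blurs the planted contrast between constructions.
* **Stable edge heterogeneity `H`** (sd 0.10, drawn once per cohort). Real
  connectomes have a reproducible backbone of strong and weak edges; a model
  with i.i.d. edge noise alone re-randomizes which edges survive
  proportional thresholding at every session, and that retention churn —
  not any planted biology — then dominates longitudinal variance in graph
  metrics.
* **SA-graded positive maturation.** Each node carries a slope
  $\alpha_i$ linear in its SA rank (default 0.006 z/year at the most
  sensorimotor node, 0 at the most association node). An edge strengthens at
  the rate of its *slower* endpoint, $\gamma_{ij} = \min(\alpha_i, \alpha_j)$
  for positive-baseline edges: developmental strengthening is limited by the
  less mature end, which concentrates maturation within sensorimotor
  circuits. (Averaging the endpoints instead spreads sensorimotor growth
  onto association-attached edges and, through the triangle terms of the
  clustering coefficient, onto association nodes — erasing the very gradient
  the generator is supposed to plant.)
* **Uniform negative maturation.** Negative-baseline edges grow in magnitude
  at a spatially uniform rate (default 0.002 z/year; 0.03 in the reversal
  scenario), matching the planted account that anticorrelation development
  is not organized along the hierarchy.
* **Subject intercepts** (sd 0.02 z) on positive-baseline edges, **covariate
  shifts** (sex, alcohol, cannabis, head motion; small z-scale coefficients)
  and **session noise** (sd 0.06 z, roughly the sampling error of a
  correlation estimated from ~150 frames).

Covariates are drawn with simple documented shapes: sex Bernoulli(0.5),
framewise displacement log-normal around 0.13 mm, substance scores
zero-inflated with age-increasing prevalence (the real screening instrument's
distribution is not public, so these are placeholders). Visit ages follow the
three-wave longitudinal design: baseline early in the 12–18 range, last visit
late, strictly increasing within subject. Dropout is missing completely at
random; the cohort's real quality-control attrition is not modeled.

Two data modes exist: direct latent-correlation matrices (default, fast) and
a time-series mode that samples frames from the latent correlation (with
nearest-correlation repair if needed, reported via `message()`) and computes
Pearson FC, so the connectivity operations are testable against their inputs.

What the generator does *not* emulate: BOLD hemodynamics, scanner noise
spectra, motion artifacts and their interaction with preprocessing, distance-
dependent artifact structure, or non-random attrition. Passing tests
demonstrate internal validity of the pipeline — correct metrics, calibrated
models and nulls, recoverable planted structure — not that real adolescent
cohorts behave like the generator.

## Graph construction choices

* **Order of operations:** distance exclusion first, then sign treatment,
  then proportional thresholding. Excluding short-range pairs before
  thresholding prevents leakage-prone edges from consuming the density
  budget.
* **Thresholding** retains the `floor(0.25 × n_eligible)` largest weights per
  session (weights kept, not binarized), so density is exact across subjects
  and sessions; ties at the cut are broken by a stable (weight, node-pair)
  sort for reproducibility.
* **Distances** are Euclidean on the 100 mm spherical volume coordinates —
  the synthetic world has no cortical surface, so no geodesic is available;
  the 30 mm default radius is meaningful at that scale.
* **Negative-only graphs are not constructed**: at ~16% negative edges, a
  25%-density negative-only graph is mostly padding.
* **Weight normalization for clustering and local efficiency.** Both metrics
  normalize weights to [0, 1]. Standalone calls use the graph's own maximum
  (the toolbox convention). The longitudinal panels instead pass the
  cohort-wide maximum retained weight: normalizing each session by its own
  single largest edge couples every node's trajectory to that one noisy
  edge and injects a spurious common age trend into all nodes. The metric
  definition is unchanged; only the scale constant is shared.
* `k_i` in the clustering denominator is the binary degree over retained
  edges (Onnela convention); local efficiency uses edge length `1/w` within
  the neighbor-induced subgraph, unreachable pairs contribute zero.

## The age model and ΔR²

For each node, the full model is

`metric ~ s(age, bs = "tp", k = 5) + sex + alcohol + cannabis + fd + s(subject, bs = "re")`

fit with `mgcv` (fast restricted-likelihood `bam` engine by default; exact
`gam` REML available via `model_spec(engine = "gam")`; a small fixed-df
smooth is the fallback if smoothness selection fails). The basis dimension
is 5 because only three visit waves exist — larger bases are not
identifiable. Substance scores are standardized before fitting.

Adjusted R² for a mixed model is ambiguous, so the package defines it
*marginally*: fitted values exclude the subject random-intercept term, and
the degrees-of-freedom adjustment counts the intercept, the four parametric
covariates, and the age smooth's effective degrees of freedom. The subject
term appears identically in full and null models, so its contribution
cancels in ΔR² = R²_adj(full) − R²_adj(null). Slightly negative ΔR² values
are retained (they carry the overfit penalty's information; downstream
Spearman statistics are rank-based and insensitive to small negatives).
The smooth-term p-value feeds Benjamini–Hochberg FDR flags at q = 0.05
across nodes.

Calibration, verified in the test suite and the analysis scripts: on
all-noise cohorts |mean ΔR²| < 0.01 with essentially no FDR positives; on
planted effects of partial R² {0, 0.05, 0.10, 0.20} at 125 subjects × 3
visits, recovery is monotone and within ±0.05 of each level (the
calibration generator draws covariates independently of age so "variance
uniquely explained by age" coincides with the planted share — in the cohort
generator substance use rises with age, and the unique contribution is then
genuinely smaller than the marginal one); planting a motion-linked artifact
with no age effect leaves ΔR² at zero because FD sits in both models.

## The spin permutation null

SA alignment is Spearman's ρ between a ΔR² map and the SA ranks. Smooth
cortical maps correlate with each other by chance, so significance is
assessed against spun versions of the SA map: uniform random rotations
(Haar measure, via QR with sign fix), applied to the right-hemisphere sphere
and mirrored to the left, with each node mapped to the nearest original node
of its hemisphere (parcel-spin convention; duplicates permitted — there is
no medial wall in the synthetic parcellation). The p-value is two-sided with
the +1 correction, so it is never zero and never below `1/(n_perm + 1)`.
The SA map is the spun object; spinning the data map instead is available
behind a flag (`spin_map = TRUE`).

One subtlety matters for calibration and is easy to get wrong: the spin
test's exchangeability argument requires the null map-generating process to
be closed under the mirrored-rotation group. `random_smooth_map()` therefore
draws its field on the right hemisphere with projection axes uniform over
the *full* sphere and copies it to homologous left nodes. Processes that
look superficially similar — asymmetric fields, or symmetric fields with
axes confined to the mirror plane — are not invariant under that group, and
the test is anti-conservative on them (empirically, type-I error of 0.2–0.3
instead of 0.05) no matter how the assignment step is implemented. With the
invariant process, rejection at α = 0.05 sits inside [0.02, 0.08] over 200
replicate maps, while a naive value shuffle rejects an order of magnitude
too often — the motivating contrast for using spins at all.

## Problem sizes and defaults

| Quantity | Default | Rationale |
|---|---|---|
| nodes / modules | 100 / 13 (demo), 334 / 13 available | module count follows the standard cortical partition |
| subjects × visits | 60 × 3 (demo), 125 × 3 (calibration) | three-wave adolescent cohort shape |
| age range | 12–18 years | adolescent window |
| graph density | 0.25 | consistent density across sessions; 0.05–0.40 sweep available |
| exclusion radius | 30 mm | short-range leakage guard |
| negative-edge fraction | 0.16 | minority anticorrelations |
| spins | 500 (demo) / 1000 (calibration) / 10000 available | permutation floor vs. runtime |
| spline basis k | 5 | three visit waves |

Demo scales keep the full grid and the calibration experiments at desk-scale
runtimes; every size is a config argument, and the full-scale settings are a
one-line change.

## Known limitations

* Euclidean, not geodesic, distances for the exclusion radius.
* The participation coefficient uses the generator's module labels; no
  community detection is performed.
* ΔR² compares full vs. age-free models only; growth-curve shape comparisons
  are out of scope.
* The synthetic covariate distributions are placeholders; effects of
  misspecified covariate models on real data are untested here.
* Spin tests assume spherical, mirror-symmetric hemispheres — exactly true in
  the synthetic world, only approximately true of real inflated surfaces.
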