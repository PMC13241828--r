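#!/usr/bin/env Rscript
# Run the full sign-aware analysis grid on the demo cohort: three
# sign-resolved strength variants plus {clustering, local efficiency,
# participation} x {absolute, positive-only}, each fit with the penalized
# spline mixed model and tested for SA-axis alignment with 500 spins.
# Writes per-cell panels, delta-R2 maps, and the report JSON.

suppressPackageStartupMessages(library(devconn))

report <- run_pipeline(
  simulation = list(n_subjects = 60, n_nodes = 100),
  density = 0.25, min_dist_mm = 30, n_perm = 500, seed = 11,
  output_dir = "results/run"
)
print(report)
cat("\nInterpretation: positive (and overall absolute) strength age effects\n")
cat("align negatively with SA rank (sensorimotor-dominant); negative-strength\n")
cat("and participation cells stay non-significant, as planted.\n")
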