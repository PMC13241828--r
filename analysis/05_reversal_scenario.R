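#!/usr/bin/env Rscript
# The headline qualitative phenomenon: when anticorrelations concentrated
# between association modules strengthen with age, clustering age effects
# align positively with SA rank in absolute-value networks (association-
# dominant) but negatively in positive-only networks (sensorimotor-
# dominant) — the same data, opposite developmental gradients, depending on
# how negative connections are treated.

suppressPackageStartupMessages(library(devconn))
dir.create("results", showWarnings = FALSE)

coh <- simulate_cohort(reversal_scenario_config(seed = 1008))
sa <- coh$parcellation$sa_rank

rows <- lapply(c("absolute", "positive_only"), function(tr) {
  map <- age_effect_map(graph_metric_panel(coh, "clustering", tr))
  data.frame(
    treatment = tr,
    rho_clustering_sa = spearman_alignment(map$delta_r2, sa),
    n_fdr_significant = sum(map$fdr_significant, na.rm = TRUE)
  )
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
write.table(tab, "results/reversal_scenario.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE
)
cat("opposite signs across constructions reproduce the reversal qualitatively\n")
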