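#!/usr/bin/env Rscript
# Step 5 -- collider-bias simulation.
#
# Stratifying on supplementation conditions on a common effect of iron
# status and the unmeasured confounder, which can manufacture score-outcome
# associations under the null.  This run quantifies that type-1-error
# inflation across a grid of iron-to-supplementation effects (log-odds per
# SD), with two falsification arms: setting either confounder arm to zero
# must restore nominal error everywhere.

library(ironmr)

out_dir <- "results/collider"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

main_cfg <- collider_sim_config(
  base = cohort_config(n_mothers = 5000L),
  gamma_grid = c(0, 0.5, 1, 2, 4),
  n_replicates = 1000L,
  seed = 20180330L
)
res <- run_collider_simulation(main_cfg)
sm <- summarize_collider(res, path_tsv = file.path(out_dir, "rejection_rates.tsv"))
ggplot2::ggsave(file.path(out_dir, "rejection_rates.pdf"), sm$plot,
  width = 6, height = 4
)
write.table(as.data.frame(res), file.path(out_dir, "collider_sim_full.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE
)

cat("rejection rate of the within-stratum score-outcome test (alpha = 0.05):\n")
print(sm$table[, c("gamma", "stratum", "rejection_rate", "mc_se")],
  row.names = FALSE, digits = 3
)

for (arm in c("confounder_effect_supp", "confounder_effect_outcome")) {
  base <- cohort_config(n_mothers = 5000L)
  base[[arm]] <- 0
  cfg <- collider_sim_config(
    base = base, gamma_grid = c(0, 0.5, 1, 2, 4),
    n_replicates = 300L, seed = 20180330L
  )
  broken <- run_collider_simulation(cfg)
  summarize_collider(
    broken,
    path_tsv = file.path(out_dir, paste0("rejection_rates_no_", arm, ".tsv"))
  )
  cat(sprintf(
    "%s = 0: rejection rates stay in [%.3f, %.3f] across the grid (nominal 0.05)\n",
    arm,
    min(broken$rejection_rate_unsupp, broken$rejection_rate_supp),
    max(broken$rejection_rate_unsupp, broken$rejection_rate_supp)
  ))
}
cat("written:", out_dir, "\n")
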