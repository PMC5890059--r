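#!/usr/bin/env Rscript
# Step 4 -- summary-data MR estimators.
#
# For each biomarker and each continuous lung-function outcome among
# unsupplemented mothers: pair the published per-allele exposure betas with
# this cohort's per-allele outcome betas, then estimate the causal slope by
# inverse-variance weighting, MR-Egger (whose intercept screens for average
# directional pleiotropy) and the weighted median (robust to <50% invalid
# weight).  Agreement across the three supports a causal reading.

library(ironmr)

out_dir <- "results/mr"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

wt <- iron_weight_table()
cohort <- read.delim("results/cohort/cohort.tsv")
genotypes <- read_genotypes("results/cohort/maternal_dosages.tsv",
  format = "tsv"
)
config <- read_cohort_config("results/cohort/config.json")
unsupp <- cohort[cohort$supp_late == 0, ]

rows <- list()
for (bm in iron_biomarkers()) {
  for (out in c("fev1_sd", "fvc_sd")) {
    pa <- per_allele_associations(
      genotypes, unsupp, out,
      covariates = paste0("pc", 1:10),
      table = wt, biomarker = bm, stratum = "unsupplemented"
    )
    msd <- assemble_mr_summary(wt, pa, bm)
    write_mr_summary(
      msd, file.path(out_dir, paste0("summary_", bm, "_", out, ".tsv"))
    )
    for (e in list(
      mr_ivw(msd), mr_egger(msd),
      mr_weighted_median(msd, n_boot = 2000, seed = config$seed)
    )) {
      rows[[length(rows) + 1L]] <- data.frame(
        biomarker = bm, outcome = out, method = e$method,
        slope = e$slope, slope_se = e$slope_se,
        ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
        intercept = if (is.null(e$intercept)) NA else e$intercept,
        intercept_p = if (is.null(e$intercept_p)) NA else e$intercept_p,
        n_snp = e$n_snp
      )
    }
  }
}
est <- do.call(rbind, rows)
write.table(est, file.path(out_dir, "mr_estimates.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE, na = "."
)

show <- est[
  est$biomarker == "transferrin_saturation" & est$outcome == "fev1_sd",
  c("method", "slope", "ci_low", "ci_high", "p")
]
cat("transferrin saturation -> FEV1, unsupplemented stratum",
  "(SD outcome per SD biomarker; positive = higher iron status helps):\n")
print(show, row.names = FALSE, digits = 3)
cat("written:", out_dir, "\n")
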