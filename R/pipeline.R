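# End-to-end driver: simulate -> score -> validate -> associate -> mr ->
# collider-sim, with TSV artifacts and a reproducibility manifest.

pipeline_stage <- function(stage, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
      call. = FALSE
    )
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains every stage of the analysis: cohort generation, risk scores for
#' all four biomarkers, instrument validation (HWE, pairwise LD,
#' haemoglobin proxy validation), per-allele haemoglobin associations, the
#' score-outcome battery overall and within supplementation strata, the
#' summary-data MR estimators (IVW, MR-Egger, weighted median) for each
#' biomarker against the continuous lung-function outcomes among
#' unsupplemented mothers, and (optionally) a reduced collider-bias
#' simulation.  Each artifact is written as TSV under `out_dir`, and a JSON
#' manifest records the seed, the full configuration, its hash, and a hash
#' of every output file, so identical configs yield identical manifests.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if absent).
#' @param table Weight table (default: packaged 12-SNP table).
#' @param mr_outcomes Continuous outcomes fed to the MR estimators.
#' @param collider `NULL` to skip the collider stage, otherwise a
#'   [collider_sim_config()].
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param force Overwrite existing outputs (default FALSE: refuses to
#'   clobber).
#' @return Invisibly, a list with every result object plus the manifest.
#' @export
run_full_pipeline <- function(config = cohort_config(),
                              out_dir,
                              table = iron_weight_table(),
                              mr_outcomes = c("fev1_sd", "fvc_sd"),
                              collider = NULL,
                              n_boot = 2000L,
                              force = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  artifacts <- c(
    "cohort.tsv", "maternal_dosages.tsv", "scores.tsv", "hwe.tsv",
    "ld_r2.tsv", "proxy_validation.tsv", "per_allele_hb.tsv",
    "score_outcome_associations.tsv", "mr_estimates.tsv",
    if (!is.null(collider)) "collider_sim.tsv", "manifest.json"
  )
  existing <- artifacts[file.exists(file.path(out_dir, artifacts))]
  if (length(existing) > 0L && !force) {
    stop(
      "output file(s) already exist (use force = TRUE to overwrite): ",
      paste(existing, collapse = ", "),
      call. = FALSE
    )
  }
  path <- function(f) file.path(out_dir, f)

  sim <- pipeline_stage("simulate", simulate_cohort(config, table = table))
  cohort <- sim$cohort
  cohort$ige <- exp(cohort$log_ige)

  scores <- pipeline_stage("score", {
    lapply(
      stats::setNames(iron_biomarkers(), iron_biomarkers()),
      function(bm) build_risk_score(sim$maternal_genotypes, table, bm)
    )
  })

  validation <- pipeline_stage("validate", {
    hwe <- hwe_test(sim$maternal_genotypes)
    ld <- pairwise_ld_r2(sim$maternal_genotypes)
    proxy <- do.call(rbind, lapply(scores, function(sc) {
      proxy_validation(sc, cohort)
    }))
    per_allele_hb <- per_allele_associations(
      sim$maternal_genotypes, cohort, "hb_late",
      table = table, biomarker = "iron"
    )
    list(hwe = hwe, ld = ld, proxy = proxy, per_allele_hb = per_allele_hb)
  })

  associations <- pipeline_stage(
    "associate",
    stratified_analysis(cohort, scores)
  )

  mr <- pipeline_stage("mr", {
    unsupp <- cohort[cohort$supp_late == 0, , drop = FALSE]
    rows <- list()
    for (bm in iron_biomarkers()) {
      for (out in mr_outcomes) {
        pa <- per_allele_associations(
          sim$maternal_genotypes, unsupp, out,
          covariates = paste0("pc", 1:10),
          table = table, biomarker = bm, stratum = "unsupplemented"
        )
        msd <- assemble_mr_summary(table, pa, bm)
        ests <- list(
          mr_ivw(msd),
          mr_egger(msd),
          mr_weighted_median(msd, n_boot = n_boot, seed = config$seed)
        )
        for (e in ests) {
          rows[[length(rows) + 1L]] <- data.frame(
            biomarker = bm, outcome = out, method = e$method,
            slope = e$slope, slope_se = e$slope_se,
            ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
            intercept = e$intercept %||% NA_real_,
            intercept_p = e$intercept_p %||% NA_real_,
            n_snp = e$n_snp,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    do.call(rbind, rows)
  })

  collider_res <- if (!is.null(collider)) {
    pipeline_stage("collider-sim", run_collider_simulation(collider, table))
  }

  # ---- artifacts ----------------------------------------------------------
  write_tsv(cohort, path("cohort.tsv"))
  write_genotypes_tsv(sim$maternal_genotypes, path("maternal_dosages.tsv"))
  score_tab <- Reduce(
    function(a, b) merge(a, b, by = "individual_id"),
    lapply(iron_biomarkers(), function(bm) {
      stats::setNames(
        scores[[bm]][, c("individual_id", "standardized")],
        c("individual_id", paste0(bm, "_score"))
      )
    })
  )
  write_tsv(score_tab, path("scores.tsv"))
  write_tsv(validation$hwe, path("hwe.tsv"))
  ld_df <- data.frame(
    snp_id = rownames(validation$ld), validation$ld,
    check.names = FALSE
  )
  write_tsv(ld_df, path("ld_r2.tsv"))
  write_tsv(as.data.frame(validation$proxy), path("proxy_validation.tsv"))
  write_tsv(
    as.data.frame(validation$per_allele_hb),
    path("per_allele_hb.tsv")
  )
  write_tsv(
    as.data.frame(associations),
    path("score_outcome_associations.tsv")
  )
  write_tsv(mr, path("mr_estimates.tsv"))
  if (!is.null(collider_res)) {
    write_tsv(as.data.frame(collider_res), path("collider_sim.tsv"))
  }

  files <- setdiff(artifacts, "manifest.json")
  files <- files[file.exists(file.path(out_dir, files))]
  manifest <- list(
    package = "ironmr",
    version = as.character(utils::packageVersion("ironmr")),
    seed = config$seed,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    outputs = lapply(
      stats::setNames(files, files),
      function(f) rlang::hash(readLines(path(f), warn = FALSE))
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  invisible(list(
    cohort = sim, scores = scores, validation = validation,
    associations = associations, mr = mr, collider = collider_res,
    manifest = manifest
  ))
}
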