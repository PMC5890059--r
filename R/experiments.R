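# Seeded simulation experiments used to validate the pipeline: null
# calibration, parameter recovery, transmission checks and the
# supplementation-dilution pattern.  Each returns plain numbers computed by
# running the package's own machinery, so the test suite and the
# reproducibility script share one implementation.

#' Null calibration of the HWE likelihood-ratio test
#'
#' Simulates genotype counts from exact Hardy-Weinberg proportions and
#' measures how often [hwe_lrt()] rejects at `alpha`.
#'
#' @param n_replicates Simulated SNPs.
#' @param n Individuals per SNP.
#' @param maf Allele frequency of the simulated SNPs.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @return List with `rate`, `mc_se`, `n_replicates`.
#' @export
calibrate_hwe_null <- function(n_replicates = 10000L, n = 1000L, maf = 0.3,
                               alpha = 0.05, seed = 1L) {
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  rej <- with_seed(seed, {
    counts <- stats::rmultinom(n_replicates, n, probs)
    apply(counts, 2L, function(cnt) hwe_lrt(cnt)$p_value < alpha)
  })
  rate <- mean(rej)
  list(
    rate = rate, mc_se = sqrt(rate * (1 - rate) / n_replicates),
    n_replicates = n_replicates
  )
}

#' Null calibration of the score-outcome association test
#'
#' Generates cohorts with every structural effect switched off (no causal
#' effect, no confounding, no differential supplementation, no haemoglobin
#' loading) and measures the rejection rate of the score term in the
#' adjusted score-outcome regression (10 principal components plus late
#' supplementation, the unstratified analysis model).
#'
#' @param n_replicates Replicates.
#' @param n Cohort size per replicate.
#' @param outcome Continuous outcome tested.
#' @param alpha Nominal level.
#' @param seed Seed.
#' @param table Weight table.
#' @return List with `rate`, `mc_se`, `n_replicates`.
#' @export
calibrate_score_outcome_null <- function(n_replicates = 10000L, n = 400L,
                                         outcome = "fev1_sd", alpha = 0.05,
                                         seed = 1L,
                                         table = iron_weight_table()) {
  rej <- with_seed(seed, {
    seeds <- draw_seeds(n_replicates)
    vapply(seq_len(n_replicates), function(i) {
      cfg <- cohort_config(
        n_mothers = n, seed = seeds[i],
        gamma_supp = 0, causal_effect = 0, causal_effect_binary = 0,
        confounder_effect_supp = 0, confounder_effect_outcome = 0,
        hb_loading = 0, supp_restore = 0
      )
      sim <- simulate_cohort(cfg, table = table, children = FALSE)
      df <- sim$cohort
      df$score <- build_risk_score(
        sim$maternal_genotypes, table, "iron"
      )$standardized
      linear_association(
        df, outcome, "score", c(paste0("pc", 1:10), "supp_late")
      )$p < alpha
    }, logical(1))
  })
  rate <- mean(rej)
  list(
    rate = rate, mc_se = sqrt(rate * (1 - rate) / n_replicates),
    n_replicates = n_replicates
  )
}

#' Null calibration of the summary-data MR estimators
#'
#' Simulates summary data with no causal effect and no pleiotropy
#' (`beta_outcome ~ Normal(0, se_outcome^2)` on a fixed instrument design)
#' and measures each estimator's rejection rate at `alpha`.
#'
#' @param n_replicates Replicates.
#' @param beta_exposure,se_outcome Fixed instrument design (defaults: 10
#'   instruments with exposure betas 0.05-0.32 and outcome SEs 0.01-0.05,
#'   the magnitudes of the packaged weight table and a cohort of thousands).
#' @param alpha Nominal level.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Seed.
#' @return Data frame with one row per method: `method`, `rate`, `mc_se`,
#'   `n_replicates`.
#' @export
calibrate_mr_null <- function(n_replicates = 10000L,
                              beta_exposure = seq(0.05, 0.32,
                                length.out = 10
                              ),
                              se_outcome = seq(0.01, 0.05,
                                length.out = 10
                              ),
                              alpha = 0.05, n_boot = 2000L, seed = 1L) {
  p <- length(beta_exposure)
  stopifnot(length(se_outcome) == p)
  rej <- with_seed(seed, {
    seeds <- draw_seeds(n_replicates)
    out <- matrix(NA, n_replicates, 3L,
      dimnames = list(NULL, c("ivw", "egger", "weighted_median"))
    )
    for (i in seq_len(n_replicates)) {
      d <- data.frame(
        snp_id = sprintf("rs%02d", seq_len(p)),
        beta_exposure = beta_exposure,
        beta_outcome = stats::rnorm(p, 0, se_outcome),
        se_outcome = se_outcome
      )
      out[i, "ivw"] <- mr_ivw(d)$p < alpha
      out[i, "egger"] <- mr_egger(d)$p < alpha
      out[i, "weighted_median"] <-
        mr_weighted_median(d, n_boot = n_boot, seed = seeds[i])$p < alpha
    }
    out
  })
  rate <- colMeans(rej)
  data.frame(
    method = names(rate),
    rate = unname(rate),
    mc_se = sqrt(unname(rate) * (1 - unname(rate)) / n_replicates),
    n_replicates = n_replicates,
    stringsAsFactors = FALSE
  )
}

#' Parameter recovery of a known causal effect by the one-sample IV
#'
#' Generates cohorts with a known causal effect of maternal iron on the
#' continuous outcome and estimates it by the ratio (Wald) estimator with
#' the iron score as instrument.  The recovery scenario switches the
#' confounder's outcome arm off so the generator's post-standardisation of
#' the outcome leaves the target effect essentially unscaled; confounded
#' scenarios are exercised by the collider simulation instead.
#'
#' @param n_replicates Replicates.
#' @param n Cohort size.
#' @param causal_effect True effect (SD outcome per SD iron).
#' @param biomarker_h2 Instrument strength.
#' @param outcome Outcome column.
#' @param seed Seed.
#' @param table Weight table.
#' @return List with `estimates` (vector), `mean`, `mc_se`, `true_effect`.
#' @export
recover_causal_effect <- function(n_replicates = 500L, n = 5000L,
                                  causal_effect = 0.1, biomarker_h2 = 0.03,
                                  outcome = "fev1_sd", seed = 1L,
                                  table = iron_weight_table()) {
  est <- with_seed(seed, {
    seeds <- draw_seeds(n_replicates)
    vapply(seq_len(n_replicates), function(i) {
      cfg <- cohort_config(
        n_mothers = n, seed = seeds[i],
        causal_effect = causal_effect, biomarker_h2 = biomarker_h2,
        confounder_effect_outcome = 0
      )
      sim <- simulate_cohort(cfg, table = table, children = FALSE)
      df <- sim$cohort
      df$iron <- sim$post_iron
      df$z <- build_risk_score(
        sim$maternal_genotypes, table, "iron"
      )$standardized
      iv_ratio_estimate(df, outcome, "iron", "z")$estimate
    }, numeric(1))
  })
  list(
    estimates = est, mean = mean(est),
    mc_se = stats::sd(est) / sqrt(n_replicates),
    true_effect = causal_effect, n_replicates = n_replicates
  )
}

#' Mother-child transmission and child-score confounding check
#'
#' Two diagnostics of the transmission model: (1) the per-SNP mother-child
#' dosage correlation (kinship expectation 0.5); (2) with an active
#' maternal causal path, the child score's association with the outcome
#' conditional on the maternal score (null by construction, because the
#' child genotype affects nothing directly) alongside its marginal
#' association (biased through the mother — the overlap the
#' child-genotype check in the analysis is designed to expose).
#'
#' @param n_transmission Cohort size for the correlation check.
#' @param n_replicates,n Replicates and cohort size for the child-score
#'   check.
#' @param causal_effect Maternal causal effect active during the check.
#' @param seed Seed.
#' @param table Weight table.
#' @return List with `dosage_correlations` (per SNP), `child_conditional`
#'   and `child_marginal` (vectors of per-replicate betas).
#' @export
check_transmission <- function(n_transmission = 50000L, n_replicates = 60L,
                               n = 4000L, causal_effect = 0.1, seed = 1L,
                               table = iron_weight_table()) {
  with_seed(seed, {
    mafs <- default_mafs()[table$snp_id]
    mom <- simulate_maternal_genotypes(n_transmission, mafs)
    kid <- simulate_child_genotypes(mom, mafs)
    cors <- vapply(
      seq_along(mafs),
      function(j) stats::cor(mom$dosage[, j], kid$dosage[, j]),
      numeric(1)
    )
    names(cors) <- names(mafs)

    seeds <- draw_seeds(n_replicates)
    betas <- vapply(seq_len(n_replicates), function(i) {
      cfg <- cohort_config(
        n_mothers = n, seed = seeds[i],
        causal_effect = causal_effect
      )
      sim <- simulate_cohort(cfg, table = table, children = TRUE)
      df <- sim$cohort
      df$mom_z <- build_risk_score(
        sim$maternal_genotypes, table, "iron"
      )$standardized
      df$kid_z <- build_risk_score(
        sim$child_genotypes, table, "iron"
      )$standardized
      c(
        conditional = linear_association(
          df, "fev1_sd", "kid_z", "mom_z"
        )$effect,
        marginal = linear_association(df, "fev1_sd", "kid_z")$effect
      )
    }, numeric(2))

    list(
      dosage_correlations = cors,
      child_conditional = betas["conditional", ],
      child_marginal = betas["marginal", ]
    )
  })
}

#' Supplementation-dilution pattern of the haemoglobin proxy
#'
#' With supplementation restoring part of the genetic iron deficit, the
#' score-haemoglobin association in late pregnancy should be stronger
#' among unsupplemented mothers.  Runs replicate cohorts under the default
#' generator and reports how often that ordering holds.
#'
#' @param n_replicates Replicates.
#' @param n Cohort size.
#' @param seed Seed.
#' @param table Weight table.
#' @return List with `prop_stronger_unsupp`, per-replicate slope pairs.
#' @export
check_hb_dilution <- function(n_replicates = 200L, n = 2000L, seed = 1L,
                              table = iron_weight_table()) {
  with_seed(seed, {
    seeds <- draw_seeds(n_replicates)
    slopes <- vapply(seq_len(n_replicates), function(i) {
      cfg <- cohort_config(n_mothers = n, seed = seeds[i])
      sim <- simulate_cohort(cfg, table = table, children = FALSE)
      z <- build_risk_score(sim$maternal_genotypes, table, "iron")$standardized
      hb <- sim$cohort$hb_late
      supp <- sim$cohort$supp_late
      c(
        unsupp = fast_slope(z[supp == 0], hb[supp == 0])[["beta"]],
        supp = fast_slope(z[supp == 1], hb[supp == 1])[["beta"]]
      )
    }, numeric(2))
    list(
      prop_stronger_unsupp =
        mean(abs(slopes["unsupp", ]) > abs(slopes["supp", ])),
      slopes_unsupp = slopes["unsupp", ],
      slopes_supp = slopes["supp", ],
      n_replicates = n_replicates
    )
  })
}
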