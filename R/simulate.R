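# Synthetic mother-child cohort generator.
#
# The generator realises the causal diagram behind the analysis: maternal
# genotype -> latent maternal iron status -> (haemoglobin proxy, iron
# supplementation) -> offspring outcomes, with Mendelian transmission of
# alleles to children and a single unmeasured confounder U acting on both
# supplementation and outcomes (the minimal structure that makes
# stratification on supplementation a collider problem).

#' Default risk-allele frequencies for the 12 weight-table SNPs
#'
#' Synthetic defaults in the plausible European range for each locus; they
#' are generator settings, not estimates from any cohort.
#'
#' @return Named numeric vector of risk-allele frequencies.
#' @export
default_mafs <- function() {
  c(
    rs1799945 = 0.85, rs1800562 = 0.93, rs855791 = 0.55,
    rs8177240 = 0.33, rs7385804 = 0.62, rs744653 = 0.85,
    rs651007 = 0.20, rs411988 = 0.45, rs9990333 = 0.45,
    rs4921915 = 0.55, rs6486121 = 0.60, rs174577 = 0.34
  )
}

#' Cohort generator configuration
#'
#' All knobs of the synthetic cohort in one validated object.  Defaults are
#' anchored so the generated data resemble the study conditions: the
#' score-haemoglobin slope is near -0.1 g/dL per SD of score
#' (`hb_loading * sqrt(biomarker_h2)` = 0.6 * 0.173), the late-pregnancy
#' supplementation rate is 0.424 (2,248 of 5,303 mothers), and the default
#' sample size is 6,002 mother-child pairs.
#'
#' @param n_mothers Number of mother-child pairs.
#' @param mafs Named risk-allele frequencies for the 12 SNPs, in (0, 1).
#' @param biomarker_h2 Fraction of latent-iron variance explained by the
#'   standardised iron score, in \[0, 1).
#' @param gamma_supp Log-odds of late supplementation per SD of *lower*
#'   iron status (a positive value means deficient mothers supplement more).
#' @param supp_base_rate,supp_early_rate Baseline supplementation
#'   probabilities in late and early pregnancy, in (0, 1).
#' @param causal_effect Effect of maternal iron status (SD) on each
#'   continuous offspring outcome (SD units).
#' @param causal_effect_binary Log-odds effect of maternal iron (SD) on the
#'   binary outcomes.
#' @param confounder_effect_supp,confounder_effect_outcome Effects of the
#'   unmeasured standard-Normal confounder U on supplementation (log-odds)
#'   and on outcomes.
#' @param hb_loading Haemoglobin g/dL per SD of iron status.
#' @param hb_mean_early,hb_mean_late,hb_sd Haemoglobin means (early/late
#'   pregnancy) and residual SD, g/dL.
#' @param supp_restore Fraction of a genetic iron deficit restored by
#'   supplementation, in \[0, 1\] (restoration applies only to deficits).
#' @param asthma_prev,atopy_prev Baseline prevalences of the binary
#'   outcomes, in (0, 1).
#' @param ige_log_mean,ige_log_sd Mean and SD of log total IgE (log kU/L).
#' @param ige_iron_effect Effect of maternal iron (SD) on log IgE.
#' @param seed Integer seed; fixes every random draw in the generator.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_mothers = 6002L,
                          mafs = default_mafs(),
                          biomarker_h2 = 0.03,
                          gamma_supp = 0.5,
                          supp_base_rate = 0.424,
                          supp_early_rate = 0.15,
                          causal_effect = 0,
                          causal_effect_binary = 0,
                          confounder_effect_supp = 0.5,
                          confounder_effect_outcome = 0.5,
                          hb_loading = 0.6,
                          hb_mean_early = 12.7,
                          hb_mean_late = 11.5,
                          hb_sd = 1.0,
                          supp_restore = 0.7,
                          asthma_prev = 0.12,
                          atopy_prev = 0.20,
                          ige_log_mean = 3.7,
                          ige_log_sd = 1.1,
                          ige_iron_effect = 0,
                          seed = 1L) {
  cfg <- list(
    n_mothers = as.integer(n_mothers), mafs = mafs,
    biomarker_h2 = biomarker_h2, gamma_supp = gamma_supp,
    supp_base_rate = supp_base_rate, supp_early_rate = supp_early_rate,
    causal_effect = causal_effect,
    causal_effect_binary = causal_effect_binary,
    confounder_effect_supp = confounder_effect_supp,
    confounder_effect_outcome = confounder_effect_outcome,
    hb_loading = hb_loading, hb_mean_early = hb_mean_early,
    hb_mean_late = hb_mean_late, hb_sd = hb_sd,
    supp_restore = supp_restore,
    asthma_prev = asthma_prev, atopy_prev = atopy_prev,
    ige_log_mean = ige_log_mean, ige_log_sd = ige_log_sd,
    ige_iron_effect = ige_iron_effect,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(...) stop("config error: ", ..., call. = FALSE)
  if (cfg$n_mothers < 1L) stop_cfg("`n_mothers` must be >= 1")
  if (any(cfg$mafs <= 0 | cfg$mafs >= 1)) {
    stop_cfg("`mafs` must lie strictly in (0, 1)")
  }
  if (is.null(names(cfg$mafs))) stop_cfg("`mafs` must be named by rsID")
  if (cfg$biomarker_h2 < 0 || cfg$biomarker_h2 >= 1) {
    stop_cfg("`biomarker_h2` must lie in [0, 1)")
  }
  for (p in c("supp_base_rate", "supp_early_rate", "asthma_prev", "atopy_prev")) {
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) {
      stop_cfg("`", p, "` must lie strictly in (0, 1)")
    }
  }
  if (cfg$supp_restore < 0 || cfg$supp_restore > 1) {
    stop_cfg("`supp_restore` must lie in [0, 1]")
  }
  if (cfg$hb_sd <= 0 || cfg$ige_log_sd <= 0) {
    stop_cfg("scale parameters must be positive")
  }
  if (is.na(cfg$seed)) stop_cfg("`seed` is required")
  invisible(cfg)
}

#' Read / write a cohort configuration
#'
#' JSON or YAML files mirroring the [cohort_config()] field names.
#'
#' @param path File path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(vals$mafs)) vals$mafs <- unlist(vals$mafs)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  vals <- unclass(config)
  vals$mafs <- as.list(vals$mafs) # keep rsID names in both formats
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Simulate maternal genotypes under Hardy-Weinberg equilibrium
#'
#' Dosages at each SNP are drawn as the sum of two independent
#' Bernoulli(`maf`) alleles, i.e. genotype probabilities
#' ((1-p)^2, 2p(1-p), p^2), independently across SNPs (the generator assumes
#' no linkage disequilibrium between the 12 loci).
#'
#' @param n Number of mothers.
#' @param mafs Named risk-allele frequencies in \[0, 1\].
#' @param counted_alleles Optional named counted-allele metadata.
#' @param seed Optional seed (isolated from the caller's RNG stream).
#' @return A `genotype_matrix` with integer dosages.
#' @export
simulate_maternal_genotypes <- function(n, mafs, counted_alleles = NULL,
                                        seed = NULL) {
  if (any(mafs < 0 | mafs > 1)) {
    stop("config error: `mafs` must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    d <- vapply(
      mafs,
      function(p) stats::rbinom(n, 1L, p) + stats::rbinom(n, 1L, p),
      integer(n)
    )
    d <- matrix(as.double(d), nrow = n, dimnames = list(
      sprintf("M%05d", seq_len(n)), names(mafs)
    ))
    genotype_matrix(d, counted_alleles = counted_alleles)
  })
}

#' Simulate child genotypes by Mendelian transmission
#'
#' Each child receives one allele drawn uniformly from the mother's two and
#' one paternal allele drawn Bernoulli(`maf`), giving the expected
#' mother-child dosage correlation of 0.5.
#'
#' @param maternal A `genotype_matrix` with integer dosages.
#' @param mafs Named paternal allele frequencies (same SNPs as `maternal`).
#' @param seed Optional seed.
#' @return A `genotype_matrix` of child dosages.
#' @export
simulate_child_genotypes <- function(maternal, mafs, seed = NULL) {
  stopifnot(inherits(maternal, "genotype_matrix"))
  d <- maternal$dosage
  if (anyNA(d) || any(d != round(d))) {
    stop("maternal dosages must be integer-valued for Mendelian transmission",
      call. = FALSE
    )
  }
  snps <- colnames(d)
  if (!all(snps %in% names(mafs))) {
    stop("`mafs` must cover every maternal SNP", call. = FALSE)
  }
  n <- nrow(d)
  with_seed(seed, {
    child <- matrix(0, n, length(snps), dimnames = list(
      sprintf("C%05d", seq_len(n)), snps
    ))
    for (j in seq_along(snps)) {
      m <- d[, j]
      transmitted <- as.double(m == 2)
      het <- m == 1
      if (any(het)) {
        transmitted[het] <- stats::rbinom(sum(het), 1L, 0.5)
      }
      paternal <- stats::rbinom(n, 1L, mafs[[snps[j]]])
      child[, j] <- transmitted + paternal
    }
    genotype_matrix(child, counted_alleles = maternal$counted_alleles)
  })
}

#' Simulate latent iron status, supplementation and the haemoglobin proxy
#'
#' Latent iron status (SD units) loads negatively on the standardised iron
#' risk score: `iron = -sqrt(h2) * z + sqrt(1 - h2) * noise`.  Late
#' supplementation is Bernoulli with log-odds
#' `logit(supp_base_rate) - gamma_supp * iron + confounder_effect_supp * U`,
#' so deficient (low-iron) mothers supplement more.  Supplementation
#' restores `supp_restore` of any deficit (`iron + supp_restore *
#' max(0, -iron)`); late haemoglobin tracks the post-supplementation value,
#' early haemoglobin the pre-supplementation value (early measurements
#' predate most supplementation).
#'
#' @param genotypes Maternal `genotype_matrix`.
#' @param table A `snp_weight_table`.
#' @param config A `cohort_config`.
#' @param u Optional confounder values (standard Normal drawn if `NULL`).
#' @param seed Optional seed.
#' @return List with `latent_iron`, `post_iron`, `u`, `hb_early`, `hb_late`,
#'   `supp_early`, `supp_late`, and `iron_score_z` (the standardised score
#'   the generator used).
#' @export
simulate_iron_and_proxy <- function(genotypes, table, config, u = NULL,
                                    seed = NULL) {
  validate_cohort_config(config)
  n <- nrow(genotypes$dosage)
  score <- build_risk_score(genotypes, table, "iron")
  z <- score$standardized
  h2 <- config$biomarker_h2
  with_seed(seed, {
    latent <- -sqrt(h2) * z + sqrt(1 - h2) * stats::rnorm(n)
    if (is.null(u)) u <- stats::rnorm(n)

    lp_late <- stats::qlogis(config$supp_base_rate) -
      config$gamma_supp * latent + config$confounder_effect_supp * u
    supp_late <- stats::rbinom(n, 1L, stats::plogis(lp_late))

    lp_early <- stats::qlogis(config$supp_early_rate) -
      config$gamma_supp / 2 * latent + config$confounder_effect_supp * u
    supp_early <- stats::rbinom(n, 1L, stats::plogis(lp_early))

    post <- latent + supp_late * config$supp_restore * pmax(0, -latent)

    hb_early <- config$hb_mean_early + config$hb_loading * latent +
      stats::rnorm(n, 0, config$hb_sd)
    hb_late <- config$hb_mean_late + config$hb_loading * post +
      stats::rnorm(n, 0, config$hb_sd)

    list(
      latent_iron = latent, post_iron = post, u = u,
      hb_early = hb_early, hb_late = hb_late,
      supp_early = supp_early, supp_late = supp_late,
      iron_score_z = z
    )
  })
}

#' Simulate offspring outcomes
#'
#' Continuous lung-function outcomes (FEV1, FVC, FEF25-75) are generated as
#' `causal_effect * iron + confounder_effect_outcome * U + Normal(0, 1)` and
#' then re-standardised, emulating age/height/gender-adjusted SD units.
#' Binary outcomes (asthma, atopy) are logistic with the configured baseline
#' prevalence; log IgE is Normal with an optional iron effect.  The ten
#' principal-component covariates are independent standard Normal noise
#' (population substructure itself is out of the generator's scope).
#'
#' @param iron Maternal iron exposure (SD units) the outcomes respond to;
#'   the full generator passes post-supplementation iron, so that
#'   supplementation dilutes genotype-outcome associations.
#' @param u Confounder values.
#' @param config A `cohort_config`.
#' @param seed Optional seed.
#' @return Data frame with `fev1_sd`, `fvc_sd`, `fef2575_sd`, `asthma`,
#'   `atopy`, `log_ige` and `pc1`..`pc10`.
#' @export
simulate_offspring_outcomes <- function(iron, u, config, seed = NULL) {
  validate_cohort_config(config)
  n <- length(iron)
  stopifnot(length(u) == n)
  b <- config$causal_effect
  cu <- config$confounder_effect_outcome
  with_seed(seed, {
    cont <- function() {
      y <- b * iron + cu * u + stats::rnorm(n)
      as.numeric(scale(y))
    }
    bin <- function(prev) {
      lp <- stats::qlogis(prev) + config$causal_effect_binary * iron + cu * u
      stats::rbinom(n, 1L, stats::plogis(lp))
    }
    out <- data.frame(
      fev1_sd = cont(), fvc_sd = cont(), fef2575_sd = cont(),
      asthma = bin(config$asthma_prev), atopy = bin(config$atopy_prev),
      log_ige = config$ige_log_mean + config$ige_iron_effect * iron +
        cu * u + stats::rnorm(n, 0, config$ige_log_sd)
    )
    pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
      dimnames = list(NULL, paste0("pc", 1:10))
    )
    cbind(out, as.data.frame(pcs))
  })
}

#' Generate a full synthetic mother-child cohort
#'
#' Runs the whole generative model under a single seed: maternal genotypes,
#' latent iron status with its haemoglobin proxy and supplementation,
#' offspring outcomes, and (optionally, last, so that the rest of the cohort
#' is unchanged either way) child genotypes.
#'
#' @param config A `cohort_config`.
#' @param table Weight table used for the generator's iron score (default:
#'   the packaged 12-SNP table).
#' @param children Simulate child genotypes too? (default TRUE)
#' @return An object of class `synthetic_cohort`: a list with
#'   `maternal_genotypes`, `child_genotypes` (or NULL), `latent_iron`,
#'   `post_iron`, `u`, `iron_score_z`, `cohort` (the per-pair data frame)
#'   and `truth` (the config).
#' @export
simulate_cohort <- function(config = cohort_config(),
                            table = iron_weight_table(),
                            children = TRUE) {
  validate_cohort_config(config)
  missing_maf <- setdiff(table$snp_id, names(config$mafs))
  if (length(missing_maf) > 0L) {
    stop(
      "config error: `mafs` missing for SNP(s) ",
      paste(missing_maf, collapse = ", "),
      call. = FALSE
    )
  }
  with_seed(config$seed, {
    mafs <- config$mafs[table$snp_id]
    mg <- simulate_maternal_genotypes(
      config$n_mothers, mafs,
      counted_alleles = default_counted_alleles(table)
    )
    iron <- simulate_iron_and_proxy(mg, table, config)
    outcomes <- simulate_offspring_outcomes(iron$post_iron, iron$u, config)
    cg <- if (children) simulate_child_genotypes(mg, mafs) else NULL

    cohort <- cbind(
      data.frame(
        individual_id = rownames(mg$dosage),
        hb_early = iron$hb_early, hb_late = iron$hb_late,
        supp_early = iron$supp_early, supp_late = iron$supp_late,
        stringsAsFactors = FALSE
      ),
      outcomes
    )
    rownames(cohort) <- NULL

    structure(
      list(
        maternal_genotypes = mg, child_genotypes = cg,
        latent_iron = iron$latent_iron, post_iron = iron$post_iron,
        u = iron$u, iron_score_z = iron$iron_score_z,
        cohort = cohort, truth = config
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(
    "<synthetic_cohort> ", nrow(x$cohort), " mother-child pairs, seed ",
    x$truth$seed,
    if (is.null(x$child_genotypes)) " (no child genotypes)" else "",
    "\n",
    sep = ""
  )
  invisible(x)
}
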