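# One-sample association models: linear, logistic, geometric-mean-ratio,
# per-allele, stratified battery, and haemoglobin proxy validation.

assoc_row <- function(outcome, exposure, stratum, n, effect, scale,
                      se, ci_low, ci_high, p, covariates) {
  out <- data.frame(
    outcome = outcome, exposure = exposure, stratum = stratum,
    n = n, effect = effect, scale = scale, se = se,
    ci_low = ci_low, ci_high = ci_high, p = p,
    covariates = paste(covariates, collapse = "+"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("association_result", "data.frame")
  out
}

check_no_alias <- function(fit) {
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop(
      "collinear covariate(s), coefficient not estimable: ",
      paste(names(co)[is.na(co)], collapse = ", "),
      call. = FALSE
    )
  }
}

model_data <- function(data, vars) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    stop(
      "column(s) not found in data: ", paste(missing_vars, collapse = ", "),
      call. = FALSE
    )
  }
  df <- data[, vars, drop = FALSE]
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Linear association of a continuous outcome with an exposure
#'
#' Ordinary least squares of `outcome` on `exposure` plus covariates on
#' complete cases, reporting the exposure coefficient with its Wald
#' (t-based) confidence interval and two-sided p value.
#'
#' @param data Data frame.
#' @param outcome,exposure Column names (exposure: a score or a dosage).
#' @param covariates Character vector of adjustment column names.
#' @param stratum Label recorded in the result (default "all").
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row `association_result` data frame.
#' @export
linear_association <- function(data, outcome, exposure,
                               covariates = character(),
                               stratum = "all", conf_level = 0.95) {
  df <- model_data(data, c(outcome, exposure, covariates))
  fit <- stats::lm(stats::reformulate(c(exposure, covariates), outcome),
    data = df
  )
  check_no_alias(fit)
  sm <- summary(fit)$coefficients
  b <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  assoc_row(
    outcome, exposure, stratum, nrow(df), b, "beta", se,
    b - tq * se, b + tq * se, sm[exposure, "Pr(>|t|)"], covariates
  )
}

#' Logistic association of a binary outcome with an exposure
#'
#' Maximum-likelihood logistic regression; the exposure effect is reported
#' as an odds ratio per unit (per SD for a standardised score, per risk
#' allele for a dosage) with a Wald CI on the log-odds scale.
#'
#' @inheritParams linear_association
#' @return A one-row `association_result` with `scale = "or"`.
#' @export
logistic_association <- function(data, outcome, exposure,
                                 covariates = character(),
                                 stratum = "all", conf_level = 0.95) {
  df <- model_data(data, c(outcome, exposure, covariates))
  y <- df[[outcome]]
  if (!all(y %in% c(0, 1))) {
    stop("outcome `", outcome, "` must be coded 0/1", call. = FALSE)
  }
  if (length(unique(df[[exposure]])) < 2L) {
    stop("exposure `", exposure, "` is constant; odds ratio undefined",
      call. = FALSE
    )
  }
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(c(exposure, covariates), outcome),
      data = df, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-12, maxit = 100L)
    )
  )
  check_no_alias(fit)
  sm <- summary(fit)$coefficients
  b <- sm[exposure, "Estimate"]
  se <- sm[exposure, "Std. Error"]
  if (!fit$converged || abs(b) > 20 || se > 100) {
    stop(
      "logistic model did not stabilise (possible complete separation): ",
      exposure, " coefficient ", signif(b, 3), ", SE ", signif(se, 3),
      call. = FALSE
    )
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  assoc_row(
    outcome, exposure, stratum, nrow(df), exp(b), "or", se,
    exp(b - zq * se), exp(b + zq * se), sm[exposure, "Pr(>|z|)"], covariates
  )
}

#' Geometric mean ratio for total IgE
#'
#' Linear regression of log-transformed IgE; the exposure effect is
#' reported as a geometric mean ratio `exp(beta)` with confidence limits
#' from heteroscedasticity-robust (Huber-White, HC1) variances.
#'
#' @param data Data frame.
#' @param ige Column of total IgE in kU/L; must be strictly positive.
#' @param exposure,covariates,stratum,conf_level As in
#'   [linear_association()].
#' @return A one-row `association_result` with `scale = "gmr"`;
#'   `effect`, `ci_low`, `ci_high` are ratios, `se` is on the log scale.
#' @export
geometric_mean_ratio <- function(data, ige, exposure,
                                 covariates = character(),
                                 stratum = "all", conf_level = 0.95) {
  df <- model_data(data, c(ige, exposure, covariates))
  bad <- which(df[[ige]] <= 0)
  if (length(bad) > 0L) {
    stop(
      "non-positive IgE values cannot be log-transformed (records: ",
      paste(utils::head(bad, 10L), collapse = ", "),
      if (length(bad) > 10L) ", ..." else "", ")",
      call. = FALSE
    )
  }
  df$.log_ige <- log(df[[ige]])
  fit <- stats::lm(stats::reformulate(c(exposure, covariates), ".log_ige"),
    data = df
  )
  check_no_alias(fit)
  vc <- sandwich::vcovHC(fit, type = "HC1")
  ct <- lmtest::coeftest(fit, vcov. = vc)
  b <- ct[exposure, "Estimate"]
  se <- ct[exposure, "Std. Error"]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$df.residual)
  assoc_row(
    ige, exposure, stratum, nrow(df), exp(b), "gmr", se,
    exp(b - tq * se), exp(b + tq * se), ct[exposure, "Pr(>|t|)"], covariates
  )
}

#' Per-SNP (per risk allele) associations
#'
#' One regression per SNP with the risk-allele dosage entering as a linear
#' term, giving per-allele effect estimates and p-trend values.  Dosages
#' are oriented to the risk alleles of `biomarker` before fitting, and only
#' that biomarker's SNPs are analysed, unless `biomarker` is `NULL` (then
#' every column of the matrix is used as stored).
#'
#' @param genotypes A `genotype_matrix`.
#' @param data Data frame of outcomes/covariates, rows aligned with the
#'   dosage rows via `individual_id`.
#' @param outcome,covariates,stratum As in [linear_association()].
#' @param family `"linear"` or `"logistic"`.
#' @param table,biomarker Weight table and biomarker used to select and
#'   orient SNPs (both `NULL` to analyse all SNPs as stored).
#' @return An `association_result` data frame, one row per SNP.
#' @export
per_allele_associations <- function(genotypes, data, outcome,
                                    covariates = character(),
                                    family = c("linear", "logistic"),
                                    table = NULL, biomarker = NULL,
                                    stratum = "all") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  family <- match.arg(family)
  d <- genotypes$dosage
  if (!is.null(table) && !is.null(biomarker)) {
    bm <- match_biomarker(biomarker)
    snps <- select_snps_for_biomarker(table, bm)
    missing <- setdiff(snps, colnames(d))
    if (length(missing) > 0L) {
      stop(
        "selected SNP(s) absent from genotype matrix: ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    d <- d[, snps, drop = FALSE]
    counted <- genotypes$counted_alleles[snps]
    risk <- biomarker_risk_alleles(table, bm)
    flip <- !is.na(counted) & counted != risk
    if (any(flip)) {
      d[, flip] <- 2 - d[, flip, drop = FALSE]
    }
  }
  if (!"individual_id" %in% names(data)) {
    stop("`data` needs an `individual_id` column to align with genotypes",
      call. = FALSE
    )
  }
  idx <- match(data$individual_id, rownames(d))
  if (anyNA(idx)) {
    stop("some `individual_id`s have no genotype row", call. = FALSE)
  }
  fit_one <- switch(family,
    linear = linear_association,
    logistic = logistic_association
  )
  rows <- lapply(colnames(d), function(snp) {
    df <- data
    df[[snp]] <- d[idx, snp]
    fit_one(df, outcome, snp, covariates, stratum = stratum)
  })
  do.call(rbind, rows)
}

#' Haemoglobin proxy validation of the genotypic instruments
#'
#' Linear regressions of maternal haemoglobin (g/dL) on the standardised
#' risk score: early and late pregnancy overall, and late pregnancy within
#' late-supplementation strata (where the instrument-biomarker association
#' is expected to be stronger among unsupplemented women).
#'
#' @param score A `risk_score`.
#' @param cohort Cohort data frame with `individual_id`, `hb_early`,
#'   `hb_late` and (for stratification) `supp_late`.
#' @param stratify_by_supp Also report late-haemoglobin associations within
#'   supplementation strata (default TRUE).
#' @param covariates Additional adjustment columns (default none; the
#'   score-haemoglobin models are unadjusted by default).
#' @param min_stratum Strata smaller than this are skipped with a warning
#'   (default 10).
#' @return An `association_result` data frame (outcome column identifies
#'   the haemoglobin timing, stratum column the supplementation stratum).
#' @export
proxy_validation <- function(score, cohort, stratify_by_supp = TRUE,
                             covariates = character(), min_stratum = 10L) {
  stopifnot(inherits(score, "risk_score"))
  for (col in c("hb_early", "hb_late")) {
    if (!col %in% names(cohort)) {
      stop("cohort is missing haemoglobin column `", col, "`", call. = FALSE)
    }
  }
  label <- paste0(attr(score, "biomarker"), "_score")
  df <- merge(cohort, stats::setNames(
    score[, c("individual_id", "standardized")],
    c("individual_id", label)
  ), by = "individual_id")

  rows <- list(
    linear_association(df, "hb_early", label, covariates, stratum = "all"),
    linear_association(df, "hb_late", label, covariates, stratum = "all")
  )
  if (stratify_by_supp) {
    if (!"supp_late" %in% names(df)) {
      stop("cohort is missing `supp_late` for stratification", call. = FALSE)
    }
    for (s in c(0, 1)) {
      sub <- df[df$supp_late == s, , drop = FALSE]
      lab <- if (s == 0) "unsupplemented" else "supplemented"
      if (nrow(sub) < min_stratum) {
        warning(
          "stratum '", lab, "' has fewer than ", min_stratum,
          " records; skipped",
          call. = FALSE
        )
        next
      }
      rows[[length(rows) + 1L]] <-
        linear_association(sub, "hb_late", label, covariates, stratum = lab)
    }
  }
  do.call(rbind, rows)
}

# default outcome battery: outcome column -> model family
.outcome_battery <- list(
  atopy = "logistic", asthma = "logistic",
  fev1_sd = "linear", fvc_sd = "linear", fef2575_sd = "linear"
)

#' Score-outcome battery, overall and within supplementation strata
#'
#' Runs the full set of score-outcome models (logistic for asthma/atopy,
#' linear for the lung-function SD units, geometric mean ratio for IgE when
#' an `ige` column is present) for each supplied score: once on the whole
#' sample, adjusted for supplementation and the stratifier, and once within
#' each observed stratum of `stratifier` (without that adjustment).
#'
#' @param cohort Cohort data frame (`individual_id`, outcomes, `pc1..pc10`,
#'   supplementation flags).
#' @param scores A single `risk_score` or list of them.
#' @param stratifier Binary column to stratify on (default `"supp_late"`).
#' @param covariates Adjustment set for every model (default the 10
#'   principal components).
#' @param supp_covariates Extra adjustment for the unstratified models
#'   (default early and late supplementation).
#' @param min_stratum Strata smaller than this are skipped with a warning.
#' @return An `association_result` data frame; `exposure` identifies the
#'   score, `stratum` is `"all"` or the stratifier level.
#' @export
stratified_analysis <- function(cohort, scores,
                                stratifier = "supp_late",
                                covariates = paste0("pc", 1:10),
                                supp_covariates = c("supp_early", "supp_late"),
                                min_stratum = 10L) {
  if (inherits(scores, "risk_score")) {
    scores <- list(scores)
  }
  if (!stratifier %in% names(cohort)) {
    stop("stratifier `", stratifier, "` not found in cohort", call. = FALSE)
  }
  sv <- cohort[[stratifier]]
  if (!all(sv %in% c(0, 1))) {
    stop("stratifier `", stratifier, "` must be binary 0/1", call. = FALSE)
  }

  df <- cohort
  labels <- character(0)
  for (sc in scores) {
    stopifnot(inherits(sc, "risk_score"))
    lab <- paste0(attr(sc, "biomarker"), "_score")
    labels <- c(labels, lab)
    df <- merge(df, stats::setNames(
      sc[, c("individual_id", "standardized")],
      c("individual_id", lab)
    ), by = "individual_id")
  }

  battery <- function(data, exposure, covs, stratum) {
    rows <- list()
    for (out in names(.outcome_battery)) {
      if (!out %in% names(data)) next
      fam <- .outcome_battery[[out]]
      rows[[length(rows) + 1L]] <- if (fam == "linear") {
        linear_association(data, out, exposure, covs, stratum = stratum)
      } else {
        logistic_association(data, out, exposure, covs, stratum = stratum)
      }
    }
    if ("ige" %in% names(data)) {
      rows[[length(rows) + 1L]] <-
        geometric_mean_ratio(data, "ige", exposure, covs, stratum = stratum)
    }
    do.call(rbind, rows)
  }

  results <- list()
  supp_adj <- intersect(unique(supp_covariates), names(df))
  # a supplementation flag that never varies carries no adjustment
  constant <- vapply(
    supp_adj, function(v) length(unique(df[[v]])) < 2L, logical(1)
  )
  if (any(constant)) {
    message(
      "dropping constant adjustment column(s): ",
      paste(supp_adj[constant], collapse = ", ")
    )
    supp_adj <- supp_adj[!constant]
  }
  for (lab in labels) {
    results[[length(results) + 1L]] <-
      battery(df, lab, c(covariates, supp_adj), "all")
  }

  strata <- sort(unique(sv))
  any_stratum <- FALSE
  for (s in strata) {
    sub <- df[df[[stratifier]] == s, , drop = FALSE]
    stratum_lab <- paste0(stratifier, "=", s)
    if (nrow(sub) < min_stratum) {
      warning("stratum ", stratum_lab, " has fewer than ", min_stratum,
        " records; skipped",
        call. = FALSE
      )
      next
    }
    any_stratum <- TRUE
    for (lab in labels) {
      results[[length(results) + 1L]] <-
        battery(sub, lab, covariates, stratum_lab)
    }
  }
  if (!any_stratum) {
    stop("no stratum of `", stratifier, "` has enough records", call. = FALSE)
  }
  do.call(rbind, results)
}
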