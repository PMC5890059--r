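# Summary-data Mendelian randomisation estimators: inverse-variance
# weighted, MR-Egger, weighted median; plus assembly of harmonised summary
# data and a one-sample ratio (Wald) estimator.
#
# Weighting is first-order throughout: the exposure betas come from a GWA
# meta-analysis that publishes point estimates without standard errors, so
# exposure-side uncertainty cannot be propagated.  IVW and Egger use
# fixed-effect weighting with the outcome variances taken as known, i.e.
# cov(coef) = (X'WX)^-1 with no residual rescaling, so their tests are
# exactly nominal when the outcome SEs are correct.

#' Assemble harmonised MR summary data
#'
#' Pairs each of the biomarker's SNPs with its per-allele outcome
#' association from the cohort, and orients every SNP so the exposure beta
#' is non-negative (flipping the signs of both betas together, which leaves
#' all estimators unchanged but makes the Egger intercept interpretable).
#' Odds-ratio outcome rows are converted to log odds.
#'
#' @param table A `snp_weight_table`.
#' @param per_allele An `association_result` data frame from
#'   [per_allele_associations()], one row per SNP (`exposure` = rsID).
#' @param biomarker Biomarker whose exposure betas to use.
#' @return An object of class `mr_summary_data`: data frame with `snp_id`,
#'   `beta_exposure`, `beta_outcome`, `se_outcome`.
#' @export
assemble_mr_summary <- function(table, per_allele, biomarker) {
  bm <- match_biomarker(biomarker)
  snps <- select_snps_for_biomarker(table, bm)
  missing <- setdiff(snps, per_allele$exposure)
  if (length(missing) > 0L) {
    stop(
      "SNP(s) in weight table but absent from per-allele results: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  idx <- match(snps, per_allele$exposure)
  eff <- per_allele$effect[idx]
  beta_y <- ifelse(per_allele$scale[idx] == "or", log(eff), eff)
  se_y <- per_allele$se[idx]
  beta_x <- unname(biomarker_effects(table, bm))

  if (any(!is.finite(se_y) | se_y <= 0)) {
    stop("outcome standard errors must be positive", call. = FALSE)
  }
  flip <- sign(beta_x)
  out <- data.frame(
    snp_id = snps,
    beta_exposure = beta_x * flip,
    beta_outcome = beta_y * flip,
    se_outcome = se_y,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_summary_data", "data.frame")
  out
}

check_mr_data <- function(data, min_snps = 1L) {
  req <- c("snp_id", "beta_exposure", "beta_outcome", "se_outcome")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop(
      "MR summary data needs columns ", paste(req, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) < min_snps) {
    stop("need at least ", min_snps, " SNP(s), got ", nrow(data),
      call. = FALSE
    )
  }
  if (anyDuplicated(data$snp_id)) {
    stop("duplicate SNPs in MR summary data", call. = FALSE)
  }
  if (anyNA(data[, req[-1]])) {
    stop("MR summary data must have no absent values", call. = FALSE)
  }
  if (any(data$se_outcome <= 0)) {
    stop("outcome standard errors must be positive", call. = FALSE)
  }
  invisible(data)
}

mr_estimate <- function(method, slope, slope_se, n_snp,
                        intercept = NULL, intercept_se = NULL,
                        conf_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(
    method = method, slope = slope, slope_se = slope_se,
    intercept = intercept, intercept_se = intercept_se,
    ci_low = slope - zq * slope_se, ci_high = slope + zq * slope_se,
    p = 2 * stats::pnorm(-abs(slope / slope_se)),
    n_snp = n_snp
  )
  if (!is.null(intercept)) {
    res$intercept_ci_low <- intercept - zq * intercept_se
    res$intercept_ci_high <- intercept + zq * intercept_se
    res$intercept_p <- 2 * stats::pnorm(-abs(intercept / intercept_se))
  }
  class(res) <- "mr_estimate"
  res
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(
    "<mr_estimate> ", x$method, ": slope ", signif(x$slope, 4),
    " (", signif(x$ci_low, 4), ", ", signif(x$ci_high, 4), "), p = ",
    signif(x$p, 3),
    sep = ""
  )
  if (!is.null(x$intercept)) {
    cat(
      "; intercept ", signif(x$intercept, 4),
      " (p = ", signif(x$intercept_p, 3), ")",
      sep = ""
    )
  }
  cat(" [", x$n_snp, " SNPs]\n", sep = "")
  invisible(x)
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted regression of the SNP-outcome associations on the SNP-exposure
#' associations through the origin, with first-order weights
#' `w_j = 1 / se_outcome_j^2`:
#' `slope = sum(w b_x b_y) / sum(w b_x^2)`,
#' `se = sqrt(1 / sum(w b_x^2))`.
#' With a single SNP this is the Wald ratio `b_y / b_x`.
#'
#' @param data An `mr_summary_data` (or data frame with the same columns).
#' @param conf_level Confidence level (default 0.95).
#' @return An `mr_estimate` with `method = "ivw"`.
#' @export
mr_ivw <- function(data, conf_level = 0.95) {
  check_mr_data(data, min_snps = 1L)
  bx <- data$beta_exposure
  by <- data$beta_outcome
  w <- 1 / data$se_outcome^2
  denom <- sum(w * bx^2)
  if (denom == 0) {
    stop("all exposure betas are zero; IVW slope undefined", call. = FALSE)
  }
  mr_estimate("ivw",
    slope = sum(w * bx * by) / denom,
    slope_se = sqrt(1 / denom),
    n_snp = nrow(data), conf_level = conf_level
  )
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome on the SNP-exposure
#' associations *with* an unconstrained intercept (weights
#' `1 / se_outcome^2`).  The intercept estimates average directional
#' pleiotropy (under the InSIDE assumption); the slope is the causal
#' estimate.  Exposure betas are oriented non-negative internally (joint
#' sign flips, to which all estimates are invariant).  Constraining the
#' intercept to zero recovers the IVW estimator exactly.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with `method = "egger"` and intercept fields.
#' @export
mr_egger <- function(data, conf_level = 0.95) {
  check_mr_data(data, min_snps = 3L)
  flip <- ifelse(data$beta_exposure < 0, -1, 1)
  bx <- data$beta_exposure * flip
  by <- data$beta_outcome * flip
  w <- 1 / data$se_outcome^2
  x <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(x, w * x)
  if (abs(det(xtwx)) < 1e-12 * sum(w)^2 || stats::var(bx) == 0) {
    stop("exposure betas have no spread; Egger regression is singular",
      call. = FALSE
    )
  }
  cov <- solve(xtwx)
  coef <- drop(cov %*% crossprod(x, w * by))
  mr_estimate("egger",
    slope = coef[["slope"]], slope_se = sqrt(cov["slope", "slope"]),
    intercept = coef[["intercept"]],
    intercept_se = sqrt(cov["intercept", "intercept"]),
    n_snp = nrow(data), conf_level = conf_level
  )
}

# Weighted median of `r` with weights `w` (positive), by linear
# interpolation of the sorted ratios at cumulative standardised weight 0.5
# using the midpoint convention s_j = cum(w)_j - w_j / 2.
weighted_median_est <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  p <- length(r)
  j <- findInterval(0.5, s)
  if (j <= 0L) {
    return(r[1L])
  }
  if (j >= p) {
    return(r[p])
  }
  r[j] + (r[j + 1L] - r[j]) * (0.5 - s[j]) / (s[j + 1L] - s[j])
}

# Row-wise weighted median for an m x p matrix of values with one shared
# positive weight vector of length p.  Used for the parametric bootstrap,
# where the weights (beta_exposure^2 / se^2) do not change across
# bootstrap draws.  Fully vectorised: elements are sorted within rows via a
# single order(), cumulative weights reset per row, and the interpolation
# index found with one findInterval() on row-shifted cumulative weights.
row_weighted_median <- function(vals, w) {
  m <- nrow(vals)
  p <- ncol(vals)
  stopifnot(length(w) == p, all(w > 0))
  w <- w / sum(w)
  o <- order(row(vals), vals)
  sv <- vals[o]
  sw <- w[(o - 1L) %/% m + 1L]
  # per-row cumulative weights: each row block sums to 1, so subtracting
  # the row offset resets the cumsum (fp error ~1e-13 * m, harmless here)
  cw <- cumsum(sw) - rep(seq_len(m) - 1L, each = p)
  s <- cw - sw / 2
  shift <- rep(seq_len(m) - 1L, each = p)
  k <- findInterval(0.5 + (seq_len(m) - 1L), s + shift)
  j <- k - (seq_len(m) - 1L) * p # within-row index, in [1, p]
  est <- numeric(m)
  at_end <- j >= p
  est[at_end] <- sv[k[at_end]]
  mid <- !at_end
  if (any(mid)) {
    km <- k[mid]
    est[mid] <- sv[km] +
      (sv[km + 1L] - sv[km]) * (0.5 - s[km]) / (s[km + 1L] - s[km])
  }
  est
}

#' Weighted median MR estimate
#'
#' The median of the per-SNP ratio estimates `b_y / b_x`, weighted by
#' precision (`w_j = b_x^2 / se_outcome^2`, normalised), interpolated at
#' cumulative standardised weight 0.5 with the midpoint convention
#' `s_j = cum(w)_j - w_j / 2`.  Consistent when at least half the weight
#' comes from valid instruments.
#'
#' The standard error comes from a seeded fitted-model parametric
#' bootstrap: outcome betas are redrawn as
#' `Normal(slope * beta_exposure, se_outcome)` and the estimator is
#' recomputed.  Because the weighted median is equivariant under location
#' shifts of the ratio estimates, this reproduces the estimator's sampling
#' law exactly under its own model (all instruments valid), giving a
#' well-calibrated test; centring the draws on the raw observed outcome
#' betas instead would overstate the dispersion whenever the observed
#' ratios are spread out.  Under pleiotropy the fitted-model SE can be
#' optimistic — the Egger intercept is the companion diagnostic for that.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 2000L, seed = 1L,
                               conf_level = 0.95) {
  check_mr_data(data, min_snps = 2L)
  bx <- data$beta_exposure
  by <- data$beta_outcome
  se <- data$se_outcome
  if (any(bx == 0)) {
    stop("zero exposure beta: ratio estimate undefined for SNP(s) ",
      paste(data$snp_id[bx == 0], collapse = ", "),
      call. = FALSE
    )
  }
  w <- bx^2 / se^2
  est <- weighted_median_est(by / bx, w)
  fitted <- est * bx
  boot <- with_seed(seed, {
    pert <- matrix(
      stats::rnorm(n_boot * length(by), mean = fitted, sd = se),
      nrow = n_boot, byrow = TRUE
    )
    ratios <- sweep(pert, 2L, bx, "/")
    row_weighted_median(ratios, w)
  })
  mr_estimate("weighted_median",
    slope = est, slope_se = stats::sd(boot),
    n_snp = nrow(data), conf_level = conf_level
  )
}

#' One-sample IV (ratio) estimate
#'
#' The Wald ratio of the reduced-form (instrument-outcome) to the
#' first-stage (instrument-exposure) regression coefficients, with a
#' first-order delta-method standard error.  Used for parameter-recovery
#' checks against the cohort generator, where the latent exposure is
#' available.
#'
#' @param data Data frame.
#' @param outcome,exposure,instrument Column names.
#' @param covariates Adjustment columns used in both stages.
#' @return List with `estimate`, `se`, `first_stage_beta`,
#'   `reduced_form_beta`.
#' @export
iv_ratio_estimate <- function(data, outcome, exposure, instrument,
                              covariates = character()) {
  red <- linear_association(data, outcome, instrument, covariates)
  first <- linear_association(data, exposure, instrument, covariates)
  if (first$effect == 0) {
    stop("first-stage coefficient is zero; ratio undefined", call. = FALSE)
  }
  est <- red$effect / first$effect
  se <- sqrt(
    red$se^2 / first$effect^2 +
      red$effect^2 * first$se^2 / first$effect^4
  )
  list(
    estimate = est, se = se,
    first_stage_beta = first$effect, reduced_form_beta = red$effect
  )
}

#' Read / write MR summary data as TSV
#'
#' @param path TSV path with columns `snp_id`, `beta_exposure`,
#'   `beta_outcome`, `se_outcome`.
#' @return `read_mr_summary()` returns an `mr_summary_data`.
#' @export
read_mr_summary <- function(path) {
  tab <- read_tsv(path)
  check_mr_data(tab)
  class(tab) <- c("mr_summary_data", "data.frame")
  tab
}

#' @rdname read_mr_summary
#' @param data An `mr_summary_data`.
#' @export
write_mr_summary <- function(data, path) {
  check_mr_data(data)
  write_tsv(as.data.frame(data), path)
}
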