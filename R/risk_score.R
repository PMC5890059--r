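# Weighted genotypic risk scores.

#' Build a weighted genotypic risk score for one iron biomarker
#'
#' Sums risk-allele dosages over the SNPs with a published effect on the
#' chosen biomarker, each weighted by the magnitude of its GWAS effect
#' estimate, so that a higher score always predicts lower iron status
#' (for transferrin: higher transferrin, the deficiency direction).  The raw
#' score is then standardised to mean 0, SD 1 over the analysis sample,
#' matching per-SD-increase reporting.
#'
#' Dosages are re-oriented per SNP when the matrix's counted allele differs
#' from the biomarker's risk allele (`d -> 2 - d`); this matters for
#' rs8177240, whose iron risk allele (T) is the opposite strand partner of
#' its transferrin/transferrin-saturation risk allele (G).  Missing dosages
#' are mean-imputed per SNP; individuals missing more than
#' `max_missing` of the selected SNPs are dropped with a warning.
#'
#' @param genotypes A `genotype_matrix`.
#' @param table A `snp_weight_table`.
#' @param biomarker Biomarker label (see [iron_biomarkers()]).
#' @param max_missing Maximum tolerated fraction of missing dosages among
#'   the selected SNPs before an individual is dropped (default 0.2).
#' @return An object of class `risk_score`: a data frame with columns
#'   `individual_id`, `raw`, `standardized`, plus attributes `biomarker`,
#'   `snps_used` and `weights`.
#' @export
build_risk_score <- function(genotypes, table, biomarker, max_missing = 0.2) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  stopifnot(inherits(table, "snp_weight_table"))
  bm <- match_biomarker(biomarker)

  snps <- select_snps_for_biomarker(table, bm)
  if (length(snps) == 0L) {
    stop("no SNPs with an effect estimate for biomarker '", bm, "'",
      call. = FALSE
    )
  }
  missing <- setdiff(snps, colnames(genotypes$dosage))
  if (length(missing) > 0L) {
    stop(
      "selected SNP(s) absent from genotype matrix: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }

  d <- genotypes$dosage[, snps, drop = FALSE]
  counted <- genotypes$counted_alleles[snps]
  risk <- biomarker_risk_alleles(table, bm)

  flip <- !is.na(counted) & counted != risk
  if (any(flip)) {
    d[, flip] <- 2 - d[, flip, drop = FALSE]
  }

  # drop individuals too incomplete to score, then mean-impute the rest
  miss_frac <- rowMeans(is.na(d))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warning(
      sum(drop), " individual(s) dropped: more than ",
      round(100 * max_missing), "% of selected SNPs missing",
      call. = FALSE
    )
    d <- d[!drop, , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    stop("no individuals left to score", call. = FALSE)
  }
  if (anyNA(d)) {
    for (j in seq_len(ncol(d))) {
      nas <- is.na(d[, j])
      if (any(nas)) {
        d[nas, j] <- mean(d[, j], na.rm = TRUE)
      }
    }
  }

  w <- abs(biomarker_effects(table, bm))
  raw <- drop(d %*% w)

  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    stop(
      "degenerate input: raw risk score has zero variance, cannot standardise",
      call. = FALSE
    )
  }
  standardized <- (raw - mean(raw)) / s

  out <- data.frame(
    individual_id = rownames(d),
    raw = raw,
    standardized = standardized,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "biomarker") <- bm
  attr(out, "snps_used") <- snps
  attr(out, "weights") <- w
  class(out) <- c("risk_score", "data.frame")
  out
}

#' @export
print.risk_score <- function(x, ...) {
  cat(
    "<risk_score> biomarker=", attr(x, "biomarker"),
    ", ", nrow(x), " individuals, ",
    length(attr(x, "snps_used")), " SNPs\n",
    sep = ""
  )
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
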