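# Instrument-validation statistics: Hardy-Weinberg likelihood-ratio test
# and pairwise composite (dosage-correlation) LD.

#' Hardy-Weinberg equilibrium likelihood-ratio test
#'
#' Compares the saturated multinomial likelihood of the observed genotype
#' counts with the HWE-constrained likelihood at the MLE allele frequency
#' `p = (2 n2 + n1) / (2 n)`:
#' `LRT = 2 * (ll_saturated - ll_HWE)`, referred to a chi-square with 1
#' degree of freedom (the asymptotic p value).
#'
#' @param counts Integer vector `c(n0, n1, n2)` of genotype counts by dosage
#'   of the counted allele (0, 1, 2 copies).
#' @param snp_id Optional label carried into the result.
#' @return An object of class `hwe_result`: list with `snp_id`, `counts`,
#'   `allele_freq`, `lrt_stat`, `p_value`, `monomorphic`.  A monomorphic SNP
#'   (one allele absent) is a defined result with statistic 0, p 1 and
#'   `monomorphic = TRUE`.
#' @export
hwe_lrt <- function(counts, snp_id = NA_character_) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
    any(counts != round(counts))) {
    stop("`counts` must be three non-negative integers (n0, n1, n2)",
      call. = FALSE
    )
  }
  n <- sum(counts)
  if (n == 0) {
    stop("`counts` must have a positive total", call. = FALSE)
  }
  p_hat <- (2 * counts[3] + counts[2]) / (2 * n)

  if (p_hat == 0 || p_hat == 1) {
    res <- list(
      snp_id = snp_id, counts = counts, allele_freq = p_hat,
      lrt_stat = 0, p_value = 1, monomorphic = TRUE
    )
    class(res) <- "hwe_result"
    return(res)
  }

  obs_p <- counts / n
  ll_sat <- sum(counts[counts > 0] * log(obs_p[counts > 0]))
  hwe_p <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  ll_hwe <- sum(counts[counts > 0] * log(hwe_p[counts > 0]))
  stat <- max(0, 2 * (ll_sat - ll_hwe))

  res <- list(
    snp_id = snp_id, counts = counts, allele_freq = p_hat,
    lrt_stat = stat,
    p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    monomorphic = FALSE
  )
  class(res) <- "hwe_result"
  res
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(
    "<hwe_result>", if (!is.na(x$snp_id)) x$snp_id else "",
    " counts=(", paste(x$counts, collapse = ", "), ")",
    " LRT=", signif(x$lrt_stat, 4), " p=", signif(x$p_value, 3),
    if (x$monomorphic) " [monomorphic]" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' HWE test for every SNP in a genotype matrix
#'
#' @param genotypes A `genotype_matrix` with integer dosages (hard calls).
#' @return Data frame with one row per SNP: `snp_id`, `n0`, `n1`, `n2`,
#'   `allele_freq`, `lrt_stat`, `p_value`, `monomorphic`.
#' @export
hwe_test <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (any(d[!is.na(d)] != round(d[!is.na(d)]))) {
    stop("HWE testing needs integer dosages (hard genotype calls)",
      call. = FALSE
    )
  }
  rows <- lapply(colnames(d), function(snp) {
    x <- d[, snp]
    x <- x[!is.na(x)]
    counts <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    r <- hwe_lrt(counts, snp_id = snp)
    data.frame(
      snp_id = snp, n0 = counts[1], n1 = counts[2], n2 = counts[3],
      allele_freq = r$allele_freq, lrt_stat = r$lrt_stat,
      p_value = r$p_value, monomorphic = r$monomorphic,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pairwise composite LD (squared dosage correlation)
#'
#' r^2 between dosage columns (pairwise-complete observations), the
#' correlation screen appropriate when phase is unavailable.  A
#' zero-variance column gives `NA` against every other SNP, with a warning.
#'
#' @param genotypes A `genotype_matrix` with at least 2 SNPs and 2
#'   individuals.
#' @return Symmetric matrix of r^2 with unit diagonal.
#' @export
pairwise_ld_r2 <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (ncol(d) < 2L || nrow(d) < 2L) {
    stop("need at least 2 SNPs and 2 individuals", call. = FALSE)
  }
  sds <- apply(d, 2, stats::sd, na.rm = TRUE)
  degenerate <- !is.finite(sds) | sds == 0
  if (any(degenerate)) {
    warning(
      "zero-variance column(s), r^2 undefined: ",
      paste(colnames(d)[degenerate], collapse = ", "),
      call. = FALSE
    )
  }
  r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
  diag(r2) <- 1
  r2
}
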