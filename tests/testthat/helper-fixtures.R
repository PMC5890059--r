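# Shared fixtures, all generated in code.

wt_fixture <- function() iron_weight_table()

# small genotype matrix with given dosage rows (list of numeric vectors)
gm_fixture <- function(rows, snps = iron_weight_table()$snp_id,
                       counted = NULL) {
  d <- do.call(rbind, rows)
  rownames(d) <- sprintf("I%03d", seq_len(nrow(d)))
  colnames(d) <- snps
  if (is.null(counted)) {
    def <- default_counted_alleles(iron_weight_table())
    counted <- stats::setNames(rep(NA_character_, length(snps)), snps)
    hit <- intersect(snps, names(def))
    counted[hit] <- def[hit]
  }
  genotype_matrix(d, counted_alleles = counted[snps])
}

# random MR summary-data fixture
mr_fixture <- function(p, seed) {
  withr::with_seed(seed, {
    data.frame(
      snp_id = sprintf("rs%04d", seq_len(p)),
      beta_exposure = stats::runif(p, 0.05, 0.4) *
        sample(c(-1, 1), p, replace = TRUE),
      beta_outcome = stats::rnorm(p, 0, 0.05),
      se_outcome = stats::runif(p, 0.01, 0.05),
      stringsAsFactors = FALSE
    )
  })
}

# minimal VCF fixture: the 12 weight-table SNPs x 3 samples.
# `flip_snp` gets REF = risk allele (so the reader must flip);
# `mismatch_snp` gets alleles unrelated to the weight table;
# `with_ds` adds a DS field that disagrees with GT by +0.1 at sample 1.
write_test_vcf <- function(path, flip_snp = NULL, mismatch_snp = NULL,
                           multiallelic_snp = NULL, with_ds = FALSE,
                           missing_call_snp = NULL) {
  wt <- iron_weight_table()
  counted <- default_counted_alleles(wt)
  other <- c(A = "G", C = "T", G = "A", T = "C") # any non-counted base
  gts <- c("0/0", "0/1", "1/1") # dosages 0, 1, 2 per sample
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ds) {
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">"
    },
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1", "S2", "S3"
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(wt)), function(i) {
    snp <- wt$snp_id[i]
    risk <- counted[[snp]]
    ref <- other[[risk]]
    alt <- risk
    if (!is.null(flip_snp) && snp == flip_snp) {
      ref <- risk
      alt <- other[[risk]]
    }
    if (!is.null(mismatch_snp) && snp == mismatch_snp) {
      ref <- "N"
      alt <- "N"
    }
    if (!is.null(multiallelic_snp) && snp == multiallelic_snp) {
      alt <- paste0(alt, ",", other[[other[[risk]]]])
    }
    g <- gts
    if (!is.null(missing_call_snp) && snp == missing_call_snp) {
      g[2] <- "./."
    }
    if (with_ds) {
      ds <- c(0.1, 1, 2)
      g <- paste(g, ds, sep = ":")
    }
    paste(c(
      "1", as.character(1000L + i), snp, ref, alt, ".", "PASS", ".",
      if (with_ds) "GT:DS" else "GT", g
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

# a null cohort config: every structural effect switched off
null_config <- function(n, seed) {
  cohort_config(
    n_mothers = n, seed = seed,
    gamma_supp = 0, causal_effect = 0, causal_effect_binary = 0,
    confounder_effect_supp = 0, confounder_effect_outcome = 0,
    hb_loading = 0, supp_restore = 0, ige_iron_effect = 0
  )
}
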