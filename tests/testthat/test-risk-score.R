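test_that("raw iron score reproduces the hand-summed weights", {
  wt <- wt_fixture()
  gm <- gm_fixture(list(rep(1, 12), rep(0, 12), rep(2, 12)))
  rs <- build_risk_score(gm, wt, "iron")
  # dosage 1 at the five iron SNPs: 0.189+0.328+0.181+0.066+0.064
  expect_equal(rs$raw[1], 0.828)
  expect_equal(rs$raw[2], 0)
  expect_equal(rs$raw[3], 2 * 0.828)
  expect_equal(attr(rs, "snps_used"), select_snps_for_biomarker(wt, "iron"))
})

test_that("standardisation is exact and scale-invariant", {
  wt <- wt_fixture()
  withr::with_seed(5, {
    d <- matrix(sample(0:2, 50 * 12, replace = TRUE), 50, 12)
  })
  rows <- lapply(seq_len(nrow(d)), function(i) d[i, ])
  gm <- gm_fixture(rows)
  rs <- build_risk_score(gm, wt, "ferritin")
  expect_lt(abs(mean(rs$standardized)), 1e-10)
  expect_lt(abs(stats::sd(rs$standardized) - 1), 1e-10)

  # doubling dosages is impossible within [0,2]; halving shows the same
  # linearity: raw halves, standardised scores unchanged
  gm_half <- gm_fixture(lapply(rows, function(r) r / 2))
  rs_half <- build_risk_score(gm_half, wt, "ferritin")
  expect_equal(rs_half$raw, rs$raw / 2)
  expect_equal(rs_half$standardized, rs$standardized)
})

test_that("degenerate inputs and missing SNPs raise errors", {
  wt <- wt_fixture()
  gm <- gm_fixture(list(rep(0, 12), rep(0, 12)))
  expect_error(build_risk_score(gm, wt, "iron"), "zero variance")

  gm_small <- gm_fixture(
    list(c(1, 2), c(0, 1)),
    snps = c("rs1799945", "rs1800562")
  )
  expect_error(
    build_risk_score(gm_small, wt, "iron"),
    "absent from genotype matrix.*rs855791"
  )
})

test_that("rs8177240 dosages are flipped for transferrin scoring", {
  wt <- wt_fixture()
  # two individuals differing only in rs8177240 T-dosage (0 vs 2)
  base <- rep(1, 12)
  lo <- hi <- base
  names(lo) <- names(hi) <- wt$snp_id
  lo["rs8177240"] <- 0
  hi["rs8177240"] <- 2
  gm <- gm_fixture(list(lo, hi))
  # iron: T is the risk allele, so more T means higher score
  rs_iron <- build_risk_score(gm, wt, "iron")
  expect_equal(rs_iron$raw[2] - rs_iron$raw[1], 2 * 0.066)
  # transferrin: G is the risk allele; T-dosage 0 means G-dosage 2
  rs_tf <- build_risk_score(gm, wt, "transferrin")
  expect_equal(rs_tf$raw[1] - rs_tf$raw[2], 2 * 0.380)
})

test_that("scores are monotone in dosage and permutation-equivariant", {
  wt <- wt_fixture()
  withr::with_seed(11, {
    d <- matrix(sample(0:2, 30 * 12, replace = TRUE), 30, 12)
  })
  rows <- lapply(seq_len(nrow(d)), function(i) d[i, ])
  gm <- gm_fixture(rows)
  counted <- default_counted_alleles(wt)
  for (bm in iron_biomarkers()) {
    rs <- build_risk_score(gm, wt, bm)
    risk <- ironmr:::biomarker_risk_alleles(wt, bm)
    # raise each selected SNP's *risk-allele* dosage for one individual
    # (a stored-orientation decrement where the counted allele differs,
    # e.g. rs8177240 T-dosage when scoring transferrin); raw never drops
    for (snp in attr(rs, "snps_used")) {
      j <- match(snp, wt$snp_id)
      step <- if (counted[[snp]] == risk[[snp]]) 1 else -1
      rows2 <- rows
      rows2[[1]][j] <- max(0, min(2, rows2[[1]][j] + step))
      rs2 <- build_risk_score(gm_fixture(rows2), wt, bm)
      expect_gte(rs2$raw[1], rs$raw[1])
      expect_equal(rs2$raw[-1], rs$raw[-1])
    }
  }
  # permuting individuals permutes scores identically
  perm <- c(7, 1:6, 8:30)
  gm_perm <- gm_fixture(rows[perm])
  rs <- build_risk_score(gm, wt, "transferrin")
  rs_perm <- build_risk_score(gm_perm, wt, "transferrin")
  expect_equal(rs_perm$raw, rs$raw[perm])
})

test_that("missing dosages are mean-imputed and heavy missingness drops", {
  wt <- wt_fixture()
  rows <- list(rep(1, 12), rep(2, 12), rep(0, 12), rep(1, 12))
  gm <- gm_fixture(rows)
  # one missing dosage at one iron SNP for individual 1
  gm$dosage[1, "rs1799945"] <- NA
  rs <- build_risk_score(gm, wt, "iron")
  # imputed with the mean of the remaining dosages (2, 0, 1)
  expect_equal(rs$raw[1], 0.828 - 0.189 + 0.189 * 1)

  # individual missing >20% of the 5 iron SNPs is dropped with a warning
  gm$dosage[2, c("rs1799945", "rs1800562")] <- NA
  expect_warning(rs2 <- build_risk_score(gm, wt, "iron"), "dropped")
  expect_equal(nrow(rs2), 3L)
})
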