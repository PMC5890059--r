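test_that("maternal genotypes follow Hardy-Weinberg proportions", {
  mafs <- c(rs1 = 0.3)
  gm <- simulate_maternal_genotypes(100000, mafs, seed = 4)
  freq <- tabulate(gm$dosage[, 1] + 1, nbins = 3) / 100000
  expected <- c(0.49, 0.42, 0.09)
  tol <- 3 * sqrt(expected * (1 - expected) / 100000)
  expect_true(all(abs(freq - expected) < tol))

  # boundary allele frequency gives a constant column
  gm0 <- simulate_maternal_genotypes(200, c(rs1 = 0), seed = 1)
  expect_true(all(gm0$dosage == 0))

  # seeded determinism, without disturbing the caller's RNG
  g1 <- simulate_maternal_genotypes(500, c(a = 0.2, b = 0.7), seed = 9)
  g2 <- simulate_maternal_genotypes(500, c(a = 0.2, b = 0.7), seed = 9)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("Mendelian transmission has the kinship dosage correlation", {
  mafs <- c(x = 0.25, y = 0.6)
  mom <- simulate_maternal_genotypes(20000, mafs, seed = 21)
  kid <- simulate_child_genotypes(mom, mafs, seed = 22)
  for (j in 1:2) {
    expect_lt(abs(stats::cor(mom$dosage[, j], kid$dosage[, j]) - 0.5), 0.02)
  }

  # homozygous mother, absent paternal allele: child is exactly heterozygous
  mom2 <- gm_fixture(list(c(2, 0), c(2, 0)), snps = c("x", "y"),
    counted = c(x = "A", y = "A")
  )
  kid2 <- simulate_child_genotypes(mom2, c(x = 0, y = 0), seed = 1)
  expect_true(all(kid2$dosage[, "x"] == 1))
  expect_true(all(kid2$dosage[, "y"] == 0))

  # fractional maternal dosages cannot be transmitted
  mom3 <- gm_fixture(list(c(0.5, 1)), snps = c("x", "y"))
  expect_error(
    simulate_child_genotypes(mom3, c(x = 0.1, y = 0.1)),
    "integer-valued"
  )
})

test_that("supplementation decouples from the score when its causes are off", {
  cfg <- cohort_config(
    n_mothers = 8000, seed = 31,
    gamma_supp = 0, confounder_effect_supp = 0
  )
  sim <- simulate_cohort(cfg, children = FALSE)
  rate <- mean(sim$cohort$supp_late)
  expect_lt(abs(rate - cfg$supp_base_rate),
    3 * sqrt(cfg$supp_base_rate * (1 - cfg$supp_base_rate) / 8000)
  )
  # independent of the score: slope p well above any signal
  fit <- summary(stats::lm(sim$cohort$supp_late ~ sim$iron_score_z))
  expect_gt(fit$coefficients[2, 4], 1e-4)
})

test_that("haemoglobin loading controls the score-haemoglobin slope", {
  # with hb_loading > 0 the association is negative by construction
  sim <- simulate_cohort(cohort_config(n_mothers = 5000, seed = 41),
    children = FALSE
  )
  sc <- build_risk_score(sim$maternal_genotypes, wt_fixture(), "iron")
  pv <- proxy_validation(sc, sim$cohort, stratify_by_supp = FALSE)
  expect_true(all(pv$effect < 0))
  expect_true(all(pv$p < 0.001))

  # with hb_loading = 0 the slope CI covers zero in most replicates
  covered <- vapply(1:60, function(i) {
    cfg <- cohort_config(n_mothers = 800, seed = 1000 + i, hb_loading = 0)
    sim <- simulate_cohort(cfg, children = FALSE)
    sc <- build_risk_score(sim$maternal_genotypes, wt_fixture(), "iron")
    row <- linear_association(
      merge(sim$cohort,
        stats::setNames(sc[, c(1, 3)], c("individual_id", "z")),
        by = "individual_id"
      ),
      "hb_late", "z"
    )
    row$ci_low <= 0 && 0 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("each standardised score tracks the latent biomarker negatively", {
  sim <- simulate_cohort(cohort_config(n_mothers = 5000, seed = 51))
  wt <- wt_fixture()
  for (bm in iron_biomarkers()) {
    sc <- build_risk_score(sim$maternal_genotypes, wt, bm)
    fit <- summary(stats::lm(sim$latent_iron ~ sc$standardized))
    expect_lt(fit$coefficients[2, 1], 0)
    expect_lt(fit$coefficients[2, 4], 0.001)
  }
})

test_that("the generator is a pure function of its config", {
  cfg <- cohort_config(n_mothers = 400, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$maternal_genotypes$dosage, b$maternal_genotypes$dosage)
  expect_identical(a$child_genotypes$dosage, b$child_genotypes$dosage)
  # skipping children leaves the rest of the cohort untouched
  c <- simulate_cohort(cfg, children = FALSE)
  expect_identical(a$cohort, c$cohort)
  expect_null(c$child_genotypes)
})

test_that("config validation catches out-of-range parameters", {
  expect_error(cohort_config(biomarker_h2 = 1), "biomarker_h2")
  expect_error(cohort_config(asthma_prev = 0), "asthma_prev")
  expect_error(cohort_config(supp_base_rate = 1.2), "supp_base_rate")
  expect_error(cohort_config(mafs = c(rs1 = 0)), "mafs")
  expect_error(cohort_config(supp_restore = 1.5), "supp_restore")
  expect_error(cohort_config(n_mothers = 0), "n_mothers")
})

test_that("config round-trips through JSON and YAML", {
  cfg <- cohort_config(n_mothers = 123, seed = 5, gamma_supp = 1.25)
  for (ext in c(".json", ".yaml")) {
    f <- withr::local_tempfile(fileext = ext)
    write_cohort_config(cfg, f)
    back <- read_cohort_config(f)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-12)
  }
})
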