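# closed-form OLS oracle via the normal equations
ols_oracle <- function(y, X) {
  X <- cbind(1, X)
  xtx <- crossprod(X)
  beta <- solve(xtx, crossprod(X, y))
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(xtx))))
}

# logistic IRLS oracle, hand-rolled independently of glm
logit_oracle <- function(y, X, iter = 60) {
  X <- cbind(1, X)
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b <- solve(crossprod(X, w * X), crossprod(X, w * z))
  }
  list(beta = drop(b), se = sqrt(diag(solve(crossprod(X, drop(w) * X)))))
}

test_that("linear association reproduces the hand-computed slope", {
  df <- data.frame(x = 0:3, y = c(1, 2, 2, 4))
  r <- linear_association(df, "y", "x")
  expect_equal(r$effect, 0.9)
  expect_equal(r$scale, "beta")
  expect_equal(r$n, 4L)
  expect_true(r$ci_low <= r$effect && r$effect <= r$ci_high)
})

test_that("regressions agree with normal-equations and IRLS oracles", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- sample(20:50, 1)
      X <- cbind(x = rnorm(n), c1 = rnorm(n), c2 = rnorm(n))
      y <- 0.5 * X[, 1] - 0.2 * X[, 2] + rnorm(n)
      df <- data.frame(y = y, X)
      r <- linear_association(df, "y", "x", c("c1", "c2"))
      o <- ols_oracle(y, X)
      expect_equal(r$effect, unname(o$beta[2]), tolerance = 1e-8)
      expect_equal(r$se, unname(o$se[2]), tolerance = 1e-8)

      yb <- rbinom(n, 1, plogis(0.8 * X[, 1]))
      dfb <- data.frame(y = yb, X)
      if (length(unique(yb)) < 2) next
      rb <- logistic_association(dfb, "y", "x", c("c1", "c2"))
      ob <- logit_oracle(yb, X)
      expect_equal(log(rb$effect), unname(ob$beta[2]), tolerance = 1e-6)
      expect_equal(rb$se, unname(ob$se[2]), tolerance = 1e-6)
    }
  })
})

test_that("logistic association recovers the contingency-table odds ratio", {
  # exposed: 20 cases / 80 controls; unexposed: 10 cases / 90 controls
  df <- data.frame(
    y = rep(c(1, 0, 1, 0), times = c(20, 80, 10, 90)),
    x = rep(c(1, 1, 0, 0), times = c(20, 80, 10, 90))
  )
  r <- logistic_association(df, "y", "x")
  expect_equal(r$effect, (20 * 90) / (80 * 10), tolerance = 1e-8)
  expect_equal(r$scale, "or")

  df$x <- 1
  expect_error(logistic_association(df, "y", "x"), "constant")
})

test_that("complete separation and collinearity raise diagnostics", {
  df <- data.frame(y = c(rep(0, 20), rep(1, 20)), x = c(rep(0, 20), rep(1, 20)))
  expect_error(logistic_association(df, "y", "x"), "separation")

  df2 <- data.frame(y = rnorm(20), x = rnorm(20))
  df2$x2 <- 2 * df2$x
  expect_error(linear_association(df2, "y", "x", "x2"), "collinear.*x2")
})

test_that("null p values are uniform across replicates", {
  p <- vapply(1:1000, function(i) {
    withr::with_seed(3000 + i, {
      df <- data.frame(y = rnorm(60), x = rnorm(60))
    })
    linear_association(df, "y", "x")$p
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("geometric mean ratio equals the ratio of geometric means", {
  withr::with_seed(23, {
    df <- data.frame(
      ige = exp(rnorm(80, 3.5, 1)),
      x = rep(c(0, 1), each = 40)
    )
  })
  r <- geometric_mean_ratio(df, "ige", "x")
  gm0 <- exp(mean(log(df$ige[df$x == 0])))
  gm1 <- exp(mean(log(df$ige[df$x == 1])))
  expect_equal(r$effect, gm1 / gm0, tolerance = 1e-10)
  expect_equal(r$scale, "gmr")

  df$ige[c(3, 7)] <- 0
  expect_error(geometric_mean_ratio(df, "ige", "x"), "non-positive.*3, 7")
})

test_that("robust (Huber-White) SEs track the bootstrap on heteroscedastic data", {
  withr::with_seed(29, {
    n <- 400
    x <- rnorm(n)
    # error variance grows with x: plain OLS SEs would be off
    y <- exp(0.2 * x + rnorm(n, 0, 0.4 + 0.6 * abs(x)))
    df <- data.frame(ige = y, x = x)
    r <- geometric_mean_ratio(df, "ige", "x")
    boot <- vapply(1:1000, function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      stats::coef(stats::lm(log(ige) ~ x, data = df[idx, ]))[2]
    }, numeric(1))
  })
  expect_lt(abs(r$se - stats::sd(boot)) / stats::sd(boot), 0.1)
})

test_that("per-allele results match single-exposure regressions", {
  wt <- wt_fixture()
  sim <- simulate_cohort(cohort_config(n_mothers = 600, seed = 71),
    children = FALSE
  )
  pa <- per_allele_associations(
    sim$maternal_genotypes, sim$cohort, "hb_late",
    table = wt, biomarker = "transferrin"
  )
  expect_equal(nrow(pa), 9L)
  expect_equal(pa$exposure, select_snps_for_biomarker(wt, "transferrin"))

  # single-SNP path is literally linear_association on that dosage
  snp <- "rs1800562"
  df <- sim$cohort
  df[[snp]] <- sim$maternal_genotypes$dosage[
    match(df$individual_id, rownames(sim$maternal_genotypes$dosage)), snp
  ]
  expect_equal(
    pa[pa$exposure == snp, c("effect", "se", "p")],
    linear_association(df, "hb_late", snp)[, c("effect", "se", "p")],
    ignore_attr = TRUE
  )

  # every column analysed when no table is given
  pa_all <- per_allele_associations(sim$maternal_genotypes, sim$cohort, "hb_late")
  expect_equal(nrow(pa_all), 12L)
})

test_that("an injected per-allele effect is recovered within its CI", {
  withr::with_seed(83, {
    n <- 20000
    d <- matrix(rbinom(n, 1, 0.5) + rbinom(n, 1, 0.5), ncol = 1,
      dimnames = list(sprintf("I%05d", 1:n), "rsX")
    )
    df <- data.frame(
      individual_id = rownames(d),
      hb = 12 - 0.1 * d[, 1] + rnorm(n),
      stringsAsFactors = FALSE
    )
  })
  pa <- per_allele_associations(genotype_matrix(d), df, "hb")
  expect_true(pa$ci_low <= -0.1 && -0.1 <= pa$ci_high)
})

test_that("stratified battery partitions records and handles constants", {
  wt <- wt_fixture()
  sim <- simulate_cohort(cohort_config(n_mothers = 800, seed = 91),
    children = FALSE
  )
  sc <- build_risk_score(sim$maternal_genotypes, wt, "iron")
  res <- stratified_analysis(sim$cohort, sc)
  # per-stratum record counts sum to the total for every outcome
  for (out in unique(res$outcome)) {
    sub <- res[res$outcome == out, ]
    expect_equal(
      sum(sub$n[sub$stratum != "all"]),
      sub$n[sub$stratum == "all"]
    )
  }

  # a constant stratifier collapses to one stratum equal to the
  # unstratified analysis without the supplementation adjustment
  coh0 <- sim$cohort
  coh0$supp_late <- 0
  expect_message(
    res0 <- stratified_analysis(coh0, sc, supp_covariates = "supp_late"),
    "constant"
  )
  all_rows <- res0[res0$stratum == "all", c("outcome", "effect", "se", "p")]
  s0_rows <- res0[res0$stratum == "supp_late=0", c("outcome", "effect", "se", "p")]
  expect_equal(all_rows, s0_rows, ignore_attr = TRUE)
})

test_that("supplementation dilutes the outcome association when restoring iron", {
  # deficits restored by supplementation weaken the genotype-outcome link
  wt <- wt_fixture()
  wins <- vapply(1:30, function(i) {
    cfg <- cohort_config(
      n_mothers = 4000, seed = 5000 + i,
      causal_effect = -0.5, supp_restore = 0.9
    )
    sim <- simulate_cohort(cfg, children = FALSE)
    sc <- build_risk_score(sim$maternal_genotypes, wt, "iron")
    df <- merge(sim$cohort,
      stats::setNames(sc[, c(1, 3)], c("individual_id", "z")),
      by = "individual_id"
    )
    b0 <- linear_association(df[df$supp_late == 0, ], "fev1_sd", "z")$effect
    b1 <- linear_association(df[df$supp_late == 1, ], "fev1_sd", "z")$effect
    abs(b0) > abs(b1)
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
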