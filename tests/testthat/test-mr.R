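# independent weighted-least-squares oracle: minimise the weighted SSE
# numerically rather than via the estimator's own closed form
wls_origin_oracle <- function(bx, by, w) {
  stats::optimize(
    function(b) sum(w * (by - b * bx)^2),
    interval = range(by / bx) + c(-10, 10), tol = 1e-12
  )$minimum
}

# stepwise-scan oracle for the weighted median interpolation
weighted_median_oracle <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  cum <- 0
  s <- numeric(length(w))
  for (j in seq_along(w)) {
    s[j] <- cum + w[j] / 2
    cum <- cum + w[j]
  }
  if (0.5 <= s[1]) {
    return(r[1])
  }
  if (0.5 >= s[length(s)]) {
    return(r[length(r)])
  }
  j <- max(which(s <= 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

test_that("IVW reduces to the Wald ratio and matches the WLS oracle", {
  one <- data.frame(
    snp_id = "rs1", beta_exposure = 0.2,
    beta_outcome = 0.05, se_outcome = 0.01
  )
  expect_equal(mr_ivw(one)$slope, 0.05 / 0.2)

  # identical ratio estimates collapse to that ratio exactly
  flat <- data.frame(
    snp_id = paste0("rs", 1:4),
    beta_exposure = c(0.1, 0.2, 0.3, 0.4),
    beta_outcome = 0.7 * c(0.1, 0.2, 0.3, 0.4),
    se_outcome = c(0.01, 0.02, 0.01, 0.03)
  )
  expect_equal(mr_ivw(flat)$slope, 0.7)

  toy <- data.frame(
    snp_id = paste0("rs", 1:3),
    beta_exposure = c(0.1, 0.2, 0.3),
    beta_outcome = c(0.02, 0.05, 0.06),
    se_outcome = c(0.01, 0.01, 0.02)
  )
  est <- mr_ivw(toy)
  expect_equal(est$slope, 165 / 725, tolerance = 1e-12)
  w <- 1 / toy$se_outcome^2
  expect_equal(est$slope,
    wls_origin_oracle(toy$beta_exposure, toy$beta_outcome, w),
    tolerance = 1e-8
  )
  expect_equal(est$slope_se, sqrt(1 / sum(w * toy$beta_exposure^2)))

  bad <- transform(toy, beta_exposure = 0)
  expect_error(mr_ivw(bad), "undefined")
})

test_that("MR-Egger separates slope from constant pleiotropy", {
  bx <- c(0.1, 0.15, 0.25, 0.3, 0.4)
  # exact proportionality: slope c, intercept 0
  d1 <- data.frame(
    snp_id = paste0("rs", 1:5), beta_exposure = bx,
    beta_outcome = 0.4 * bx, se_outcome = rep(0.02, 5)
  )
  e1 <- mr_egger(d1)
  expect_equal(e1$slope, 0.4, tolerance = 1e-12)
  expect_equal(e1$intercept, 0, tolerance = 1e-12)

  # constant directional pleiotropy lands in the intercept, not the slope
  d2 <- transform(d1, beta_outcome = beta_outcome + 0.03)
  e2 <- mr_egger(d2)
  expect_equal(e2$slope, 0.4, tolerance = 1e-12)
  expect_equal(e2$intercept, 0.03, tolerance = 1e-12)

  expect_error(mr_egger(d1[1:2, ]), "at least 3")
  expect_error(
    mr_egger(transform(d1, beta_exposure = 0.2)),
    "no spread"
  )
})

test_that("Egger matches a general weighted-regression oracle", {
  for (seed in c(101, 102, 103)) {
    d <- mr_fixture(8, seed)
    d$beta_exposure <- abs(d$beta_exposure)
    fit <- stats::lm(beta_outcome ~ beta_exposure,
      data = d, weights = 1 / d$se_outcome^2
    )
    e <- mr_egger(d)
    expect_equal(e$slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)
    expect_equal(e$intercept, unname(stats::coef(fit)[1]), tolerance = 1e-10)
    # covariance with known outcome variances: strip lm's residual scaling
    vc <- stats::vcov(fit) / summary(fit)$sigma^2
    expect_equal(e$slope_se, sqrt(vc[2, 2]), tolerance = 1e-10)
    expect_equal(e$intercept_se, sqrt(vc[1, 1]), tolerance = 1e-10)
  }
})

test_that("Egger with the intercept constrained to zero is IVW", {
  for (seed in c(111, 112)) {
    d <- mr_fixture(6, seed)
    d$beta_exposure <- abs(d$beta_exposure)
    # constrained fit = weighted regression through the origin
    fit0 <- stats::lm(beta_outcome ~ 0 + beta_exposure,
      data = d, weights = 1 / d$se_outcome^2
    )
    ivw <- mr_ivw(d)
    expect_equal(ivw$slope, unname(stats::coef(fit0)), tolerance = 1e-12)
    vc0 <- stats::vcov(fit0) / summary(fit0)$sigma^2
    expect_equal(ivw$slope_se, sqrt(vc0[1, 1]), tolerance = 1e-12)
  }
})

test_that("weighted median interpolates at half the standardised weight", {
  d <- data.frame(
    snp_id = paste0("rs", 1:3),
    beta_exposure = c(1, 1, 1),
    beta_outcome = c(1, 2, 9),
    se_outcome = c(1, 1, 1) # equal weights
  )
  e <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(e$slope, 2) # the plain median

  flat <- transform(d, beta_outcome = 3.5 * beta_exposure)
  expect_equal(mr_weighted_median(flat, n_boot = 50, seed = 1)$slope, 3.5)

  expect_error(
    mr_weighted_median(transform(d, beta_exposure = c(1, 0, 1))),
    "zero exposure beta"
  )

  # general fixtures agree with the stepwise-scan oracle
  for (seed in c(121, 122, 123)) {
    dd <- mr_fixture(9, seed)
    r <- dd$beta_outcome / dd$beta_exposure
    w <- dd$beta_exposure^2 / dd$se_outcome^2
    expect_equal(
      mr_weighted_median(dd, n_boot = 50, seed = 1)$slope,
      weighted_median_oracle(r, w),
      tolerance = 1e-12
    )
  }
})

test_that("row-wise weighted median equals the scalar computation", {
  withr::with_seed(131, {
    for (rep in 1:20) {
      p <- sample(2:12, 1)
      m <- sample(1:40, 1)
      vals <- matrix(rnorm(m * p), m, p)
      w <- runif(p, 0.1, 2)
      got <- ironmr:::row_weighted_median(vals, w)
      want <- apply(vals, 1, weighted_median_oracle, w = w)
      expect_equal(got, want, tolerance = 1e-10)
    }
  })
})

test_that("all estimators are invariant to joint per-SNP sign flips", {
  d <- mr_fixture(7, 141)
  d$beta_exposure <- abs(d$beta_exposure) # oriented input
  flip <- c(-1, 1, -1, -1, 1, 1, -1)
  d2 <- transform(d,
    beta_exposure = beta_exposure * flip,
    beta_outcome = beta_outcome * flip
  )
  expect_equal(mr_ivw(d2)$slope, mr_ivw(d)$slope, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$slope, mr_egger(d)$slope, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$intercept, mr_egger(d)$intercept,
    tolerance = 1e-12
  )
  expect_equal(
    mr_weighted_median(d2, n_boot = 200, seed = 3)$slope,
    mr_weighted_median(d, n_boot = 200, seed = 3)$slope,
    tolerance = 1e-12
  )
})

test_that("weighted median resists <50% invalid instruments where IVW fails", {
  bx <- rep(0.2, 10)
  c_true <- 0.3
  by <- c_true * bx
  by[7:10] <- by[7:10] + 0.05 # four pleiotropic instruments
  d <- data.frame(
    snp_id = paste0("rs", 1:10), beta_exposure = bx,
    beta_outcome = by, se_outcome = rep(0.02, 10)
  )
  wm <- mr_weighted_median(d, n_boot = 100, seed = 5)$slope
  ivw <- mr_ivw(d)$slope
  expect_equal(wm, c_true, tolerance = 1e-10) # valid weight > 50%
  expect_gt(ivw, c_true + 0.02) # IVW dragged by the pleiotropy
})

test_that("summary data assembly harmonises orientation", {
  wt <- wt_fixture()
  sim <- simulate_cohort(cohort_config(n_mothers = 500, seed = 151),
    children = FALSE
  )
  pa <- per_allele_associations(
    sim$maternal_genotypes, sim$cohort, "fev1_sd",
    table = wt, biomarker = "iron"
  )
  msd <- assemble_mr_summary(wt, pa, "iron")
  expect_s3_class(msd, "mr_summary_data")
  expect_equal(nrow(msd), 5L)
  expect_true(all(msd$beta_exposure >= 0))

  # flipping one SNP's input orientation leaves MR estimates unchanged
  pa2 <- pa
  i <- match("rs1800562", pa2$exposure)
  pa2$effect[i] <- -pa2$effect[i]
  msd2 <- assemble_mr_summary(wt, pa2, "iron")
  # (the flip changes the outcome beta the assembly sees, so this checks
  # the orientation contract rather than bitwise equality of inputs)
  expect_equal(abs(msd2$beta_exposure), abs(msd$beta_exposure))

  expect_error(
    assemble_mr_summary(wt, pa[-1, ], "iron"),
    "absent from per-allele.*rs1799945"
  )
})

test_that("MR summary data round-trips through TSV", {
  d <- mr_fixture(5, 161)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_mr_summary(d, f)
  back <- read_mr_summary(f)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
})

test_that("IVW and Egger CIs cover the null at close to 95%", {
  # lighter companion to the acceptance-suite calibration run
  bx <- seq(0.05, 0.32, length.out = 10)
  se <- seq(0.01, 0.05, length.out = 10)
  hits <- withr::with_seed(171, {
    vapply(1:1000, function(i) {
      d <- data.frame(
        snp_id = paste0("rs", 1:10), beta_exposure = bx,
        beta_outcome = rnorm(10, 0, se), se_outcome = se
      )
      c(
        ivw = mr_ivw(d)$p >= 0.05,
        egger = mr_egger(d)$p >= 0.05
      )
    }, logical(2))
  })
  expect_lt(abs(mean(hits["ivw", ]) - 0.95), 0.025)
  expect_lt(abs(mean(hits["egger", ]) - 0.95), 0.025)
})

test_that("the one-sample ratio estimator recovers a known effect", {
  withr::with_seed(181, {
    n <- 4000
    z <- rnorm(n)
    x <- 0.3 * z + rnorm(n)
    y <- 0.25 * x + rnorm(n)
    df <- data.frame(y = y, x = x, z = z)
  })
  iv <- iv_ratio_estimate(df, "y", "x", "z")
  expect_lt(abs(iv$estimate - 0.25), 3 * iv$se)
  expect_equal(iv$estimate, iv$reduced_form_beta / iv$first_stage_beta)
})
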