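test_that("linear fits recover exact and null relationships", {
  d <- tibble::tibble(x = seq(-2, 2, length.out = 40), y = 2 * x)
  # noise-free fit: summary.lm warns about the perfect fit, which is the point
  f <- suppressWarnings(fit_linear(d, "y", "x"))
  expect_equal(f$result$estimate, 2, tolerance = 1e-12)
  expect_equal(f$variance$full_r2, 1, tolerance = 1e-12)

  withr::with_seed(61, {
    d2 <- tibble::tibble(x = rnorm(500), y = rnorm(500))
    r <- fit_linear(d2, "y", "x")$result
    expect_lt(abs(r$estimate), 2 * r$se)
  })
  expect_error(fit_linear(tibble::tibble(x = rep(1, 30), y = rnorm(30)),
                          "y", "x"), "constant")
})

test_that("standardised linear estimate equals the Pearson correlation", {
  withr::with_seed(62, {
    d <- tibble::tibble(x = rnorm(200), y = rnorm(200) + 0.4 * x)
    r <- fit_linear(d, "y", "x")$result
    expect_equal(r$estimate * sd(d$x) / sd(d$y), cor(d$x, d$y),
                 tolerance = 1e-10)
  })
})

test_that("logistic fits reproduce the 2x2 closed form and the per-0.1 identity", {
  withr::with_seed(63, {
    n <- 400
    exposure <- rbinom(n, 1, 0.5)
    outcome <- rbinom(n, 1, plogis(-0.5 + 1.2 * exposure))
    f <- fit_logistic(tibble::tibble(y = outcome, x = exposure), "y", "x")
    oracle <- table_or(exposure, outcome)
    expect_equal(f$result$or, oracle$or, tolerance = 1e-8)
    expect_equal(f$result$se, oracle$se, tolerance = 1e-6)
    expect_equal(f$result$or_per_0.1, exp(0.1 * f$result$estimate),
                 tolerance = 1e-12)
    # null: OR confidence interval covers 1
    y0 <- rbinom(n, 1, 0.5)
    f0 <- fit_logistic(tibble::tibble(y = y0, x = exposure), "y", "x")
    expect_true(f0$result$or_ci_lo <= 1 && 1 <= f0$result$or_ci_hi)
  })
  expect_error(fit_logistic(tibble::tibble(y = rep(1, 20), x = rnorm(20)),
                            "y", "x"), "classes")
})

test_that("separation is reported as an explicit error", {
  d <- tibble::tibble(x = c(rep(0, 20), rep(1, 20)),
                      y = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_logistic(d, "y", "x"), "separation")
})

test_that("logistic recovery works at a large published effect scale", {
  withr::with_seed(64, {
    n <- 5000
    x <- rnorm(n, 1.18, 0.13)
    y <- rbinom(n, 1, plogis(-4.8 + 3.86 * x))
    r <- fit_logistic(tibble::tibble(y = y, x = x), "y", "x")$result
    expect_lt(abs(r$estimate - 3.86), 2 * r$se)
  })
})

test_that("quantile contrasts match the collapsed 2x2 odds ratio", {
  withr::with_seed(65, {
    n <- 600
    sc <- quantile_strata(tibble::tibble(pgrs = rnorm(n)), k = 3)
    sc$y <- rbinom(n, 1, plogis(-0.4 + 0.8 * (sc$stratum == "Q3")))
    res <- quantile_contrast(sc, "y", reference = "Q1")
    expect_equal(nrow(res), 2)
    # 2x2 collapse: Q3 vs Q1, no covariates
    sub <- sc[sc$stratum %in% c("Q1", "Q3"), ]
    oracle <- table_or(as.integer(sub$stratum == "Q3"), sub$y)
    expect_equal(res$or[res$stratum == "Q3"], oracle$or, tolerance = 1e-6)
  })
  expect_error(quantile_contrast(tibble::tibble(y = 1, stratum = "Q2"), "y",
                                 reference = "Q1"), "Reference")
})

test_that("Benjamini-Hochberg adjustment matches the reference implementation", {
  withr::with_seed(66, {
    for (i in 1:20) {
      p <- runif(sample(3:60, 1))
      q <- bh_fdr(p)
      expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
      expect_true(all(q >= p))
      expect_true(all(q <= 1))
      o <- order(p)
      expect_true(!is.unsorted(q[o]))
    }
  })
  expect_equal(bh_fdr(rep(0.3, 7)), rep(0.3, 7))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("the per-SNP scan returns one row per variant and survives bad columns", {
  withr::with_seed(67, {
    n <- 300
    dos <- tibble::tibble(id = sprintf("i%03d", 1:n),
                          s1 = sample(0:2, n, replace = TRUE),
                          s2 = sample(0:2, n, replace = TRUE),
                          s3 = rep(1, n))          # constant: row-level error
    coh <- tibble::tibble(id = dos$id,
                          bmi_z = 0.5 * dos$s1 + rnorm(n))
    scan <- per_snp_scan(dos, coh)
    expect_equal(nrow(scan), 3)
    expect_true(is.na(scan$estimate[scan$snp_id == "s3"]))
    expect_match(scan$error[scan$snp_id == "s3"], "constant")
    expect_equal(which.min(scan$fdr), which(scan$snp_id == "s1"))
  })
})

test_that("stepwise AIC keeps covariates, finds the causal SNP and improves AIC", {
  withr::with_seed(68, {
    n <- 400
    dat <- tibble::tibble(age = rnorm(n))
    for (j in 1:10) dat[[sprintf("s%02d", j)]] <- sample(0:2, n, replace = TRUE)
    dat$y <- 0.8 * dat$s03 + 0.3 * dat$age + rnorm(n)
    cand <- sprintf("s%02d", 1:10)
    sel <- stepwise_aic(dat, "y", cand, covariates = "age")
    expect_true("s03" %in% sel$selected)
    expect_true("age" %in% attr(terms(sel$fit), "term.labels"))
    full <- lm(y ~ ., data = dat)
    base <- lm(y ~ age, data = dat)
    expect_lte(sel$aic, AIC(full) + 1e-9)
    expect_lte(sel$aic, AIC(base) + 1e-9)
  })
})

test_that("variance explained is zero for identical models and recovers the target", {
  withr::with_seed(69, {
    d <- tibble::tibble(x = rnorm(200), z = rnorm(200), y = rnorm(200) + 0.5 * x)
    full <- lm(y ~ x + z, data = d)
    expect_equal(variance_explained(full, full)$component_r2, 0)
    red <- lm(y ~ z, data = d)
    ve <- variance_explained(full, red)
    expect_gt(ve$component_r2, 0)
    expect_lte(ve$component_r2, ve$full_r2)
    expect_error(variance_explained(full, lm(y ~ z, data = d[1:100, ])),
                 "different numbers")
  })
})

test_that("tidy and glance expose broom-style summaries", {
  d <- tibble::tibble(x = rnorm(100), y = rnorm(100))
  f <- fit_linear(d, "y", "x")
  td <- tidy(f)
  expect_true(all(c("term", "estimate", "se", "p_value") %in% names(td)))
  expect_equal(nrow(td), 2)
  gl <- glance(f)
  expect_equal(gl$model_type, "linear")
  expect_equal(gl$n, 100)
})
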