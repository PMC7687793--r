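test_that("robust fit recovers an exact linear relationship to machine precision", {
  x <- seq(0.1, 0.9, length.out = 40)
  y <- 0.3 + 2 * x
  fit <- fit_robust(y, x)
  expect_true(fit$converged)
  expect_equal(fit$beta, 2.0, tolerance = 1e-8)
})

test_that("Huber fit agrees with least squares on clean Gaussian data", {
  set.seed(11)
  n <- 500
  x <- stats::runif(n, 0.2, 0.8)
  y <- 1 + 0.8 * x + stats::rnorm(n, 0, 0.5)
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])  # closed-form oracle
  fit <- fit_robust(y, x)
  expect_lt(abs(fit$beta - ols), 0.02)
})

test_that("Huber fit equals least squares when residuals are all inside the tuning band", {
  # alternating +/-c errors: every standardized residual sits well below the
  # 1.345 tuning constant at the least-squares solution, so all Huber
  # weights are 1 and the M-estimate coincides with least squares
  set.seed(12)
  n <- 100
  x <- stats::runif(n)
  y <- 2 + x + rep(c(-0.01, 0.01), n / 2)
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])
  fit <- fit_robust(y, x)
  expect_equal(fit$beta, ols, tolerance = 1e-8)
})

test_that("robust fit resists a gross outlier better than least squares", {
  set.seed(13)
  n <- 200
  x <- stats::runif(n, 0.2, 0.8)
  y <- 1 + 2 * x + stats::rnorm(n, 0, 0.3)
  y[1] <- y[1] + 50
  ols_dev <- abs(unname(stats::coef(stats::lm(y ~ x))[2]) - 2)
  rob_dev <- abs(fit_robust(y, x)$beta - 2)
  expect_lt(rob_dev, 0.5 * ols_dev)
})

test_that("standard errors shrink as 1/sqrt(n) under data duplication", {
  set.seed(14)
  n <- 300
  x <- stats::runif(n)
  y <- x + stats::rnorm(n)
  f1 <- fit_robust(y, x)
  f2 <- fit_robust(c(y, y), c(x, x))
  expect_equal(f1$se / f2$se, sqrt(2), tolerance = 0.05)
})

test_that("robust fit reports failure reasons instead of spurious estimates", {
  # rank-deficient design: covariate duplicates the exposure
  x <- stats::runif(30)
  y <- x + stats::rnorm(30)
  f <- fit_robust(y, x, covariates = cbind(dup = x))
  expect_false(f$converged)
  expect_equal(f$reason, "rank_deficient")
  # too few observations relative to predictors
  f2 <- fit_robust(y[1:6], x[1:6], covariates = cbind(a = rnorm(6),
                                                      b = rnorm(6)))
  expect_false(f2$converged)
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  # 30 exposed cases, 10 exposed controls, 20 unexposed cases, 40 unexposed controls
  case <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  x <- c(rep(1, 40), rep(0, 60))
  fit <- fit_logistic(case, x)
  expect_true(fit$converged)
  expect_equal(fit$or, (30 * 40) / (10 * 20), tolerance = 1e-6)
  # CI geometric mean equals the OR
  expect_equal(sqrt(prod(fit$or_ci)), fit$or, tolerance = 1e-9)
})

test_that("logistic fit is null when the outcome is independent of exposure", {
  set.seed(15)
  case <- stats::rbinom(400, 1, 0.4)
  x <- stats::runif(400)
  fit <- fit_logistic(case, x)
  expect_true(fit$or_ci[1] < 1 && fit$or_ci[2] > 1)
})

test_that("a published OR/CI triple is internally consistent under the Wald form", {
  # symmetric-on-log-scale check used for reported case-control results
  expect_equal(sqrt(2.08 * 4.63), 3.10, tolerance = 0.01)
})

test_that("logistic fit records separation and one-class outcomes as failures", {
  case <- c(rep(0, 20), rep(1, 20))
  x <- c(stats::runif(20, 0, 0.4), stats::runif(20, 0.6, 1))  # perfect split
  expect_false(fit_logistic(case, x)$converged)
  expect_false(fit_logistic(rep(1, 30), stats::runif(30))$converged)
  expect_equal(fit_logistic(rep(1, 30), stats::runif(30))$reason,
               "one_outcome_class")
})

test_that("cohort EWAS is calibrated under the null and honors missingness", {
  cfg <- sim_config(master_seed = 31, n_cohorts = 1,
                    samples_per_cohort = 150L, n_probes = 100)
  ch <- generate_consortium(cfg)[[1]]
  ch$betas[3, ] <- NA  # all-missing probe
  ch$betas[4, 1:10] <- NA
  res <- run_cohort_ewas(ch, model_spec("A"))
  expect_false("cg00000003" %in% res$cpg_id)
  expect_equal(res$n[res$cpg_id == "cg00000004"], 140)
  # ~5 of 99 probes nominal under the uniform null, +/- 3 sigma binomial
  n_sig <- sum(res$p < 0.05)
  expect_lt(abs(n_sig - 0.05 * nrow(res)), 3 * sqrt(nrow(res) * 0.05 * 0.95))
})

test_that("ethnic strata within one study are analyzed separately", {
  cfg <- sim_config(master_seed = 32, n_cohorts = 1,
                    samples_per_cohort = 120L, n_probes = 10)
  ch <- generate_consortium(cfg)[[1]]
  ch$samples$ethnic_group <- rep(c("EUR", "AFR"), 60)
  res <- run_cohort_ewas(ch, model_spec("A"), stratify_by = "ethnic_group")
  expect_setequal(unique(res$cohort_id),
                  c("cohort_01_EUR", "cohort_01_AFR"))
  expect_equal(sum(res$cohort_id == "cohort_01_EUR"), 10)
})

test_that("genomic lambda satisfies its defining identities", {
  m <- 1000
  # exact uniform quantiles -> lambda 1
  p_unif <- (seq_len(m) - 0.5) / m
  expect_equal(genomic_lambda(p_unif), 1.0, tolerance = 0.01)
  # every statistic at the chi-square(1) median -> exactly 1
  p_med <- rep(stats::pchisq(0.4549364, 1, lower.tail = FALSE), 200)
  expect_equal(genomic_lambda(p_med), 1.0, tolerance = 1e-5)
  # doubling every chi-square doubles lambda
  chi <- stats::qchisq(p_unif, 1, lower.tail = FALSE)
  p_doubled <- stats::pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_doubled), 2 * genomic_lambda(p_unif),
               tolerance = 1e-8)
  expect_warning(genomic_lambda(stats::runif(50)), "fewer than 100")
  expect_error(genomic_lambda(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("cohort-level null P values control type-I error at the nominal rate", {
  run <- null_calibration_run()
  p <- run$results$p[run$results$converged]
  expect_gt(length(p), 10000)
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})
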