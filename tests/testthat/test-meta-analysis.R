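# naive reference pooling, written independently of ivw_pool
naive_pool <- function(beta, se) {
  w <- se^-2
  b <- sum(beta * w) / sum(w)
  s <- sqrt(1 / sum(w))
  c(beta = b, se = s, z = b / s, p = 2 * (1 - stats::pnorm(abs(b / s))))
}

test_that("inverse-variance pooling matches hand computation and identities", {
  # single study is the identity
  p1 <- ivw_pool(0.5, 0.1)
  expect_equal(p1$beta, 0.5)
  expect_equal(p1$se, 0.1)
  # weights 100 and 25: pooled (100*0.5 + 25*1.0)/125 = 0.6
  p2 <- ivw_pool(c(0.5, 1.0), c(0.1, 0.2))
  expect_equal(p2$beta, 0.6, tolerance = 1e-12)
  expect_equal(p2$se, sqrt(1 / 125), tolerance = 1e-9)
  expect_equal(p2$se, 0.089443, tolerance = 1e-5)
  expect_error(ivw_pool(c(0.5, 1), c(0.1, 0)), "standard error")
})

test_that("a coefficient/SE pair reproduces its reported meta P value", {
  p <- ivw_pool(0.96288, 0.16871)$p
  expect_equal(signif(p, 3), 1.15e-8)
})

test_that("pooling agrees with a naive oracle on 1000 random probes", {
  set.seed(21)
  for (i in 1:1000) {
    k <- sample(2:8, 1)
    beta <- stats::rnorm(k)
    se <- stats::runif(k, 0.05, 0.5)
    ours <- ivw_pool(beta, se)
    ref <- naive_pool(beta, se)
    expect_equal(ours$beta, unname(ref["beta"]), tolerance = 1e-10)
    expect_equal(ours$se, unname(ref["se"]), tolerance = 1e-10)
    # bounds: pooled se no larger than the best study, pooled beta inside hull
    expect_lte(ours$se, min(se) + 1e-12)
    expect_gte(ours$beta, min(beta) - 1e-12)
    expect_lte(ours$beta, max(beta) + 1e-12)
  }
})

test_that("pooling cross-checks against an established fixed-effects implementation", {
  skip_if_not_installed("metafor")
  set.seed(22)
  for (i in 1:20) {
    beta <- stats::rnorm(5)
    se <- stats::runif(5, 0.05, 0.5)
    fe <- metafor::rma(yi = beta, sei = se, method = "FE")
    ours <- ivw_pool(beta, se)
    expect_equal(ours$beta, as.numeric(fe$beta), tolerance = 1e-8)
    expect_equal(ours$se, as.numeric(fe$se), tolerance = 1e-8)
  }
})

test_that("heterogeneity statistics follow their definitions", {
  h0 <- heterogeneity(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_equal(h0$Q, 0)
  expect_equal(h0$i2, 0)
  # hand computation from the (0.5,0.1)/(1.0,0.2) example: Q = 5, I2 = 80
  h <- heterogeneity(c(0.5, 1.0), c(0.1, 0.2))
  expect_equal(h$Q, 5, tolerance = 1e-9)
  expect_equal(h$i2, 80, tolerance = 1e-9)
  expect_true(h$heterogeneous)
  # I2 of exactly 50 is NOT flagged (strict >): k = 2, Q = 2 gives I2 = 50
  se <- c(1, 1)
  beta <- c(-1, 1)  # pooled 0, Q = 1 + 1 = 2
  h50 <- heterogeneity(beta, se)
  expect_equal(h50$i2, 50)
  expect_false(h50$heterogeneous)
  # single study: i2 missing
  expect_true(is.na(heterogeneity(0.5, 0.1)$i2))
  # I2 invariant to rescaling all estimates by a common factor
  h_scaled <- heterogeneity(10 * c(0.5, 1.0), 10 * c(0.1, 0.2))
  expect_equal(h_scaled$i2, h$i2, tolerance = 1e-9)
})

test_that("Bonferroni threshold is alpha over the analyzed probe count", {
  expect_equal(signif(bonferroni_threshold(429959), 3), 1.16e-7)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(428967), 0.05 / 428967)
  expect_error(bonferroni_threshold(0), ">= 1")
})

# brute-force step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  adj
}

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(23)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # monotone with respect to the raw ordering
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("per-10% rescaling multiplies effect and SE by 0.1 and preserves z", {
  r <- rescale_per10pct(9.6288, 1.6871)
  expect_equal(r$beta, 0.96288)
  expect_equal(r$se, 0.16871)
  expect_equal(r$beta / r$se, 9.6288 / 1.6871, tolerance = 1e-12)
  expect_equal(rescale_per10pct(0, 3)$beta, 0)
})

mk_results <- function(tab) {
  # tab: data.frame(cohort_id, cpg_id, beta, se, n)
  tab$converged <- TRUE
  tab
}

test_that("run_meta pools per CpG and exposes counts, direction, FDR and flags", {
  res <- mk_results(data.frame(
    cohort_id = rep(c("c1", "c2"), each = 3),
    cpg_id = rep(c("cgA", "cgB", "cgC"), 2),
    beta = c(0.5, -0.2, 0.1, 1.0, -0.4, 0.3),
    se = c(0.1, 0.1, 0.2, 0.2, 0.1, 0.2),
    n = 100, stringsAsFactors = FALSE))
  meta <- run_meta(res, sort = FALSE)
  expect_equal(nrow(meta), 3)
  rowA <- meta[meta$cpg_id == "cgA", ]
  expect_equal(rowA$beta, 0.6 * 0.1, tolerance = 1e-12)  # per-10% scale
  expect_equal(rowA$direction, "++")
  expect_equal(meta$direction[meta$cpg_id == "cgB"], "--")
  expect_equal(rowA$total_n, 200)
  expect_true(all(meta$p_fdr >= meta$p))
  # Bonferroni hits never exceed BH hits at q = 0.05
  expect_lte(sum(meta$bonferroni), sum(meta$p_fdr < 0.05))
})

test_that("two identical cohorts halve the variance and keep the estimate", {
  one <- data.frame(cohort_id = "c1", cpg_id = c("cgA", "cgB"),
                    beta = c(0.5, -0.3), se = c(0.1, 0.2), n = 50,
                    stringsAsFactors = FALSE)
  two <- one; two$cohort_id <- "c2"
  meta <- run_meta(mk_results(rbind(one, two)), sort = FALSE)
  expect_equal(meta$beta[meta$cpg_id == "cgA"], 0.5 * 0.1, tolerance = 1e-12)
  expect_equal(meta$se[meta$cpg_id == "cgA"], 0.1 * 0.1 / sqrt(2),
               tolerance = 1e-12)
})

test_that("pooling is associative: pooling pre-pooled pairs equals pooling all", {
  set.seed(24)
  beta <- stats::rnorm(6); se <- stats::runif(6, 0.05, 0.3)
  all_at_once <- ivw_pool(beta, se)
  p1 <- ivw_pool(beta[1:3], se[1:3])
  p2 <- ivw_pool(beta[4:6], se[4:6])
  staged <- ivw_pool(c(p1$beta, p2$beta), c(p1$se, p2$se))
  expect_equal(staged$beta, all_at_once$beta, tolerance = 1e-12)
  expect_equal(staged$se, all_at_once$se, tolerance = 1e-12)
  # and order invariance
  perm <- sample(6)
  expect_equal(ivw_pool(beta[perm], se[perm])$beta, all_at_once$beta,
               tolerance = 1e-12)
})

test_that("leave-one-out reduces to the remaining studies", {
  res <- mk_results(data.frame(
    cohort_id = c("c1", "c2"), cpg_id = "cgA",
    beta = c(0.5, 1.0), se = c(0.1, 0.2), n = 100,
    stringsAsFactors = FALSE))
  loo <- leave_one_out(res)
  expect_named(loo, c("c1", "c2"))
  # dropping study 2 leaves study 1 alone
  expect_equal(loo$c2$beta, 0.5 * 0.1, tolerance = 1e-12)
  expect_equal(loo$c2$se, 0.1 * 0.1, tolerance = 1e-12)
  # duplicate a study and drop one copy: equals the pool with one copy
  res3 <- rbind(res, transform(res[2, ], cohort_id = "c3"))
  loo3 <- leave_one_out(res3)
  full2 <- run_meta(res, min_studies = 2, sort = FALSE)
  expect_equal(loo3$c3$beta, full2$beta, tolerance = 1e-12)
  expect_warning(leave_one_out(res[1, ]), ">= 2 cohorts")
})

test_that("cohort subset rules drop the right cohorts before pooling", {
  res <- mk_results(data.frame(
    cohort_id = rep(c("c1", "c2", "c3"), each = 1),
    cpg_id = "cgA", beta = c(0.5, 1.0, 0.2), se = c(0.1, 0.2, 0.1),
    n = 100, stringsAsFactors = FALSE))
  info <- data.frame(cohort_id = c("c1", "c2", "c3"),
                     ancestry = c("European", "European", "Hispanic"),
                     overweight_fraction = c(0.1, 0.4, 0.2),
                     selection_flag = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  eur <- run_meta(res, subset_rule = "europeans_only", cohort_info = info,
                  sort = FALSE)
  # equals leave-one-out of the non-European cohort
  loo <- leave_one_out(res, min_studies = 2)
  expect_equal(eur$beta, loo$c3$beta, tolerance = 1e-12)
  lean <- run_meta(res, subset_rule = "max_overweight_30pct",
                   cohort_info = info, sort = FALSE)
  expect_equal(lean$k_studies, 2L)  # c2 dropped
  # conservative leaves only c1 -> below min_studies
  expect_error(run_meta(res, subset_rule = "conservative",
                        cohort_info = info),
               "no probes")
})

test_that("a null meta-analysis rarely produces Bonferroni hits", {
  run <- null_calibration_run()
  expect_lte(sum(run$meta$bonferroni), 1)
})
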