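#' Fixed-effects inverse-variance-weighted pooling
#'
#' Each study estimate is weighted by the inverse of its squared standard
#' error: \eqn{w_i = 1/se_i^2}, pooled effect \eqn{\sum w_i \beta_i / \sum w_i},
#' pooled SE \eqn{(\sum w_i)^{-1/2}}, and a two-sided P value from the
#' standard-normal tail of z = pooled effect / pooled SE.
#'
#' @param beta numeric vector of study effect estimates.
#' @param se numeric vector of study standard errors, all > 0.
#' @return a list with `beta`, `se`, `z`, `p`.
#' @export
ivw_pool <- function(beta, se) {
  if (length(beta) == 0) stop("no estimates to pool")
  if (length(beta) != length(se)) stop("beta and se lengths differ")
  if (any(!is.finite(se) | se <= 0))
    stop("non-positive standard error at study ",
         which(!is.finite(se) | se <= 0)[1])
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  list(beta = pooled, se = pooled_se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Cochran's Q and the I-squared heterogeneity statistic
#'
#' `Q = sum(w_i * (beta_i - pooled)^2)` with `w_i = 1/se_i^2`;
#' `I2 = max(0, 100 * (Q - (k - 1)) / Q)`, the percentage of total variation
#' across studies attributed to between-study differences rather than
#' sampling variation. Heterogeneity is flagged when I2 is strictly above
#' 50; I2 is missing for a single study.
#'
#' @inheritParams ivw_pool
#' @param pooled_beta the fixed-effects pooled estimate (computed via
#'   [ivw_pool()] when omitted).
#' @return a list with `Q`, `i2` (percent, or `NA` when k < 2), and
#'   `heterogeneous` (logical).
#' @export
heterogeneity <- function(beta, se, pooled_beta = NULL) {
  if (is.null(pooled_beta)) pooled_beta <- ivw_pool(beta, se)$beta
  w <- 1 / se^2
  Q <- sum(w * (beta - pooled_beta)^2)
  k <- length(beta)
  i2 <- if (k < 2) NA_real_ else if (Q <= 0) 0 else max(0, 100 * (Q - (k - 1)) / Q)
  list(Q = Q, i2 = i2, heterogeneous = isTRUE(i2 > 50))
}

#' Bonferroni significance threshold
#'
#' @param m number of tests (analyzed probes), at least 1.
#' @param alpha family-wise error rate (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Benjamini-Hochberg step-up adjusted P values
#'
#' Step-up FDR adjustment: with P values sorted ascending, the adjusted
#' value at rank i is `min over j >= i of p_(j) * m / j`, capped at 1 and
#' mapped back to the input order. Wraps [stats::p.adjust()].
#'
#' @param p numeric vector of raw P values in (0, 1].
#' @return adjusted P values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1))
    stop("P values must lie in (0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Rescale per-unit-beta effects to the per-10%-methylation reporting scale
#'
#' Cohort models estimate effects per unit beta value (a 0-to-1 proportion,
#' i.e. per 100 percentage points of methylation); consortium results are
#' reported per 10% increase in methylation, so effect and SE are both
#' multiplied by 0.1. The z statistic is unchanged.
#'
#' @param beta,se effect estimate(s) and standard error(s) per unit beta.
#' @return a list with `beta` and `se` on the per-10% scale.
#' @export
rescale_per10pct <- function(beta, se) {
  list(beta = beta * 0.1, se = se * 0.1)
}

#' Meta-analyze per-cohort EWAS results
#'
#' Pools per-cohort (beta, SE) pairs per CpG by fixed-effects inverse-
#' variance weighting over the cohorts reporting that CpG, computes
#' Cochran's Q and I-squared, Benjamini-Hochberg adjusted P values over the
#' analyzed probe set, and the Bonferroni flag at `alpha / m`. Effects are
#' reported per 10% increase in methylation. Optional subset rules drop
#' whole cohorts before pooling (the probe universe and m are recomputed on
#' the subset).
#'
#' @param results data.frame of stacked cohort results with columns
#'   `cohort_id`, `cpg_id`, `beta`, `se`, `n`, `converged` (per-unit-beta
#'   scale, as produced by [run_cohort_ewas()]).
#' @param probe_set optional character vector restricting the analyzed
#'   probes (e.g. `filter_probes()$retained`).
#' @param min_studies minimum number of cohorts per CpG (default 2;
#'   set to 1 only for single-cohort unit testing).
#' @param subset_rule optional: `"europeans_only"`,
#'   `"max_overweight_30pct"`, or `"conservative"`; requires `cohort_info`.
#' @param cohort_info data.frame with columns `cohort_id`, `ancestry`,
#'   `overweight_fraction`, `selection_flag`, used by `subset_rule`.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param flags optional flag table (`filter_probes()$flags`) merged into
#'   the output.
#' @param sort sort results by P value (ties broken by CpG id)?
#' @return a data.frame with one row per CpG: `cpg_id`, `beta`, `se`
#'   (per 10% methylation), `z`, `p`, `p_fdr`, `bonferroni`, `k_studies`,
#'   `total_n`, `direction`, `Q`, `i2`, `het_flag`, `flags`.
#' @export
run_meta <- function(results, probe_set = NULL, min_studies = 2,
                     subset_rule = NULL, cohort_info = NULL, alpha = 0.05,
                     flags = NULL, sort = TRUE) {
  results <- results[results$converged & !is.na(results$se) & results$se > 0, ,
                     drop = FALSE]
  if (!is.null(subset_rule)) {
    keep_cohorts <- subset_cohorts(subset_rule, cohort_info)
    results <- results[results$cohort_id %in% keep_cohorts, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no cohort results to meta-analyze")
  if (!is.null(probe_set))
    results <- results[results$cpg_id %in% probe_set, , drop = FALSE]

  counts <- table(results$cpg_id)
  keep_ids <- names(counts)[counts >= min_studies]
  results <- results[results$cpg_id %in% keep_ids, , drop = FALSE]
  if (nrow(results) == 0) stop("no probes present in >= ", min_studies, " cohorts")

  cohort_order <- sort(unique(results$cohort_id))
  f <- factor(results$cpg_id)
  w <- 1 / results$se^2
  sw <- as.numeric(rowsum(w, f))
  swb <- as.numeric(rowsum(w * results$beta, f))
  swb2 <- as.numeric(rowsum(w * results$beta^2, f))
  k <- as.integer(table(f))
  total_n <- as.integer(rowsum(as.numeric(results$n), f))
  pooled <- swb / sw
  pooled_se <- 1 / sqrt(sw)
  z <- pooled / pooled_se
  # floor at the smallest positive double so extreme z never underflows to 0
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  Q <- pmax(0, swb2 - pooled^2 * sw)
  i2 <- ifelse(k < 2, NA_real_, ifelse(Q <= 0, 0, pmax(0, 100 * (Q - (k - 1)) / Q)))

  # direction string over a fixed cohort ordering
  dir_mat <- matrix("?", nrow = nlevels(f), ncol = length(cohort_order),
                    dimnames = list(levels(f), cohort_order))
  dir_mat[cbind(as.integer(f), match(results$cohort_id, cohort_order))] <-
    ifelse(results$beta > 0, "+", ifelse(results$beta < 0, "-", "0"))
  direction <- apply(dir_mat, 1, paste, collapse = "")

  per10 <- rescale_per10pct(pooled, pooled_se)
  out <- data.frame(
    cpg_id = levels(f),
    beta = per10$beta, se = per10$se, z = z, p = p,
    p_fdr = bh_adjust(p),
    bonferroni = p < bonferroni_threshold(nlevels(f), alpha),
    k_studies = k, total_n = total_n, direction = direction,
    Q = Q, i2 = i2, het_flag = !is.na(i2) & i2 > 50,
    stringsAsFactors = FALSE)
  out$flags <- if (is.null(flags)) "" else {
    fl <- flags$flags[match(out$cpg_id, flags$cpg_id)]
    ifelse(is.na(fl), "", fl)
  }
  if (sort) out <- out[order(out$p, out$cpg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m") <- nrow(out)
  attr(out, "bonferroni_threshold") <- bonferroni_threshold(nrow(out), alpha)
  attr(out, "cohort_order") <- cohort_order
  out
}

subset_cohorts <- function(rule, cohort_info) {
  rule <- match.arg(rule, c("europeans_only", "max_overweight_30pct",
                            "conservative"))
  if (is.null(cohort_info))
    stop("subset_rule '", rule, "' requires cohort_info")
  keep <- rep(TRUE, nrow(cohort_info))
  if (rule %in% c("europeans_only", "conservative"))
    keep <- keep & cohort_info$ancestry == "European"
  if (rule %in% c("max_overweight_30pct", "conservative"))
    keep <- keep & cohort_info$overweight_fraction <= 0.30
  if (rule == "conservative")
    keep <- keep & !cohort_info$selection_flag
  cohort_info$cohort_id[keep]
}

#' Leave-one-out meta-analysis
#'
#' Re-pools each CpG with one cohort removed at a time, to detect studies
#' that drive individual findings. Removing a cohort that did not report a
#' CpG leaves its pooled result unchanged.
#'
#' @inheritParams run_meta
#' @param cpg_ids optional character vector restricting the CpGs (typically
#'   the Bonferroni/FDR-significant hits).
#' @return a named list of meta-result data.frames, one per removed cohort.
#' @export
leave_one_out <- function(results, cpg_ids = NULL, probe_set = NULL,
                          min_studies = 1) {
  cohorts <- sort(unique(results$cohort_id))
  if (length(cohorts) < 2) {
    warning("leave-one-out requires >= 2 cohorts")
    return(list())
  }
  if (!is.null(cpg_ids))
    results <- results[results$cpg_id %in% cpg_ids, , drop = FALSE]
  out <- lapply(cohorts, function(ch)
    run_meta(results[results$cohort_id != ch, , drop = FALSE],
             probe_set = probe_set, min_studies = min_studies, sort = FALSE))
  names(out) <- cohorts
  out
}

#' Plot-data exports
#'
#' Tabular exports backing the standard meta-analysis figures: Manhattan
#' (chromosome, position, -log10 P), volcano (effect, -log10 P), and forest
#' (per-cohort estimates with 95% CIs plus the pooled row) plots. Rendering
#' is left to the caller.
#'
#' @param meta a meta-result table from [run_meta()].
#' @param manifest probe manifest (for chromosome/position).
#' @return a data.frame of plot coordinates.
#' @export
manhattan_data <- function(meta, manifest) {
  idx <- match(meta$cpg_id, manifest$cpg_id)
  data.frame(cpg_id = meta$cpg_id, chr = manifest$chr[idx],
             pos = manifest$pos[idx], neg_log10_p = -log10(meta$p),
             stringsAsFactors = FALSE)
}

#' @rdname manhattan_data
#' @export
volcano_data <- function(meta) {
  data.frame(cpg_id = meta$cpg_id, effect = meta$beta,
             neg_log10_p = -log10(meta$p), stringsAsFactors = FALSE)
}

#' @rdname manhattan_data
#' @param results stacked per-cohort results (per-unit-beta scale).
#' @param cpg_id the CpG to plot.
#' @export
forest_data <- function(results, cpg_id) {
  sub <- results[results$cpg_id == cpg_id & results$converged, , drop = FALSE]
  if (nrow(sub) == 0) stop("no cohort results for ", cpg_id)
  pooled <- ivw_pool(sub$beta, sub$se)
  rows <- rbind(
    data.frame(label = sub$cohort_id,
               beta = sub$beta * 0.1, se = sub$se * 0.1,
               stringsAsFactors = FALSE),
    data.frame(label = "pooled", beta = pooled$beta * 0.1,
               se = pooled$se * 0.1, stringsAsFactors = FALSE))
  rows$ci_lo <- rows$beta - 1.96 * rows$se
  rows$ci_hi <- rows$beta + 1.96 * rows$se
  rows
}
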