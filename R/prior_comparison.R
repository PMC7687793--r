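#' Construct or read a published prior CpG set
#'
#' A prior set is a published list of BMI-associated CpGs, optionally with
#' effect estimates, used for look-up replication, enrichment, and
#' effect-estimate correlation against a meta-analysis result table.
#'
#' @param cpg_ids character vector of unique CpG ids.
#' @param effects optional numeric vector of published effect estimates,
#'   aligned with `cpg_ids`.
#' @param source_label short label for the source study.
#' @param n_cpgs_tested number of CpGs reported by the source (defaults to
#'   `length(cpg_ids)`); used for the per-study Bonferroni look-up cutoff.
#' @param effect_units free-text record of the source's effect units
#'   (units are recorded, not converted).
#' @return an object of class `prior_cpg_set`.
#' @export
prior_cpg_set <- function(cpg_ids, effects = NULL, source_label = "prior",
                          n_cpgs_tested = length(cpg_ids),
                          effect_units = NA_character_) {
  if (length(cpg_ids) == 0) stop("prior set is empty")
  if (anyDuplicated(cpg_ids)) stop("prior set cpg_ids must be unique")
  if (!is.null(effects) && length(effects) != length(cpg_ids))
    stop("effects must align with cpg_ids")
  if (n_cpgs_tested < 1) stop("n_cpgs_tested must be >= 1")
  structure(list(cpg_ids = as.character(cpg_ids), effects = effects,
                 source_label = source_label, n_cpgs_tested = n_cpgs_tested,
                 effect_units = effect_units),
            class = "prior_cpg_set")
}

#' @rdname prior_cpg_set
#' @param path comma-separated file with header columns `cpg_id`, `effect`,
#'   `source`, `n_cpgs_tested` (`effect` may be empty).
#' @export
read_prior_set <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  effects <- if ("effect" %in% names(df) && !all(is.na(df$effect)))
    df$effect else NULL
  prior_cpg_set(df$cpg_id, effects = effects,
                source_label = if ("source" %in% names(df)) df$source[1] else "prior",
                n_cpgs_tested = if ("n_cpgs_tested" %in% names(df))
                  df$n_cpgs_tested[1] else nrow(df))
}

#' Look up a prior CpG set in a meta-analysis table
#'
#' Replication uses a per-study Bonferroni cutoff of
#' `0.05 / n_cpgs_tested` in the source study. Prior CpGs absent from the
#' analyzed universe are reported as untested, not counted as failures.
#'
#' @param prior a [prior_cpg_set()].
#' @param meta a meta-result table from [run_meta()].
#' @param alpha family-wise rate for the per-study cutoff (default 0.05).
#' @return a data.frame with one row per prior CpG: `cpg_id`, `tested`,
#'   `p`, `replicated`; the per-study `cutoff` is attached as an attribute.
#' @export
lookup_replication <- function(prior, meta, alpha = 0.05) {
  stopifnot(inherits(prior, "prior_cpg_set"))
  cutoff <- alpha / prior$n_cpgs_tested
  idx <- match(prior$cpg_ids, meta$cpg_id)
  out <- data.frame(cpg_id = prior$cpg_ids,
                    tested = !is.na(idx),
                    p = meta$p[idx],
                    stringsAsFactors = FALSE)
  out$replicated <- ifelse(out$tested, out$p < cutoff, NA)
  attr(out, "cutoff") <- cutoff
  out
}

#' Top CpG list at a P-value cutoff
#'
#' @param meta a meta-result table.
#' @param cutoff P-value threshold in (0, 1); strictly-below rule, so a P
#'   exactly equal to the cutoff is excluded.
#' @return character vector of CpG ids with raw meta P < cutoff.
#' @export
top_list <- function(meta, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  meta$cpg_id[meta$p < cutoff]
}

#' One-sided hypergeometric enrichment test
#'
#' Probability of observing at least `k` prior-set CpGs among the top `n`
#' of a universe of `N` analyzed probes containing `K` prior CpGs:
#' `P(X >= k)` for X hypergeometric, computed exactly via
#' [stats::phyper()] (no normal approximation).
#'
#' @param K prior-set size present in the universe context.
#' @param n top-list size (draws).
#' @param N universe size (analyzed probes).
#' @param k observed overlap.
#' @return a list of class `enrichment_result` with fields `K`, `n`, `N`,
#'   `k`, `p_upper`.
#' @export
hypergeom_enrichment <- function(K, n, N, k) {
  if (k < 0 || k > min(K, n) || K > N || n > N)
    stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(K = K, n = n, N = N, k = k, p_upper = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("hypergeometric enrichment: %d/%d in top %d of %d, P = %.3g\n",
              x$k, x$K, x$n, x$N, x$p_upper))
  invisible(x)
}

#' Pearson correlation of prior vs meta effect estimates
#'
#' Correlates published effect estimates with the meta-analysis estimates
#' for the matching CpGs (per-10% reporting scale); the two-sided P value
#' comes from `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param prior_effects,meta_effects numeric vectors matched on CpG.
#' @return a list with `r`, `n_pairs`, `p`.
#' @export
effect_correlation <- function(prior_effects, meta_effects) {
  keep <- stats::complete.cases(prior_effects, meta_effects)
  x <- prior_effects[keep]; y <- meta_effects[keep]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in effect estimates; correlation undefined")
  r <- stats::cor(x, y)
  p <- correlation_p(r, n)
  list(r = r, n_pairs = n, p = p)
}

#' @rdname effect_correlation
#' @param r a correlation coefficient.
#' @param n the number of pairs behind it.
#' @details `effect_correlation_p()` exposes the P-value computation for a
#'   known (r, n) pair directly; a degenerate |r| = 1 underflows to the
#'   smallest positive double rather than zero.
#' @export
effect_correlation_p <- function(r, n) {
  if (abs(r) >= 1) return(.Machine$double.xmin)  # degenerate, underflow floor
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  max(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
}

correlation_p <- effect_correlation_p

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided standard-normal P value.
#'
#' @param r1,r2 correlation coefficients, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, both > 3.
#' @return a list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Chi-square test for overlap of two CpG sets within a universe
#'
#' Pearson chi-square (1 df) on the 2x2 membership table of the universe
#' cross-classified by membership in each set; no continuity correction by
#' default.
#'
#' @param set1,set2 character vectors, both subsets of `universe`.
#' @param universe character vector of all analyzed CpGs.
#' @param correct apply the Yates continuity correction?
#' @return a list with `chi2`, `p`, and the 2x2 `table`.
#' @export
overlap_chi2 <- function(set1, set2, universe, correct = FALSE) {
  if (!all(set1 %in% universe) || !all(set2 %in% universe))
    stop("both sets must be subsets of the universe")
  in1 <- universe %in% set1
  in2 <- universe %in% set2
  if (!any(in1) || all(in1) || !any(in2) || all(in2))
    stop("degenerate margins: sets must be nonempty proper subsets of the universe")
  tab <- table(factor(in1, c(FALSE, TRUE)), factor(in2, c(FALSE, TRUE)))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}

#' Enrichment report against multiple prior sets
#'
#' Builds the standard enrichment table: for each prior set and each
#' P-value cutoff, the overlap of the prior CpGs with the top list and the
#' one-sided hypergeometric enrichment P value. By default the prior-set
#' size K is the full published count; `restrict_to_universe = TRUE`
#' restricts K to the intersection with the analyzed universe.
#'
#' @param meta a meta-result table from [run_meta()].
#' @param priors a list of [prior_cpg_set()] objects.
#' @param cutoffs P-value cutoffs defining the top lists
#'   (default `c(1e-5, 0.05)`).
#' @param restrict_to_universe restrict K to prior CpGs present in the
#'   analyzed universe?
#' @return a data.frame with columns `source`, `cutoff`, `k`, `K`, `n`,
#'   `N`, `p_upper`.
#' @export
enrichment_report <- function(meta, priors, cutoffs = c(1e-5, 0.05),
                              restrict_to_universe = FALSE) {
  if (inherits(priors, "prior_cpg_set")) priors <- list(priors)
  N <- nrow(meta)
  rows <- list()
  for (prior in priors) {
    in_universe <- prior$cpg_ids[prior$cpg_ids %in% meta$cpg_id]
    K <- if (restrict_to_universe) length(in_universe) else length(prior$cpg_ids)
    for (cutoff in cutoffs) {
      top <- top_list(meta, cutoff)
      k <- length(intersect(in_universe, top))
      er <- hypergeom_enrichment(K, length(top), N, k)
      rows[[length(rows) + 1]] <- data.frame(
        source = prior$source_label, cutoff = cutoff, k = k, K = K,
        n = length(top), N = N, p_upper = er$p_upper,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
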