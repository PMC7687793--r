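#' Model specifications for the consortium analyses
#'
#' Four continuous-outcome models plus a binary case-control model:
#' \describe{
#'   \item{A, B}{cord-blood methylation vs early / late childhood BMI-SDS,
#'     adjusted for maternal age, education, smoking, BMI, parity,
#'     gestational age, batch, and estimated cell-type proportions.}
#'   \item{C}{cross-sectional childhood model; as A/B plus birth weight and
#'     breastfeeding.}
#'   \item{D}{cross-sectional adolescent model; as C plus sex, age, own
#'     smoking, and puberty status.}
#'   \item{case_control}{overweight/obesity vs normal weight (logistic),
#'     covariates as model C.}
#' }
#' One of the six compositional cell proportions is omitted from the design
#' to avoid exact collinearity.
#'
#' @param model_id one of `"A"`, `"B"`, `"C"`, `"D"`, `"case_control"`.
#' @return a list with `model_id`, `outcome`, `covariates`, `description`.
#' @export
model_spec <- function(model_id = c("A", "B", "C", "D", "case_control")) {
  model_id <- match.arg(model_id)
  cells <- c("cp_bcell", "cp_cd4t", "cp_cd8t", "cp_gran", "cp_mono")
  base <- c("maternal_age", "maternal_education", "maternal_smoking",
            "maternal_bmi", "parity", "gestational_age_weeks", "batch", cells)
  child <- c(base, "birth_weight_g", "breastfeeding")
  adol <- c(child, "sex", "age_years", "child_smoking", "puberty")
  spec <- switch(model_id,
    A = list(outcome = "bmi_sds", covariates = base,
             description = "cord blood methylation vs early childhood BMI-SDS"),
    B = list(outcome = "bmi_sds", covariates = base,
             description = "cord blood methylation vs late childhood BMI-SDS"),
    C = list(outcome = "bmi_sds", covariates = child,
             description = "cross-sectional childhood methylation vs BMI-SDS"),
    D = list(outcome = "bmi_sds", covariates = adol,
             description = "cross-sectional adolescent methylation vs BMI-SDS"),
    case_control = list(outcome = "overweight_binary", covariates = child,
             description = "overweight/obesity vs normal weight (logistic)"))
  c(list(model_id = model_id), spec)
}

#' Huber robust linear regression for one CpG
#'
#' Huber M-estimation by iteratively reweighted least squares with tuning
#' constant 1.345 (95% Gaussian efficiency), residual scale estimated by the
#' normalized median absolute deviation, and standard errors from the
#' asymptotic M-estimator covariance. This is the per-CpG model for the
#' continuous BMI-SDS outcome; the fit is delegated to [MASS::rlm()].
#'
#' @param y numeric outcome vector (BMI-SDS).
#' @param x numeric exposure vector (methylation beta, native 0-1 scale).
#' @param covariates optional numeric design matrix of adjustment covariates
#'   (already expanded to columns; no intercept).
#' @param maxit,acc IRLS iteration cap and convergence tolerance.
#' @return a list with `beta` (BMI-SDS per unit beta), `se`, `n`,
#'   `converged`, and the Wald `p`.
#' @export
fit_robust <- function(y, x, covariates = NULL, maxit = 50, acc = 1e-8) {
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n <= ncol(X) + 5)
    return(list(beta = NA_real_, se = NA_real_, n = n, converged = FALSE,
                p = NA_real_, reason = "insufficient_n"))
  if (qr(X)$rank < ncol(X))
    return(list(beta = NA_real_, se = NA_real_, n = n, converged = FALSE,
                p = NA_real_, reason = "rank_deficient"))
  fit <- tryCatch(
    suppressWarnings(
      MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345, scale.est = "MAD",
                maxit = maxit, acc = acc)),
    error = function(e) NULL)
  if (!is.null(fit) && !isTRUE(fit$converged)) {
    # degenerate exact fit: the MAD residual scale collapses to zero and the
    # IRLS flags non-convergence although the coefficients are exact
    resid <- y - drop(X %*% fit$coefficients)
    if (max(abs(resid)) < 1e-8 * max(1, max(abs(y))))
      return(list(beta = unname(fit$coefficients["x"]), se = NA_real_, n = n,
                  converged = TRUE, p = NA_real_, reason = "exact_fit"))
  }
  if (is.null(fit) || !isTRUE(fit$converged))
    return(list(beta = NA_real_, se = NA_real_, n = n, converged = FALSE,
                p = NA_real_, reason = "non_convergence"))
  sm <- summary(fit, method = "XtX")
  beta <- unname(sm$coefficients["x", "Value"])
  se <- unname(sm$coefficients["x", "Std. Error"])
  z <- beta / se
  list(beta = beta, se = se, n = n, converged = TRUE,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Logistic regression for the overweight/obesity case-control outcome
#'
#' Maximum-likelihood logistic fit; reports the coefficient on the log-odds
#' scale together with the odds ratio and its Wald 95% confidence interval.
#' Separation (diverging estimates) is recorded as non-convergence.
#'
#' @param case binary outcome vector (1 = overweight/obese, 0 = normal).
#' @param x numeric exposure vector (methylation beta).
#' @param covariates optional numeric design matrix (no intercept).
#' @return a list with `beta` (log-odds per unit beta), `se`, `n`,
#'   `converged`, `p`, `or`, and `or_ci` (length 2).
#' @export
fit_logistic <- function(case, x, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, x = x, covariates)
  keep <- stats::complete.cases(X, case)
  X <- X[keep, , drop = FALSE]
  case <- case[keep]
  n <- length(case)
  fail <- function(reason) list(beta = NA_real_, se = NA_real_, n = n,
                                converged = FALSE, p = NA_real_,
                                or = NA_real_, or_ci = c(NA_real_, NA_real_),
                                reason = reason)
  if (length(unique(case)) < 2) return(fail("one_outcome_class"))
  if (qr(X)$rank < ncol(X)) return(fail("rank_deficient"))
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, case, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(fail("non_convergence"))
  beta <- fit$coefficients["x"]
  cov <- tryCatch(chol2inv(chol(crossprod(X * sqrt(fit$weights)))),
                  error = function(e) NULL)
  if (is.null(cov)) return(fail("singular_information"))
  se <- sqrt(cov[2, 2])
  if (!is.finite(se) || abs(beta) > 20) return(fail("separation"))
  z <- beta / se
  list(beta = unname(beta), se = se, n = n, converged = TRUE,
       p = 2 * stats::pnorm(-abs(z)),
       or = exp(unname(beta)),
       or_ci = exp(unname(beta) + c(-1, 1) * 1.96 * se))
}

# Expand a sample sheet into a numeric covariate design (no intercept).
build_covariate_matrix <- function(samples, covariate_names) {
  missing_cols <- setdiff(covariate_names, names(samples))
  if (length(missing_cols) > 0)
    stop("sample sheet is missing covariates: ",
         paste(missing_cols, collapse = ", "))
  df <- samples[, covariate_names, drop = FALSE]
  for (nm in names(df))
    if (is.character(df[[nm]]) || is.logical(df[[nm]]))
      df[[nm]] <- factor(df[[nm]])
  # drop factors with a single observed level (e.g. one batch)
  for (nm in names(df))
    if (is.factor(df[[nm]]) && nlevels(droplevels(df[[nm]])) < 2)
      df[[nm]] <- NULL
  if (ncol(df) == 0) return(NULL)
  stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
}

#' Run the EWAS within one cohort
#'
#' Fits the per-CpG model of `spec` probe by probe. Rows with any missing
#' covariate or outcome for the model are dropped once, before all probes
#' (complete-case analysis); probe-level beta missingness then varies per
#' probe, so per-probe `n` reflects it. Probes with all-missing or constant
#' beta values are absent from the result.
#'
#' @param dataset a `cohort_dataset` (see [generate_consortium()] /
#'   [read_cohort()]).
#' @param spec a model specification from [model_spec()].
#' @param probes optional character vector restricting the analyzed CpGs.
#' @param lms_ref,cutoffs growth reference and IOTF cutoff tables used to
#'   derive BMI-SDS and weight class when not already present.
#' @param stratify_by optional sample-sheet column; strata are analyzed
#'   separately and results returned with suffixed cohort ids.
#' @return a data.frame with columns `cohort_id`, `cpg_id`, `beta`, `se`,
#'   `n`, `converged`, `p` (one row per analyzable probe).
#' @export
run_cohort_ewas <- function(dataset, spec, probes = NULL,
                            lms_ref = ewas_lms_reference(),
                            cutoffs = ewas_iotf_cutoffs(),
                            stratify_by = NULL) {
  if (!is.null(stratify_by)) {
    groups <- unique(dataset$samples[[stratify_by]])
    out <- lapply(groups, function(g) {
      idx <- dataset$samples[[stratify_by]] == g
      sub <- dataset
      sub$samples <- dataset$samples[idx, , drop = FALSE]
      sub$betas <- dataset$betas[, idx, drop = FALSE]
      sub$cohort_id <- paste(dataset$cohort_id, g, sep = "_")
      run_cohort_ewas(sub, spec, probes, lms_ref, cutoffs)
    })
    return(do.call(rbind, out))
  }

  samples <- dataset$samples
  if (is.null(samples$bmi_sds) || is.null(samples$weight_class))
    samples <- prepare_phenotypes(samples, lms_ref, cutoffs)

  if (spec$outcome == "bmi_sds") {
    y <- samples$bmi_sds
    keep_outcome <- !is.na(y)
  } else {
    cc <- build_case_control(samples, cutoffs)
    if (!cc$eligible) {
      warning("cohort ", dataset$cohort_id,
              " ineligible for case-control analysis (<= 10 in one group)")
      return(empty_ewas_result())
    }
    y <- as.integer(cc$assignment == "case")
    keep_outcome <- !is.na(cc$assignment)
  }

  covars <- build_covariate_matrix(samples, spec$covariates)
  keep <- keep_outcome & stats::complete.cases(if (is.null(covars)) y else covars)
  y <- y[keep]
  covars <- if (is.null(covars)) NULL else covars[keep, , drop = FALSE]
  betas <- dataset$betas[, keep, drop = FALSE]
  if (!is.null(probes))
    betas <- betas[intersect(probes, rownames(betas)), , drop = FALSE]

  rows <- vector("list", nrow(betas))
  for (i in seq_len(nrow(betas))) {
    x <- betas[i, ]
    obs <- !is.na(x)
    if (sum(obs) == 0 || stats::var(x[obs]) == 0) next
    fit <- if (spec$outcome == "bmi_sds")
      fit_robust(y, x, covars)
    else
      fit_logistic(y, x, covars)
    rows[[i]] <- data.frame(cohort_id = dataset$cohort_id,
                            cpg_id = rownames(betas)[i],
                            beta = fit$beta, se = fit$se, n = fit$n,
                            converged = fit$converged, p = fit$p,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no analyzable probes in cohort ", dataset$cohort_id)
    return(empty_ewas_result())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_ewas_result <- function() {
  data.frame(cohort_id = character(0), cpg_id = character(0),
             beta = numeric(0), se = numeric(0), n = integer(0),
             converged = logical(0), p = numeric(0), stringsAsFactors = FALSE)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, df = 1, lower.tail = FALSE)) / 0.4549364`,
#' the ratio of the median observed association chi-square to the null
#' chi-square(1) median; approximately 1 under a well-calibrated null.
#'
#' @param p numeric vector of P values in (0, 1].
#' @return the inflation factor (scalar).
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  if (length(p) < 100)
    warning("fewer than 100 P values; lambda estimate is unstable")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
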