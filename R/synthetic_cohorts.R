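#' Configure a synthetic methylation consortium
#'
#' The simulator emulates a multi-cohort EWAS consortium: each cohort has
#' its own size, ancestry composition, overweight prevalence, batch
#' structure, and the full covariate set used by the analysis models.
#' Methylation beta values are drawn logit-normally with probe-specific
#' means shared across cohorts (so probes are comparable in meta-analysis),
#' and BMI can depend on methylation in either causal direction:
#' \describe{
#'   \item{`null`}{no probe-BMI dependence (calibration runs).}
#'   \item{`meth_to_bmi`}{BMI-SDS gains `effect * (beta - mean_beta)` from
#'     each planted probe before back-transforming to raw BMI through the
#'     LMS reference (effects in BMI-SDS per unit beta).}
#'   \item{`bmi_to_meth`}{logit(beta) at each planted probe is shifted by
#'     `age_multiplier(age) * effect * BMI-SDS`, emulating methylation that
#'     responds to adiposity increasingly with age.}
#' }
#'
#' @param master_seed integer master seed; all randomness derives from it.
#' @param n_cohorts number of cohorts.
#' @param samples_per_cohort integer vector of cohort sizes (length
#'   `n_cohorts`).
#' @param n_probes number of CpG probes.
#' @param age_window numeric `(min_years, max_years)`; ages are drawn
#'   uniformly inside it.
#' @param causal_mode `"null"`, `"meth_to_bmi"`, or `"bmi_to_meth"`.
#' @param planted_probes integer probe indices carrying planted effects.
#' @param planted_effects numeric effects, aligned with `planted_probes`
#'   (BMI-SDS per unit beta for `meth_to_bmi`; logit-beta per BMI-SDS,
#'   scaled by the age multiplier, for `bmi_to_meth`).
#' @param age_effect_schedule either a function `age -> multiplier` or a
#'   numeric `c(intercept, slope_per_year)`; multipliers are truncated at 0.
#' @param probe_mean_logit per-probe logit-scale means; `NULL` draws them
#'   from N(0, 1.5) under the master seed (shared across cohorts).
#' @param probe_sd_logit logit-scale within-probe SD (scalar or per probe).
#' @param covariate_effects named numeric vector of effects of standardized
#'   covariates on BMI-SDS.
#' @param noise_sd residual SD of BMI-SDS.
#' @param overweight_target per-cohort target fraction of overweight/obese
#'   children (or `NA` for no tuning); achieved within +/- 2% by shifting
#'   the cohort BMI-SDS intercept.
#' @param ancestry per-cohort ancestry labels.
#' @param selection_flag per-cohort logical: sample selected/enriched on an
#'   exposure or outcome (used by the conservative sensitivity subset).
#' @param batch_effect_logit logit-scale shift applied to the second batch.
#' @param missing_rate per-cell completely-at-random missingness rate for
#'   the beta matrix.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(master_seed = 1,
                       n_cohorts = 4,
                       samples_per_cohort = rep(250L, n_cohorts),
                       n_probes = 1000,
                       age_window = c(2, 10),
                       causal_mode = c("null", "meth_to_bmi", "bmi_to_meth"),
                       planted_probes = integer(0),
                       planted_effects = numeric(0),
                       age_effect_schedule = c(1, 0),
                       probe_mean_logit = NULL,
                       probe_sd_logit = 1.0,
                       covariate_effects = c(maternal_bmi = 0.25,
                                             maternal_smoking = 0.15,
                                             breastfeeding = -0.10,
                                             sex = 0.05),
                       noise_sd = 1.0,
                       overweight_target = rep(NA_real_, n_cohorts),
                       ancestry = rep("European", n_cohorts),
                       selection_flag = rep(FALSE, n_cohorts),
                       batch_effect_logit = 0.1,
                       missing_rate = 0) {
  causal_mode <- match.arg(causal_mode)
  cfg <- list(master_seed = as.integer(master_seed), n_cohorts = n_cohorts,
              samples_per_cohort = as.integer(samples_per_cohort),
              n_probes = n_probes, age_window = age_window,
              causal_mode = causal_mode, planted_probes = planted_probes,
              planted_effects = planted_effects,
              age_effect_schedule = age_effect_schedule,
              probe_mean_logit = probe_mean_logit,
              probe_sd_logit = probe_sd_logit,
              covariate_effects = covariate_effects, noise_sd = noise_sd,
              overweight_target = overweight_target, ancestry = ancestry,
              selection_flag = selection_flag,
              batch_effect_logit = batch_effect_logit,
              missing_rate = missing_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, field, what)
    if (!cond) stop("invalid sim_config field '", field, "': ", what)
  chk(cfg$n_cohorts >= 1, "n_cohorts", "must be >= 1")
  chk(length(cfg$samples_per_cohort) == cfg$n_cohorts, "samples_per_cohort",
      "length must equal n_cohorts")
  chk(all(cfg$samples_per_cohort >= 1), "samples_per_cohort", "counts must be >= 1")
  chk(cfg$n_probes >= 1, "n_probes", "must be >= 1")
  chk(length(cfg$age_window) == 2 && cfg$age_window[1] < cfg$age_window[2],
      "age_window", "must be (min, max) with min < max")
  chk(length(cfg$planted_probes) == length(cfg$planted_effects),
      "planted_effects", "length must equal planted_probes")
  chk(all(cfg$planted_probes >= 1 & cfg$planted_probes <= cfg$n_probes),
      "planted_probes", "indices must lie in 1..n_probes")
  chk(all(cfg$probe_sd_logit > 0), "probe_sd_logit", "must be > 0")
  chk(is.null(cfg$probe_mean_logit) ||
        length(cfg$probe_mean_logit) == cfg$n_probes, "probe_mean_logit",
      "length must equal n_probes")
  chk(length(cfg$ancestry) == cfg$n_cohorts, "ancestry",
      "length must equal n_cohorts")
  chk(length(cfg$selection_flag) == cfg$n_cohorts, "selection_flag",
      "length must equal n_cohorts")
  chk(length(cfg$overweight_target) == cfg$n_cohorts, "overweight_target",
      "length must equal n_cohorts")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  if (is.function(cfg$age_effect_schedule)) {
    mult <- cfg$age_effect_schedule(seq(cfg$age_window[1], cfg$age_window[2],
                                        length.out = 5))
    chk(all(mult >= 0), "age_effect_schedule", "multipliers must be >= 0")
  }
  invisible(cfg)
}

# Fixed seed-splitting rule: the master seed is mixed with the cohort index
# through a linear congruential combination, so adding a cohort never
# perturbs the draws of earlier cohorts. Index 0 is reserved for the
# probe-level parameters shared across cohorts.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 48271 + index * 69621) %% 2147483647)
}

age_multiplier <- function(schedule, age) {
  if (is.function(schedule)) pmax(0, schedule(age))
  else pmax(0, schedule[1] + schedule[2] * age)
}

probe_ids <- function(n_probes) sprintf("cg%08d", seq_len(n_probes))

#' Generate a synthetic probe manifest
#'
#' Probe ids match [generate_consortium()]'s beta matrices. Chromosomes are
#' drawn with a small fraction of X/Y probes, and SNP/INDEL/repeat/
#' cross-reactive flags at realistic 450K-like rates, so the probe-filter
#' stage has work to do.
#'
#' @param n_probes number of probes.
#' @param seed integer seed (use the simulation master seed to pair the
#'   manifest with a generated consortium).
#' @param xy_fraction fraction of probes placed on X/Y.
#' @param cross_reactive_fraction fraction flagged cross-reactive.
#' @return a manifest `data.frame` (see [read_manifest()]).
#' @export
make_manifest <- function(n_probes, seed = 1, xy_fraction = 0.03,
                          cross_reactive_fraction = 0.02) {
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(rs))
  set.seed(derive_seed(seed, 999))
  chr <- sample(as.character(1:22), n_probes, replace = TRUE)
  n_xy <- round(xy_fraction * n_probes)
  if (n_xy > 0)
    chr[sample.int(n_probes, n_xy)] <- sample(c("X", "Y"), n_xy,
                                              replace = TRUE, prob = c(0.8, 0.2))
  man <- data.frame(
    cpg_id = probe_ids(n_probes),
    chr = chr,
    pos = sample.int(1e8, n_probes, replace = TRUE),
    gene = paste0("GENE", sample.int(max(2, n_probes %/% 3), n_probes,
                                     replace = TRUE)),
    flag_snp = stats::rbinom(n_probes, 1, 0.05),
    flag_indel = stats::rbinom(n_probes, 1, 0.02),
    flag_repeat = stats::rbinom(n_probes, 1, 0.05),
    flag_cross_reactive = stats::rbinom(n_probes, 1, cross_reactive_fraction),
    stringsAsFactors = FALSE)
  man
}

restore_seed <- function(rs) {
  if (is.null(rs)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", rs, envir = globalenv())
}

#' Autosomal, unflagged probes of a manifest
#'
#' Convenience selector for planting effects on probes that survive
#' [filter_probes()].
#'
#' @param manifest a probe manifest.
#' @return integer indices of clean autosomal probes.
#' @export
clean_probes <- function(manifest) {
  which(!manifest$chr %in% c("X", "Y") & manifest$flag_cross_reactive == 0)
}

#' Generate a synthetic multi-cohort consortium
#'
#' Deterministic given the configuration: per-cohort sub-seeds are derived
#' from the master seed by a fixed splitting rule. Returns one
#' `cohort_dataset` per cohort, each holding a probe-by-sample beta matrix
#' and a sample sheet with the full covariate set (sex, age, raw BMI,
#' maternal covariates, birth weight, breastfeeding, own smoking, Tanner
#' stages, Dirichlet cell-type proportions, batch).
#'
#' @param config a [sim_config()].
#' @param lms_ref,cutoffs growth reference and IOTF cutoffs used to
#'   back-transform BMI-SDS to raw BMI and to tune overweight prevalence.
#' @return a list of `cohort_dataset` objects. Each carries a `truth`
#'   attribute recording the planted probe ids, effects, causal mode, and
#'   the intercept shift applied for prevalence tuning.
#' @export
generate_consortium <- function(config, lms_ref = ewas_lms_reference(),
                                cutoffs = ewas_iotf_cutoffs()) {
  validate_sim_config(config)
  rs <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(rs))

  set.seed(derive_seed(config$master_seed, 0))
  mu <- config$probe_mean_logit %||% stats::rnorm(config$n_probes, 0, 1.5)
  sd_logit <- rep(config$probe_sd_logit, length.out = config$n_probes)
  pid <- probe_ids(config$n_probes)

  lapply(seq_len(config$n_cohorts), function(ci) {
    set.seed(derive_seed(config$master_seed, ci))
    generate_cohort(config, ci, mu, sd_logit, pid, lms_ref, cutoffs)
  })
}

generate_cohort <- function(cfg, ci, mu, sd_logit, pid, lms_ref, cutoffs) {
  n <- cfg$samples_per_cohort[ci]
  cohort_id <- sprintf("cohort_%02d", ci)

  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- stats::runif(n, cfg$age_window[1], cfg$age_window[2])
  maternal_age <- stats::rnorm(n, 30, 4.5)
  maternal_education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                               prob = c(0.25, 0.45, 0.30))
  maternal_smoking <- stats::rbinom(n, 1, 0.15)
  maternal_bmi <- stats::rnorm(n, 24, 4)
  parity <- stats::rbinom(n, 1, 0.45)
  gestational_age_weeks <- stats::rnorm(n, 39.5, 1.7)
  birth_weight_g <- stats::rnorm(n, 3450, 500)
  breastfeeding <- stats::rbinom(n, 1, 0.7)
  child_smoking <- stats::rbinom(n, 1, ifelse(age >= 12, 0.08, 0))
  tanner1 <- pmin(5L, pmax(1L, as.integer(round(1 + 0.6 * (age - 9) +
                                                  stats::rnorm(n, 0, 0.7)))))
  tanner2 <- pmin(5L, pmax(1L, as.integer(round(1 + 0.6 * (age - 9) +
                                                  stats::rnorm(n, 0, 0.7)))))
  menarche_or_voice <- stats::runif(n) < stats::plogis(1.5 * (age - 13))
  batch <- sample(c("b1", "b2"), n, replace = TRUE)

  cell_alpha <- c(cp_bcell = 6, cp_cd4t = 12, cp_cd8t = 8, cp_gran = 45,
                  cp_mono = 6, cp_nk = 4)
  g <- matrix(stats::rgamma(n * 6, shape = rep(cell_alpha, each = n)), n, 6)
  cells <- g / rowSums(g)
  colnames(cells) <- names(cell_alpha)

  # covariate contribution to BMI-SDS, on standardized covariate scales
  std <- cbind(maternal_bmi = (maternal_bmi - 24) / 4,
               maternal_smoking = maternal_smoking,
               breastfeeding = breastfeeding,
               sex = as.numeric(sex == "M"),
               maternal_age = (maternal_age - 30) / 4.5,
               birth_weight = (birth_weight_g - 3450) / 500)
  eff <- cfg$covariate_effects
  used <- intersect(names(eff), colnames(std))
  cov_lp <- if (length(used)) drop(std[, used, drop = FALSE] %*% eff[used]) else 0

  # logit-normal betas with shared probe means and a batch shift
  eps <- matrix(stats::rnorm(cfg$n_probes * n, 0, sd_logit),
                cfg$n_probes, n)
  logit_beta <- mu + eps +
    matrix(cfg$batch_effect_logit * (batch == "b2"), cfg$n_probes, n,
           byrow = TRUE)

  noise <- stats::rnorm(n, 0, cfg$noise_sd)
  meth_lp <- 0
  if (cfg$causal_mode == "meth_to_bmi" && length(cfg$planted_probes) > 0) {
    b <- stats::plogis(logit_beta[cfg$planted_probes, , drop = FALSE])
    centered <- b - stats::plogis(mu[cfg$planted_probes])
    meth_lp <- drop(crossprod(centered, cfg$planted_effects))
  }
  base_lp <- cov_lp + meth_lp + noise

  shift <- 0
  target <- cfg$overweight_target[ci]
  if (!is.na(target))
    shift <- tune_overweight_shift(base_lp, sex, age, target, lms_ref, cutoffs)
  bmi_sds <- base_lp + shift
  bmi <- lms_inverse(bmi_sds, sex, age, lms_ref)
  # guard against extreme tails falling off the Box-Cox support
  bad <- !is.finite(bmi)
  if (any(bad)) bmi[bad] <- lms_inverse(sign(bmi_sds[bad]) * 4, sex[bad],
                                        age[bad], lms_ref)

  if (cfg$causal_mode == "bmi_to_meth" && length(cfg$planted_probes) > 0) {
    mult <- age_multiplier(cfg$age_effect_schedule, age)
    shift_mat <- outer(cfg$planted_effects, mult * bmi_sds)
    logit_beta[cfg$planted_probes, ] <-
      logit_beta[cfg$planted_probes, , drop = FALSE] + shift_mat
  }

  betas <- stats::plogis(logit_beta)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(betas)) < cfg$missing_rate
    betas[miss] <- NA_real_
  }
  sample_id <- sprintf("%s_s%04d", cohort_id, seq_len(n))
  dimnames(betas) <- list(pid, sample_id)

  samples <- data.frame(
    sample_id = sample_id, sex = sex, age_years = age, bmi_kg_m2 = bmi,
    maternal_age = maternal_age, maternal_education = maternal_education,
    maternal_smoking = maternal_smoking, maternal_bmi = maternal_bmi,
    parity = parity, gestational_age_weeks = gestational_age_weeks,
    birth_weight_g = birth_weight_g, breastfeeding = breastfeeding,
    child_smoking = child_smoking,
    tanner_breast_or_genital = tanner1, tanner_pubic = tanner2,
    menarche_or_voice = menarche_or_voice, batch = batch,
    ancestry = cfg$ancestry[ci], selection_flag = cfg$selection_flag[ci],
    stringsAsFactors = FALSE)
  samples <- cbind(samples, as.data.frame(cells))

  structure(list(cohort_id = cohort_id, betas = betas, samples = samples,
                 ancestry = cfg$ancestry[ci],
                 selection_flag = cfg$selection_flag[ci]),
            class = "cohort_dataset",
            truth = list(causal_mode = cfg$causal_mode,
                         planted_cpgs = pid[cfg$planted_probes],
                         planted_effects = cfg$planted_effects,
                         intercept_shift = shift,
                         bmi_sds = bmi_sds))
}

# Monotone bisection on the BMI-SDS intercept until the IOTF overweight/
# obesity fraction is within +/- 2% of the target.
tune_overweight_shift <- function(base_lp, sex, age, target, lms_ref, cutoffs) {
  frac_at <- function(shift) {
    bmi <- lms_inverse(pmin(4, pmax(-4, base_lp + shift)), sex, age, lms_ref)
    wc <- iotf_classify(bmi, sex, age, cutoffs)
    denom <- sum(wc != "underweight")
    if (denom == 0) return(0)
    sum(wc %in% c("overweight", "obesity")) / denom
  }
  lo <- -4; hi <- 4
  for (iter in 1:50) {
    mid <- (lo + hi) / 2
    f <- frac_at(mid)
    if (abs(f - target) <= 0.02) return(mid)
    if (f < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset '%s': %d probes x %d samples, ancestry %s\n",
              x$cohort_id, nrow(x$betas), ncol(x$betas), x$ancestry))
  invisible(x)
}

#' Cohort-level summary table for subsetting rules
#'
#' Tabulates per-cohort ancestry, overweight/obesity fraction (after
#' excluding underweight), and the selection flag; the input expected by
#' `run_meta(subset_rule = ...)`.
#'
#' @param cohorts list of `cohort_dataset` objects.
#' @param cutoffs IOTF cutoff table.
#' @return a data.frame with one row per cohort.
#' @export
cohort_summary <- function(cohorts, cutoffs = ewas_iotf_cutoffs()) {
  do.call(rbind, lapply(cohorts, function(ch) {
    ov <- overweight_fraction(ch$samples, cutoffs)
    data.frame(cohort_id = ch$cohort_id, n = nrow(ch$samples),
               ancestry = ch$ancestry,
               overweight_fraction = ov$fraction,
               selection_flag = ch$selection_flag,
               stringsAsFactors = FALSE)
  }))
}

#' Write / read one cohort as plain-text files
#'
#' The beta matrix is written tab-separated with the probe id in the first
#' column (`probe_id`), sample ids as the remaining column names, and `NA`
#' as the missing-value token. The sample sheet is comma-separated with a
#' header; columns are matched by name on read, so column order does not
#' matter. When a manifest is supplied, the slice covering the cohort's
#' probes is written alongside.
#'
#' @param dataset a `cohort_dataset`.
#' @param directory output directory (created if needed).
#' @param manifest optional probe manifest to slice and write.
#' @return (invisibly) the named vector of file paths written.
#' @export
write_cohort <- function(dataset, directory, manifest = NULL) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  base <- file.path(directory, dataset$cohort_id)
  paths <- c(betas = paste0(base, "_betas.tsv"),
             samples = paste0(base, "_samples.csv"))
  bdf <- data.frame(probe_id = rownames(dataset$betas), dataset$betas,
                    check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(bdf, paths["betas"], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    utils::write.csv(dataset$samples, paths["samples"], row.names = FALSE,
                     na = "NA")
    TRUE
  }, error = function(e)
    stop("failed to write cohort files under ", directory, ": ",
         conditionMessage(e)))
  if (!is.null(manifest)) {
    paths["manifest"] <- paste0(base, "_manifest.csv")
    slice <- manifest[manifest$cpg_id %in% rownames(dataset$betas), ,
                      drop = FALSE]
    utils::write.csv(slice, paths["manifest"], row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param cohort_id the cohort id used when the files were written.
#' @return `read_cohort` returns the reconstructed `cohort_dataset`.
#' @export
read_cohort <- function(directory, cohort_id) {
  base <- file.path(directory, cohort_id)
  bdf <- utils::read.delim(paste0(base, "_betas.tsv"), check.names = FALSE,
                           stringsAsFactors = FALSE)
  betas <- as.matrix(bdf[, -1, drop = FALSE])
  rownames(betas) <- bdf$probe_id
  samples <- utils::read.csv(paste0(base, "_samples.csv"),
                             stringsAsFactors = FALSE)
  if (!is.null(samples$sample_id)) {
    idx <- match(colnames(betas), samples$sample_id)
    if (any(is.na(idx)))
      stop("sample ids in the beta matrix and sample sheet disagree")
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(cohort_id = cohort_id, betas = betas, samples = samples,
                 ancestry = samples$ancestry[1] %||% NA_character_,
                 selection_flag = samples$selection_flag[1] %||% NA),
            class = "cohort_dataset")
}
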