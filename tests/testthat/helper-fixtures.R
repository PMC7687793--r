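# Shared fixtures. The expensive simulation runs are computed once per test
# session and reused by the calibration and acceptance tests.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A flat toy LMS reference: constant parameters over age so the analytic
# LMS formula can be checked directly against hand computation.
flat_lms <- function(L, M, S, ages = c(2, 18)) {
  rbind(data.frame(sex = "F", age_years = ages, L = L, M = M, S = S),
        data.frame(sex = "M", age_years = ages, L = L, M = M, S = S))
}

flat_cutoffs <- function(under = 14, over = 18, obese = 21, ages = c(2, 18)) {
  rbind(data.frame(sex = "F", age_years = ages, bmi_underweight = under,
                   bmi_overweight = over, bmi_obesity = obese),
        data.frame(sex = "M", age_years = ages, bmi_underweight = under,
                   bmi_overweight = over, bmi_obesity = obese))
}

# independent per-value oracle for the 3*IQR rule: quartiles by linear
# interpolation between order statistics, each value checked against the
# fences directly
iqr_oracle <- function(v, mult = 3) {
  obs <- sort(v[!is.na(v)])
  n <- length(obs)
  interp_q <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    obs[lo] + (h - lo) * (obs[min(lo + 1, n)] - obs[lo])
  }
  q1 <- interp_q(0.25); q3 <- interp_q(0.75)
  iqr <- q3 - q1
  ifelse(!is.na(v) & (v < q1 - mult * iqr | v > q3 + mult * iqr), NA_real_, v)
}

toy_manifest <- function(n, chr = "1", pos = NULL) {
  data.frame(cpg_id = sprintf("cg%08d", seq_len(n)),
             chr = rep(chr, length.out = n),
             pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
             gene = paste0("G", seq_len(n)),
             flag_snp = 0L, flag_indel = 0L, flag_repeat = 0L,
             flag_cross_reactive = 0L, stringsAsFactors = FALSE)
}

# Null-pipeline run at the calibration problem size: 3 cohorts x 300
# samples, 5000 probes, no probe-BMI dependence.
null_calibration_run <- function() {
  cached("null_run", {
    cfg <- sim_config(master_seed = 20260101, n_cohorts = 3,
                      samples_per_cohort = rep(300L, 3), n_probes = 5000)
    cohorts <- generate_consortium(cfg)
    res <- do.call(rbind, lapply(cohorts, run_cohort_ewas,
                                 spec = model_spec("A")))
    meta <- run_meta(res)
    list(results = res, meta = meta)
  })
}

# Parameter-recovery run: planted methylation -> BMI effects of 2.0
# BMI-SDS per unit beta at 8 probes, pooled n = 2000.
recovery_run <- function() {
  cached("recovery_run", {
    planted <- c(5L, 17L, 42L, 61L, 88L, 103L, 140L, 171L)
    cfg <- sim_config(master_seed = 4021, n_cohorts = 4,
                      samples_per_cohort = rep(500L, 4), n_probes = 200,
                      causal_mode = "meth_to_bmi", planted_probes = planted,
                      planted_effects = rep(2.0, length(planted)))
    cohorts <- generate_consortium(cfg)
    res <- do.call(rbind, lapply(cohorts, run_cohort_ewas,
                                 spec = model_spec("A")))
    meta <- run_meta(res)
    list(meta = meta, planted_ids = sprintf("cg%08d", planted),
         truth = 2.0)
  })
}

# Reverse-causation runs across three age windows with an age-increasing
# effect schedule at a 50-CpG "adult" set. The planted CpGs get
# intermediate methylation means (adult-BMI CpGs are typically mid-range
# and variable) and small logit-scale effects, so the estimated effect is
# proportional to the planted one rather than saturating.
age_trend_runs <- function() {
  cached("age_trend", {
    set.seed(909)
    adult_eff <- stats::rnorm(50, 0, 0.15)
    planted <- 1:50
    mu <- stats::rnorm(800, 0, 1.5)
    mu[planted] <- stats::rnorm(50, 0, 0.4)
    windows <- list(early = c(2, 5), late = c(5, 10), adolescent = c(14, 18))
    prior <- prior_cpg_set(sprintf("cg%08d", planted), effects = adult_eff,
                           source_label = "adult_synthetic")
    runs <- lapply(windows, function(w) {
      cfg <- sim_config(master_seed = 5150, n_cohorts = 3,
                        samples_per_cohort = rep(200L, 3), n_probes = 800,
                        age_window = w, causal_mode = "bmi_to_meth",
                        planted_probes = planted,
                        planted_effects = adult_eff,
                        probe_mean_logit = mu,
                        age_effect_schedule = c(-2 / 14, 1 / 14))
      cohorts <- generate_consortium(cfg)
      res <- do.call(rbind, lapply(cohorts, run_cohort_ewas,
                                   spec = model_spec("C")))
      meta <- run_meta(res)
      er <- enrichment_report(meta, prior, cutoffs = 0.05)
      idx <- match(prior$cpg_ids, meta$cpg_id)
      ec <- effect_correlation(adult_eff, meta$beta[idx])
      list(enrich_p = er$p_upper, r = ec$r)
    })
    runs
  })
}
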