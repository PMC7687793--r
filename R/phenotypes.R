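#' LMS growth-reference utilities and weight-status phenotypes
#'
#' BMI in children is standardized against a sex- and age-specific growth
#' reference using the LMS method: at each sex and age the reference stores a
#' Box-Cox power (L), the median BMI (M, kg/m^2) and a coefficient of
#' variation (S). The standard-deviation score of an observed BMI y is
#' \deqn{z = ((y/M)^L - 1) / (L S)}
#' with the logarithmic limit \eqn{z = \log(y/M)/S} when L is (numerically)
#' zero. Parameters are interpolated linearly in age within sex.
#'
#' @name lms
NULL

LMS_L_EPS <- 1e-8

#' Read an LMS growth reference table
#'
#' Expects a comma-separated file with header columns `sex`, `age_years`,
#' `L`, `M`, `S`. Ages must be strictly increasing within each sex, M and S
#' strictly positive, and both sexes present.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` with columns `sex`, `age_years`, `L`, `M`, `S`.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lms_reference(ref)
}

validate_lms_reference <- function(ref) {
  needed <- c("sex", "age_years", "L", "M", "S")
  missing_cols <- setdiff(needed, names(ref))
  if (length(missing_cols) > 0)
    stop("LMS reference is missing columns: ", paste(missing_cols, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop("LMS reference requires M > 0 and S > 0")
  if (length(unique(ref$sex)) < 2)
    stop("LMS reference must contain both sexes")
  for (s in unique(ref$sex)) {
    ages <- ref$age_years[ref$sex == s]
    if (any(diff(ages) <= 0))
      stop("LMS reference ages must be strictly increasing within sex ", s)
  }
  ref[, needed]
}

#' Read an IOTF-style BMI cutoff table
#'
#' Comma-separated with header columns `sex`, `age_years`,
#' `bmi_underweight`, `bmi_overweight`, `bmi_obesity` (kg/m^2). Cutoffs must
#' be ordered underweight < overweight < obesity on every row.
#'
#' @param path path to a CSV file.
#' @return a `data.frame` of cutoffs.
#' @export
read_iotf_cutoffs <- function(path) {
  cut <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_iotf_cutoffs(cut)
}

validate_iotf_cutoffs <- function(cut) {
  needed <- c("sex", "age_years", "bmi_underweight", "bmi_overweight", "bmi_obesity")
  missing_cols <- setdiff(needed, names(cut))
  if (length(missing_cols) > 0)
    stop("IOTF cutoff table is missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- cut$bmi_underweight >= cut$bmi_overweight | cut$bmi_overweight >= cut$bmi_obesity
  if (any(bad))
    stop("IOTF cutoffs must satisfy underweight < overweight < obesity on every row")
  cut[, needed]
}

#' Packaged synthetic LMS reference and IOTF cutoffs
#'
#' A coarse synthetic growth reference (ages 2-18 years, both sexes) shipped
#' with the package so that the simulator and the tests run without any
#' external growth-reference download. It is *not* the British 1990 reference
#' nor the published IOTF coefficients; real references can be supplied via
#' [read_lms_reference()] / [read_iotf_cutoffs()].
#'
#' @return a `data.frame` (LMS reference or IOTF cutoff table).
#' @export
ewas_lms_reference <- function() {
  read_lms_reference(system.file("extdata", "lms_reference_synthetic.csv",
                                 package = "ewasmeta", mustWork = TRUE))
}

#' @rdname ewas_lms_reference
#' @export
ewas_iotf_cutoffs <- function() {
  read_iotf_cutoffs(system.file("extdata", "iotf_cutoffs_synthetic.csv",
                                package = "ewasmeta", mustWork = TRUE))
}

# Linearly interpolate reference columns in age at one sex; errors outside
# the tabulated age range (no extrapolation).
interp_reference <- function(ref, sex, age, cols) {
  out <- matrix(NA_real_, length(age), length(cols),
                dimnames = list(NULL, cols))
  for (s in unique(sex)) {
    sub <- ref[ref$sex == s, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("sex '", s, "' absent from reference table")
    idx <- sex == s
    a <- age[idx]
    if (any(a < min(sub$age_years) | a > max(sub$age_years)))
      stop("age outside reference range [", min(sub$age_years), ", ",
           max(sub$age_years), "] for sex ", s)
    for (cl in cols)
      out[idx, cl] <- stats::approx(sub$age_years, sub[[cl]], xout = a,
                                    method = "linear", ties = "ordered")$y
  }
  out
}

#' BMI standard-deviation score via the LMS transform
#'
#' @param bmi numeric vector of BMI values, kg/m^2, all > 0.
#' @param sex vector of sex labels matching the reference (`"F"`/`"M"`).
#' @param age numeric vector of ages in years, inside the reference range.
#' @param ref LMS reference (see [read_lms_reference()]).
#' @return numeric vector of BMI-SDS values.
#' @seealso [lms_inverse()] for the inverse transform.
#' @export
lms_zscore <- function(bmi, sex, age, ref = ewas_lms_reference()) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop("bmi must be finite and > 0")
  ref <- validate_lms_reference(ref)
  prm <- interp_reference(ref, sex, age, c("L", "M", "S"))
  L <- prm[, "L"]; M <- prm[, "M"]; S <- prm[, "S"]
  z <- ifelse(abs(L) < LMS_L_EPS,
              log(bmi / M) / S,
              ((bmi / M)^L - 1) / (L * S))
  as.numeric(z)
}

#' Inverse LMS transform: BMI-SDS back to raw BMI
#'
#' @param z numeric vector of BMI-SDS values.
#' @inheritParams lms_zscore
#' @return numeric vector of BMI values in kg/m^2.
#' @export
lms_inverse <- function(z, sex, age, ref = ewas_lms_reference()) {
  ref <- validate_lms_reference(ref)
  prm <- interp_reference(ref, sex, age, c("L", "M", "S"))
  L <- prm[, "L"]; M <- prm[, "M"]; S <- prm[, "S"]
  base <- 1 + L * S * z
  bmi <- ifelse(abs(L) < LMS_L_EPS,
                M * exp(S * z),
                M * ifelse(base > 0, base^(1 / L), NA_real_))
  as.numeric(bmi)
}

#' Classify weight status against IOTF-style cutoffs
#'
#' Cutoffs are interpolated linearly in age. A BMI exactly equal to a cutoff
#' is assigned to the (heavier) category that the cutoff names.
#'
#' @inheritParams lms_zscore
#' @param cutoffs IOTF cutoff table (see [read_iotf_cutoffs()]).
#' @return factor with levels `underweight`, `normal`, `overweight`, `obesity`.
#' @export
iotf_classify <- function(bmi, sex, age, cutoffs = ewas_iotf_cutoffs()) {
  cutoffs <- validate_iotf_cutoffs(cutoffs)
  cc <- interp_reference(cutoffs, sex, age,
                         c("bmi_underweight", "bmi_overweight", "bmi_obesity"))
  cls <- ifelse(bmi >= cc[, "bmi_obesity"], "obesity",
         ifelse(bmi >= cc[, "bmi_overweight"], "overweight",
         ifelse(bmi >= cc[, "bmi_underweight"], "normal", "underweight")))
  factor(cls, levels = c("underweight", "normal", "overweight", "obesity"))
}

#' Dichotomize puberty status from Tanner stages
#'
#' Early puberty requires both the breast/genital and the pubic-hair Tanner
#' stage to be 1, 2 or 3 *and* no menarche (girls) / voice change (boys);
#' any stage of 4 or 5, or menarche/voice change, classifies as late.
#'
#' @param tanner_breast_or_genital integer vector, stages 1-5.
#' @param tanner_pubic integer vector, stages 1-5.
#' @param menarche_or_voice logical vector.
#' @return factor with levels `early`, `late`.
#' @export
categorize_puberty <- function(tanner_breast_or_genital, tanner_pubic,
                               menarche_or_voice) {
  stages <- c(tanner_breast_or_genital, tanner_pubic)
  if (any(!stages %in% 1:5))
    stop("Tanner stages must be integers in 1-5")
  early <- tanner_breast_or_genital <= 3 & tanner_pubic <= 3 &
    !as.logical(menarche_or_voice)
  factor(ifelse(early, "early", "late"), levels = c("early", "late"))
}

#' Build the overweight/obesity case-control assignment for one cohort
#'
#' Cases are overweight or obese children, controls are normal weight;
#' underweight children are excluded. A cohort with 10 or fewer participants
#' in either group is marked ineligible for the binary analysis.
#'
#' @param samples data.frame with columns `bmi_kg_m2`, `sex`, `age_years`
#'   (or a precomputed `weight_class` column).
#' @param cutoffs IOTF cutoff table.
#' @param min_group_size minimum group size; the strict threshold is
#'   `> min_group_size` (default 10, so 11 cases / 11 controls is eligible).
#' @return a list with `assignment` (factor `case`/`control`, `NA` for
#'   excluded underweight), `n_cases`, `n_controls`, and `eligible`.
#' @export
build_case_control <- function(samples, cutoffs = ewas_iotf_cutoffs(),
                               min_group_size = 10) {
  wc <- samples$weight_class
  if (is.null(wc))
    wc <- iotf_classify(samples$bmi_kg_m2, samples$sex, samples$age_years, cutoffs)
  assignment <- factor(ifelse(wc %in% c("overweight", "obesity"), "case",
                       ifelse(wc == "normal", "control", NA)),
                       levels = c("control", "case"))
  n_cases <- sum(assignment == "case", na.rm = TRUE)
  n_controls <- sum(assignment == "control", na.rm = TRUE)
  list(assignment = assignment, n_cases = n_cases, n_controls = n_controls,
       eligible = min(n_cases, n_controls) > min_group_size)
}

#' Fraction of overweight/obese children after excluding underweight
#'
#' @inheritParams build_case_control
#' @param flag_threshold cohorts with a fraction strictly above this value
#'   are flagged (default 0.30).
#' @return a list with `fraction` and logical `flagged`.
#' @export
overweight_fraction <- function(samples, cutoffs = ewas_iotf_cutoffs(),
                                flag_threshold = 0.30) {
  wc <- samples$weight_class
  if (is.null(wc))
    wc <- iotf_classify(samples$bmi_kg_m2, samples$sex, samples$age_years, cutoffs)
  denom <- sum(wc != "underweight")
  if (denom == 0)
    stop("overweight fraction undefined: no non-underweight samples")
  frac <- sum(wc %in% c("overweight", "obesity")) / denom
  list(fraction = frac, flagged = frac > flag_threshold)
}

#' Select the measurement time point for one subject
#'
#' Picks the oldest age within the analysis window at which both BMI and
#' DNA methylation were measured; the window is inclusive at both ends.
#'
#' @param timepoints data.frame with columns `age`, `bmi_available`,
#'   `meth_available`.
#' @param window numeric length-2, `(min_age, max_age)` in years.
#' @return the chosen age, or `NA` when no time point qualifies.
#' @export
select_measurement <- function(timepoints, window) {
  ok <- timepoints$age >= window[1] & timepoints$age <= window[2] &
    as.logical(timepoints$bmi_available) & as.logical(timepoints$meth_available)
  if (!any(ok)) return(NA_real_)
  max(timepoints$age[ok])
}

#' Derive analysis phenotypes for a sample sheet
#'
#' Adds `bmi_sds` (LMS z-score), `weight_class` (IOTF category) and, when
#' Tanner columns are present, `puberty` to a cohort sample sheet.
#'
#' @param samples cohort sample sheet (one row per child).
#' @param lms_ref LMS reference table.
#' @param cutoffs IOTF cutoff table.
#' @return `samples` with phenotype columns appended.
#' @export
prepare_phenotypes <- function(samples, lms_ref = ewas_lms_reference(),
                               cutoffs = ewas_iotf_cutoffs()) {
  samples$bmi_sds <- lms_zscore(samples$bmi_kg_m2, samples$sex,
                                samples$age_years, lms_ref)
  samples$weight_class <- iotf_classify(samples$bmi_kg_m2, samples$sex,
                                        samples$age_years, cutoffs)
  if (all(c("tanner_breast_or_genital", "tanner_pubic", "menarche_or_voice")
          %in% names(samples))) {
    samples$puberty <- categorize_puberty(samples$tanner_breast_or_genital,
                                          samples$tanner_pubic,
                                          samples$menarche_or_voice)
  }
  samples
}
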