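---
title: "Meta-analysis of epigenome-wide association studies of childhood BMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of epigenome-wide association studies of childhood BMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewasmeta)
```

## The analysis problem

Consortium EWAS of childhood adiposity ask whether DNA methylation measured
in cord or whole blood is associated with body-mass index (BMI) across
childhood and adolescence. No individual-level data are shared: each cohort
fits the same pre-specified per-CpG regression locally and contributes only
summary statistics (effect estimate, standard error, sample size per CpG),
which a coordinating center pools. `ewasmeta` implements both sides of that
workflow plus a synthetic-data generator with known ground truth, so the
entire pipeline can be validated end to end without any participant data.

The pipeline stages are:

1. **Phenotypes** — raw BMI is transformed to sex- and age-standardized
   SD scores with the LMS method; IOTF-style cutoffs classify weight status
   for the secondary case-control analysis.
2. **Methylation QC** — per-CpG extreme beta values outside
   `[Q1 − 3·IQR, Q3 + 3·IQR]` are set to missing; probes on X/Y, probes
   measured in only one study and cross-reactive probes are excluded;
   SNP/INDEL/repeat probes are retained but flagged.
3. **Cohort EWAS** — Huber robust linear regression of BMI-SDS on each
   CpG's beta value with the model's covariate set; logistic regression
   for overweight/obesity vs normal weight.
4. **Meta-analysis** — fixed-effects inverse-variance pooling with
   Cochran's Q and I², leave-one-out diagnostics, Bonferroni and
   Benjamini–Hochberg control, per-10%-methylation reporting.
5. **Prior comparison** — look-up replication, hypergeometric enrichment,
   and effect-estimate correlation against published CpG sets.
6. **Annotation windows** — ±5 kb CpG neighborhoods and ±2 Mb GWAS-locus
   proximity queries over the probe manifest.

## Models and their statistics

### LMS standardization

At each sex and age the growth reference stores a Box–Cox power $L$, the
median BMI $M$ and a coefficient of variation $S$, interpolated linearly in
age. For observed BMI $y$,

$$ z = \frac{(y/M)^L - 1}{L\,S}, \qquad z = \frac{\log(y/M)}{S} \;\text{when}\; |L| < 10^{-8}. $$

Linear age interpolation is the package's choice; growth-reference software
does not agree on a single convention and the differences are negligible on
a yearly grid. The transform is strictly increasing in BMI and inverts
exactly, which the tests verify to $10^{-9}$ across
$L \in [-3, 3]$, $S \in (0, 0.3]$. The packaged reference
(`ewas_lms_reference()`) is **synthetic** — a smooth, plausible surface over
ages 2–18 for both sexes with an adiposity-rebound dip near age 5 — so the
package is self-contained; real references are supplied by file. The
packaged IOTF-style cutoffs are derived from the same synthetic surface at
fixed z-values (−1.7, 1.1, 2.0), giving realistic overweight (~14%) and
obesity (~2%) prevalences under a standard-normal BMI-SDS distribution. A
BMI exactly at a cutoff goes to the heavier category the cutoff names — a
deterministic, documented tie rule. Age windows are inclusive at both ends;
the analysis window is a configuration parameter, not hard-coded, because
verbal age ranges ("2–5 years") are ambiguous at the boundary.

### Robust regression

The continuous-outcome model is Huber M-estimation (tuning constant 1.345,
95% Gaussian efficiency), residual scale re-estimated each iteration by the
normalized MAD, standard errors from the asymptotic M-estimator covariance
— the default behavior of `MASS::rlm`, which performs the fit. Convergence
is declared at a coefficient-change tolerance of $10^{-8}$ within 50
iterations; non-converging probes are recorded and excluded from pooling.
Two degenerate cases are handled explicitly: rank-deficient designs are
skipped with a reason code, and an exactly collinear (zero-residual) fit —
which collapses the MAD scale to zero — reports its exact coefficient with
a missing SE so it can never enter the pooled analysis with spurious
weight. Complete cases are determined once per model (any missing covariate
drops the row for all probes); beta-value missingness then varies per
probe, so per-probe sample sizes differ after the IQR filter.

### Quantile convention in the outlier filter

The 3·IQR rule needs a quartile definition; the package uses linear
interpolation between the closest order statistics (`quantile` type 7, the
common statistical default) and exposes the type as an argument so other
dialects can be matched. Quartiles are computed once on the input, not
iterated. Outliers become missing values rather than dropping the sample,
mirroring per-CpG trimming practice in consortium pipelines, and the filter
is applied per cohort before modeling. Fewer than four observed values
leave the CpG untouched with a warning.

### Fixed-effects pooling and heterogeneity

With per-study estimates $(\beta_i, se_i)$ and weights $w_i = 1/se_i^2$:

$$ \hat\beta = \frac{\sum w_i \beta_i}{\sum w_i}, \quad
   se(\hat\beta) = \Big(\sum w_i\Big)^{-1/2}, \quad
   Q = \sum w_i (\beta_i - \hat\beta)^2, \quad
   I^2 = \max\!\Big(0, 100\,\frac{Q - (k-1)}{Q}\Big). $$

P values use the standard-normal tail of $z = \hat\beta/se$, the
inverse-variance convention. Heterogeneity is flagged strictly above
$I^2 = 50$. Effects are estimated on the native beta scale (0–1) within
cohorts and rescaled to "per 10% methylation" (×0.1) only at reporting, so
cohort files stay on one consistent scale and the z statistic is
unaffected. Probes reaching fewer than two cohorts are excluded before
pooling; single-cohort mode exists only for unit tests. FDR adjustment runs
over exactly the analyzed probe set of the model at hand, so $m$ differs
between models and between sensitivity subsets (the probe universe is
recomputed after cohort subsetting). Reporting ties in P are broken by CpG
id.

### Enrichment and correlation against prior sets

Enrichment of a published $K$-CpG set among the top $n$ of $N$ analyzed
probes with overlap $k$ is the exact hypergeometric upper tail
$P(X \ge k)$ via `phyper` — no normal approximation; the tests check it
against brute-force combinatorial summation for $N \le 60$. The universe
$N$ defaults to the analyzed-probe count of the model being compared, and
$K$ defaults to the full published set size (with an option to restrict to
the intersection), the combination consistent with published enrichment
tables. Effect correlations use Pearson's $r$ with the $t$-distribution P
value on $n-2$ degrees of freedom; comparisons of two correlations use the
Fisher r-to-z transformation,
$z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$.
Set-overlap tests use the Pearson chi-square on the 2×2 membership table
without continuity correction by default (a correction flag exists).

## The synthetic consortium

`sim_config()` / `generate_consortium()` emulate the features of real
consortium data that drive the analysis:

- **Beta values** are Gaussian on the logit scale (probe-specific means
  drawn from N(0, 1.5), within-probe SD 1.0 by default) and inverse-logit
  transformed, preserving [0, 1] and the U-shaped marginal typical of
  450K arrays without extra parameters.
- **Cell proportions** come from a fixed-concentration Dirichlet
  (B cells 6, CD4+ 12, CD8+ 8, granulocytes 45, monocytes 6, NK 4 —
  roughly whole-blood-like) and enter the models as covariates; one
  component is dropped from designs to avoid exact collinearity.
  Reference-based deconvolution itself is out of scope.
- **Covariates** match the consortium adjustment sets (maternal age,
  education, smoking, BMI, parity, gestational age, birth weight,
  breastfeeding, child smoking, Tanner stages, batch); a configurable
  subset of them genuinely shifts BMI-SDS (defaults: maternal BMI +0.25
  SDS per SD, maternal smoking +0.15, breastfeeding −0.10, male sex
  +0.05), so adjustment matters.
- **Batch** shifts logit-betas by +0.1 for the second batch, giving the
  batch covariate real work.
- **Overweight prevalence** per cohort is tuned by bisection on the
  cohort's BMI-SDS intercept until the IOTF-classified fraction is within
  ±2% of target, enabling the ">30% overweight" sensitivity path.
- **Seeding**: per-cohort sub-seeds derive from the master seed by a fixed
  linear congruential mix with the cohort index, so adding a cohort never
  perturbs earlier cohorts; probe-level parameters use a reserved index.
- **Missingness** is injected completely at random at a configurable rate
  (default 0).

Under `meth_to_bmi`, planted probes add
`effect × (beta − probe mean)` to the BMI-SDS linear predictor before the
LMS back-transform to raw BMI, so a downstream EWAS estimates exactly the
planted slope. Under `bmi_to_meth`, logit-beta at planted probes gains
`age_multiplier(age) × effect × BMI-SDS`, emulating methylation that
responds to adiposity increasingly with age.

What the generator does **not** emulate: probe type (I/II) chemistry,
normalization artifacts, genetic (mQTL) structure, realistic
linkage/correlation between neighboring CpGs, non-Gaussian covariate
dependence, or cohort-specific array batches beyond a two-level shift.
Passing calibration tests on these data therefore demonstrates the
statistical machinery is correct under the stated generative model — not
that real-data confounding is fully handled.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle (closed
forms, brute-force enumeration, naive reference implementations, permutation
tests) and then exercises the full pipeline at deliberately moderate sizes
chosen to keep the whole suite to a few minutes while leaving the
statistical conclusions stable:

- **Null calibration**: 3 cohorts × 300 children × 5,000 probes, no
  probe–BMI dependence. Expected: genomic inflation factor
  $\lambda \in [0.9, 1.1]$, per-CpG type-I error within [0.04, 0.06] at
  the 0.05 level, and uniform P values (Kolmogorov–Smirnov).
- **Effect recovery**: 4 cohorts × 500 children, eight planted probes at
  2.0 BMI-SDS per unit beta; pooled estimates must land within 3 SE
  per probe and within 10% systematic bias on average.
- **Age trend**: the reverse-causation mode plants a 50-CpG "adult" set
  (effects drawn N(0, 0.15) on the logit scale) whose influence scales
  with age as $\max(0, (\text{age} - 2)/14)$ — essentially zero in early
  childhood, full strength by late adolescence, mirroring the idea that
  methylation differences accumulate with exposure to higher BMI. Across
  the three age windows (2–5, 5–10, 14–18 years; 3 cohorts × 200 each,
  800 probes), enrichment −log10 P of the planted set among nominal hits
  and the correlation between estimated and planted effects must both be
  non-decreasing. Two design choices keep the trend identifiable rather
  than an artifact of tuning. First, the effect scale is small: large
  planted effects saturate the regression (the estimated slope stops
  being proportional to the planted effect once the planted term
  dominates the methylation variance), which compresses the correlation
  at the oldest ages. Second, the planted CpGs get intermediate
  methylation means (logit means N(0, 0.4) instead of the genome-wide
  N(0, 1.5)): beta-scale regression slopes scale inversely with the
  probe's $p(1-p)$ variance factor, so a set of planted probes with
  widely varying means caps the achievable correlation with the
  logit-scale planted effects well below 1. Mid-range means match what
  is known of adult BMI-associated CpGs, which sit at variable,
  intermediate methylation levels. Both quantities were confirmed to be
  monotone across several independent master seeds under these
  conditions.

One published quantity could not be reproduced exactly from printed
numbers: the t-test P values for the effect correlations at the two oldest
ages derive from unrounded correlation coefficients, so the package's
values from the 3-decimal printed r differ in the second significant
figure; the acceptance test asserts both values fall inside the interval
that rounding of r implies. Similarly, a published 2×2 overlap test on
enriched CpG sets is not recoverable from its printed marginals under any
standard chi-square variant; the operation is implemented per its
definition and that single printed value is not used as a target.

## A worked example

```{r example, eval = FALSE}
library(ewasmeta)

cfg <- sim_config(master_seed = 11, n_cohorts = 4,
                  samples_per_cohort = rep(500L, 4), n_probes = 200,
                  causal_mode = "meth_to_bmi",
                  planted_probes = c(5L, 17L, 42L),
                  planted_effects = rep(2.0, 3))
cohorts <- generate_consortium(cfg)
manifest <- make_manifest(200, seed = 11)

pcfg <- pipeline_config(cohorts = cohorts, manifest = manifest,
                        models = "A")
out <- run_pipeline(pcfg)
head(out$meta$A)       # pooled effects per 10% methylation, FDR, I2, ...
out$lambda$A           # per-cohort and pooled inflation factors
```

## Known limitations

- The robust-regression SE is the asymptotic M-estimator covariance;
  cohorts in real consortia sometimes use sandwich variants, which can
  shift SEs by a few percent at small n.
- The simulator's cohorts are exchangeable draws; real between-study
  heterogeneity (platform, ancestry-specific LD with mQTLs, age
  composition) is richer, so I² behavior on real data is not fully
  represented.
- Case-control analyses require both groups with more than 10 members per
  cohort; small simulated cohorts often fail this by construction, as do
  small real ones.
- EPIC-array support, DMR calling, cell-type deconvolution and external
  annotation retrieval are out of scope.
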