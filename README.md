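# ewasmeta

Consortium-style meta-analysis of epigenome-wide association studies
(EWAS) of child and adolescent body-mass index, with a synthetic
multi-cohort data generator for end-to-end validation.

## Who this is for

Epigenetic epidemiologists running (or simulating) a distributed EWAS: each
cohort regresses a phenotype on DNA methylation locally and shares only
per-CpG summary statistics; a coordinating center pools them. `ewasmeta`
implements both sides — the per-cohort models and the central meta-analysis
with all its diagnostics — plus the phenotype standardization, probe-level
quality control, comparison against previously published CpG sets, and a
ground-truth simulator so every stage is testable without any participant
data.

## The statistics at its core

- **BMI standardization (LMS).** BMI `y` at a given sex/age maps to an SD
  score `z = ((y/M)^L − 1)/(L·S)` (log-limit when `L ≈ 0`), with L, M, S
  interpolated in age from a growth reference; IOTF-style age/sex cutoffs
  classify underweight / normal / overweight / obesity.
- **Per-cohort EWAS.** Huber robust linear regression (tuning constant
  1.345, MAD scale, asymptotic SEs) of BMI-SDS on each CpG's beta value
  with the model's covariate set; logistic regression for
  overweight/obesity vs normal weight.
- **Per-CpG QC.** Beta values outside `[Q1 − 3·IQR, Q3 + 3·IQR]` become
  missing; X/Y, single-study, and cross-reactive probes are excluded;
  SNP/INDEL/repeat probes are flagged, never silently dropped.
- **Fixed-effects inverse-variance pooling.** Weights `w_i = 1/se_i²`,
  pooled effect `Σw_iβ_i/Σw_i`, SE `(Σw_i)^(−1/2)`, normal-tail P values;
  Cochran's Q and `I² = max(0, 100(Q−(k−1))/Q)` with heterogeneity flagged
  strictly above 50; leave-one-out re-pooling; Bonferroni (`0.05/m`) and
  Benjamini–Hochberg control; effects reported per 10% methylation.
- **Prior-set comparison.** Per-study Bonferroni look-up replication,
  exact hypergeometric enrichment of published CpG sets among top hits,
  Pearson correlation of effect estimates with t-based P values, and
  Fisher r-to-z comparison of correlations across age ranges.
- **Genomic windows.** ±5 kb CpG neighborhoods and ±2 Mb GWAS-locus
  proximity queries over the probe manifest.

## Worked example

Simulate a four-cohort consortium with three planted methylation→BMI
effects of 2.0 BMI-SDS per unit beta, run the full pipeline, and look at
the pooled results:

```r
library(ewasmeta)

cfg <- sim_config(master_seed = 11, n_cohorts = 4,
                  samples_per_cohort = rep(500L, 4), n_probes = 200,
                  causal_mode = "meth_to_bmi",
                  planted_probes = c(5L, 17L, 42L),
                  planted_effects = rep(2.0, 3))
cohorts <- generate_consortium(cfg)
manifest <- make_manifest(200, seed = 11)

out <- run_pipeline(pipeline_config(cohorts = cohorts, manifest = manifest,
                                    models = "A"))
head(out$meta$A, 3)[, c("cpg_id", "beta", "se", "p", "p_fdr", "bonferroni")]
#>       cpg_id       beta         se            p        p_fdr bonferroni
#> 1 cg00000017 0.21669238 0.03997351 5.930001e-08 0.0000113856       TRUE
#> 2 cg00000042 0.21535397 0.05827360 2.193971e-04 0.0210621204       TRUE
#> 3 cg00000084 0.04531551 0.01576680 4.051693e-03 0.2593083714      FALSE
out$lambda$A["pooled"]
#>   pooled
#> 1.048348
```

Two of the three planted probes top the table as Bonferroni-significant
hits (the threshold is `0.05/191 ≈ 2.6e-4` for the 191 analyzed probes).
The `beta` column is on the per-10%-methylation reporting scale, so the
planted per-unit effect of 2.0 corresponds to 0.20 — both estimates land
within one standard error of it. The third planted probe, `cg00000005`,
was placed on chromosome X by this manifest seed and is therefore excluded
by the probe filter before pooling — exactly what the QC stage is supposed
to do (`out$probe_filter$excluded` records it with reason
`xy_chromosome`). The pooled genomic inflation factor stays near 1 because
only a few probes carry signal.

Cohorts can also run standalone from a shell via the bundled CLI
(`system.file("cli", "ewasmeta-cli.R", package = "ewasmeta")`), which
exposes `simulate`, `ewas`, `meta` and `enrich` subcommands over the
plain-text file formats (tab-separated beta matrices, CSV sample sheets,
METAL-style meta output).

## Scope notes

GWAS-loci files are single-position, 1-based, tab-separated `(chr, pos)`
records — note this differs from BED's 0-based half-open convention.
Cell-type deconvolution, cohort-level normalization, EPIC arrays,
GO/KEGG enrichment against external databases, and Mendelian randomization
are out of scope. See the methods vignette
(`vignettes/ewas-meta-analysis.Rmd`) for the model details, simulator
design, and known limitations.
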