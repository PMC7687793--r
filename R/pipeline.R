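#' Configure a full pipeline run
#'
#' Bundles inputs, model selections, subset rules and thresholds for
#' [run_pipeline()]. Inputs are either in-memory `cohort_dataset` objects
#' or a directory of files written by [write_cohort()].
#'
#' @param cohorts list of `cohort_dataset` objects, or `NULL` when reading
#'   from `cohort_dir`.
#' @param cohort_dir directory containing `<id>_betas.tsv` /
#'   `<id>_samples.csv` pairs.
#' @param cohort_ids cohort ids to read from `cohort_dir` (default: all
#'   `*_betas.tsv` found).
#' @param manifest probe manifest (data.frame or path to a manifest CSV).
#' @param models character vector of model ids to run (see [model_spec()]).
#' @param subset_rule optional sensitivity subset applied before pooling:
#'   `"europeans_only"`, `"max_overweight_30pct"`, or `"conservative"`.
#' @param priors optional list of [prior_cpg_set()] objects for the
#'   comparison stage.
#' @param lms_ref,cutoffs growth reference and IOTF cutoff tables (objects
#'   or file paths).
#' @param iqr_multiplier fence multiplier for the per-CpG outlier filter.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param top_cutoffs P-value cutoffs for the enrichment top lists.
#' @param min_studies minimum cohorts per probe.
#' @param out_dir optional output directory; when set, result tables are
#'   written as tab-separated files with provenance headers.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = NULL, cohort_dir = NULL,
                            cohort_ids = NULL, manifest,
                            models = c("A"), subset_rule = NULL,
                            priors = NULL,
                            lms_ref = ewas_lms_reference(),
                            cutoffs = ewas_iotf_cutoffs(),
                            iqr_multiplier = 3, alpha = 0.05,
                            top_cutoffs = c(1e-5, 0.05), min_studies = 2,
                            out_dir = NULL) {
  if (is.null(cohorts) && is.null(cohort_dir))
    stop("pipeline_config requires cohorts or cohort_dir")
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    manifest <- read_manifest(manifest)
  } else manifest <- validate_manifest(manifest)
  if (is.character(lms_ref)) lms_ref <- read_lms_reference(lms_ref)
  if (is.character(cutoffs)) cutoffs <- read_iotf_cutoffs(cutoffs)
  bad <- setdiff(models, c("A", "B", "C", "D", "case_control"))
  if (length(bad) > 0) stop("unknown model id(s): ", paste(bad, collapse = ", "))
  structure(list(cohorts = cohorts, cohort_dir = cohort_dir,
                 cohort_ids = cohort_ids, manifest = manifest,
                 models = models, subset_rule = subset_rule, priors = priors,
                 lms_ref = lms_ref, cutoffs = cutoffs,
                 iqr_multiplier = iqr_multiplier, alpha = alpha,
                 top_cutoffs = top_cutoffs, min_studies = min_studies,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full EWAS meta-analysis pipeline
#'
#' Executes, for each selected model: beta-matrix validation, per-cohort
#' 3*IQR outlier filtering, probe exclusion/flagging, per-cohort EWAS,
#' fixed-effects inverse-variance meta-analysis with heterogeneity and
#' multiple-testing control, genomic inflation factors, and (when prior
#' sets are supplied) the enrichment comparison. Reruns with an identical
#' configuration and inputs reproduce identical result tables.
#'
#' @param config a [pipeline_config()].
#' @return a list with `meta` (named list of meta-result tables, one per
#'   model), `cohort_results`, `lambda` (per model, per cohort and pooled),
#'   `probe_filter`, `enrichment` (per model, when priors given),
#'   `cohort_info`, and `exclusion_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohorts <- config$cohorts
  if (is.null(cohorts)) {
    ids <- config$cohort_ids
    if (is.null(ids)) {
      found <- list.files(config$cohort_dir, pattern = "_betas\\.tsv$")
      ids <- sub("_betas\\.tsv$", "", found)
    }
    if (length(ids) == 0) stop("no cohort files found in ", config$cohort_dir)
    cohorts <- lapply(ids, function(id) read_cohort(config$cohort_dir, id))
  }

  log <- list()
  # per-cohort QC: range validation then the 3*IQR extreme-value filter
  for (i in seq_along(cohorts)) {
    validate_betas(cohorts[[i]]$betas)
    filt <- apply_iqr_filter(cohorts[[i]]$betas,
                             multiplier = config$iqr_multiplier)
    cohorts[[i]]$betas <- filt$betas
    removed <- filt$n_removed[filt$n_removed > 0]
    if (length(removed) > 0)
      log[[length(log) + 1]] <- data.frame(
        stage = "iqr_filter", cohort_id = cohorts[[i]]$cohort_id,
        cpg_id = names(removed), reason = "outlier_removed",
        count = as.integer(removed), stringsAsFactors = FALSE)
  }

  presence <- table(unlist(lapply(cohorts, function(ch) {
    keep <- rowSums(!is.na(ch$betas)) > 0
    rownames(ch$betas)[keep]
  })))
  presence <- stats::setNames(as.integer(presence), names(presence))
  pf <- filter_probes(config$manifest, presence,
                      min_studies = config$min_studies)
  if (nrow(pf$excluded) > 0)
    log[[length(log) + 1]] <- data.frame(
      stage = "filter_probes", cohort_id = NA_character_,
      cpg_id = pf$excluded$cpg_id, reason = pf$excluded$reason, count = 1L,
      stringsAsFactors = FALSE)

  cohort_info <- cohort_summary(cohorts, config$cutoffs)
  out <- list(meta = list(), cohort_results = list(), lambda = list(),
              enrichment = list(), probe_filter = pf,
              cohort_info = cohort_info)

  for (model_id in config$models) {
    spec <- model_spec(model_id)
    res <- do.call(rbind, lapply(cohorts, function(ch)
      run_cohort_ewas(ch, spec, probes = pf$retained,
                      lms_ref = config$lms_ref, cutoffs = config$cutoffs)))
    meta <- run_meta(res, probe_set = pf$retained,
                     min_studies = config$min_studies,
                     subset_rule = config$subset_rule,
                     cohort_info = cohort_info,
                     alpha = config$alpha, flags = pf$flags)
    lam <- c(vapply(split(res$p[res$converged], res$cohort_id[res$converged]),
                    genomic_lambda, numeric(1)),
             pooled = genomic_lambda(meta$p))
    out$cohort_results[[model_id]] <- res
    out$meta[[model_id]] <- meta
    out$lambda[[model_id]] <- lam
    if (!is.null(config$priors))
      out$enrichment[[model_id]] <-
        enrichment_report(meta, config$priors, cutoffs = config$top_cutoffs)
  }
  out$exclusion_log <- if (length(log)) do.call(rbind, log) else
    data.frame(stage = character(0), cohort_id = character(0),
               cpg_id = character(0), reason = character(0),
               count = integer(0), stringsAsFactors = FALSE)

  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

config_digest <- function(config) {
  slim <- config[setdiff(names(config), c("cohorts", "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(slim, tmp)
  unname(tools::md5sum(tmp))
}

write_table_with_header <- function(df, path, digest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ewasmeta ", as.character(utils::packageVersion("ewasmeta"))),
    paste0("# config_digest=", digest),
    paste0("# generated=", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  digest <- config_digest(config)
  for (model_id in names(out$meta)) {
    meta <- out$meta[[model_id]]
    metal <- data.frame(
      MarkerName = meta$cpg_id, Effect = meta$beta, StdErr = meta$se,
      Zscore = meta$z, P = meta$p, FDR_P = meta$p_fdr,
      Direction = meta$direction, HetQ = meta$Q, HetISq = meta$i2,
      K_Studies = meta$k_studies, Total_N = meta$total_n,
      Flags = meta$flags, stringsAsFactors = FALSE)
    write_table_with_header(
      metal, file.path(config$out_dir, paste0("meta_", model_id, ".tsv")),
      digest)
    write_table_with_header(
      manhattan_data(meta, config$manifest),
      file.path(config$out_dir, paste0("manhattan_", model_id, ".tsv")),
      digest)
    write_table_with_header(
      volcano_data(meta),
      file.path(config$out_dir, paste0("volcano_", model_id, ".tsv")),
      digest)
    if (!is.null(out$enrichment[[model_id]]))
      write_table_with_header(
        out$enrichment[[model_id]],
        file.path(config$out_dir, paste0("enrichment_", model_id, ".tsv")),
        digest)
  }
  write_table_with_header(out$exclusion_log,
                          file.path(config$out_dir, "exclusion_log.tsv"),
                          digest)
  invisible(NULL)
}

#' Write one cohort's EWAS result file
#'
#' Tab-separated with a header comment line documenting the encoding,
#' then columns `cpg_id`, `beta`, `se`, `n`, `converged` (effects per unit
#' beta; the per-10% rescaling happens at meta-analysis reporting).
#'
#' @param results one cohort's results from [run_cohort_ewas()].
#' @param path output file path.
#' @export
write_cohort_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ewasmeta cohort EWAS results; effects are BMI-SDS ",
                    "(or log-odds) per unit methylation beta; ",
                    "robust fit: Huber M-estimation, k=1.345, MAD scale"), con)
  utils::write.table(results[, c("cpg_id", "beta", "se", "n", "converged")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_cohort_results
#' @param cohort_id cohort id to attach to the rows read back.
#' @export
read_cohort_results <- function(path, cohort_id) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$cohort_id <- cohort_id
  df[, c("cohort_id", "cpg_id", "beta", "se", "n", "converged")]
}
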