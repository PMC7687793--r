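#' Per-CpG extreme-value filter (3 IQR rule)
#'
#' Removes methylation beta values below `Q1 - 3*IQR` or above `Q3 + 3*IQR`,
#' where the quartiles are computed once on the input values (not iterated)
#' by linear interpolation between the closest order statistics
#' (`stats::quantile` type 7). Removed values become missing so the sample
#' is retained for other CpGs.
#'
#' @param values numeric vector of beta values for one CpG across samples;
#'   missing values allowed.
#' @param multiplier IQR multiplier defining the fence (default 3).
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between closest order statistics).
#' @return a list with `values` (filtered vector, outliers set to `NA`),
#'   `n_removed`, and the `bounds` used.
#' @export
iqr_filter <- function(values, multiplier = 3, quantile_type = 7) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) {
    warning("fewer than 4 non-missing values; CpG skipped, no removal")
    return(list(values = values, n_removed = 0L, bounds = c(NA_real_, NA_real_)))
  }
  q <- stats::quantile(obs, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - multiplier * iqr, q[2] + multiplier * iqr)
  out <- !is.na(values) & (values < bounds[1] | values > bounds[2])
  values[out] <- NA_real_
  list(values = values, n_removed = sum(out), bounds = bounds)
}

#' Apply the 3 IQR filter to every row of a beta matrix
#'
#' @param betas numeric matrix, CpGs in rows, samples in columns.
#' @inheritParams iqr_filter
#' @return a list with `betas` (filtered matrix) and `n_removed`
#'   (integer vector, per CpG).
#' @export
apply_iqr_filter <- function(betas, multiplier = 3, quantile_type = 7) {
  n_removed <- integer(nrow(betas))
  names(n_removed) <- rownames(betas)
  for (i in seq_len(nrow(betas))) {
    v <- betas[i, ]
    obs <- v[!is.na(v)]
    if (length(obs) < 4) next  # silently skipped here; reported by validate_betas
    q <- stats::quantile(obs, c(0.25, 0.75), type = quantile_type, names = FALSE)
    iqr <- q[2] - q[1]
    out <- !is.na(v) & (v < q[1] - multiplier * iqr | v > q[2] + multiplier * iqr)
    if (any(out)) {
      betas[i, out] <- NA_real_
      n_removed[i] <- sum(out)
    }
  }
  list(betas = betas, n_removed = n_removed)
}

#' Read a probe manifest
#'
#' Comma-separated with header: `cpg_id`, `chr`, `pos` (1-based), `gene`,
#' and 0/1 flag columns `flag_snp`, `flag_indel`, `flag_repeat`,
#' `flag_cross_reactive`.
#'
#' @param path path to a manifest CSV.
#' @return a `data.frame` with one row per probe.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(chr = "character"))
  validate_manifest(man)
}

validate_manifest <- function(man) {
  needed <- c("cpg_id", "chr", "pos", "gene", "flag_snp", "flag_indel",
              "flag_repeat", "flag_cross_reactive")
  missing_cols <- setdiff(needed, names(man))
  if (length(missing_cols) > 0)
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(man$cpg_id)) stop("manifest cpg_id values must be unique")
  if (any(man$pos < 1)) stop("manifest positions must be >= 1 (1-based)")
  man
}

#' Build the analysis probe set with exclusions and flags
#'
#' Excluded outright: probes measured in at most one study, probes on the X
#' or Y chromosome, and cross-reactive probes. Probes overlapping a SNP,
#' INDEL or repeat element are retained but flagged so the flags propagate
#' into result files. Probes present in the data but absent from the
#' manifest are retained with an `unannotated` flag and a warning.
#'
#' @param manifest probe manifest (see [read_manifest()]).
#' @param presence named integer vector: number of studies in which each
#'   CpG was measured (names are CpG ids).
#' @param min_studies minimum study count to retain a probe (default 2).
#' @return a list with `retained` (character vector of CpG ids), `excluded`
#'   (data.frame `cpg_id`, `reason`), and `flags` (data.frame `cpg_id`,
#'   `flags` comma-separated, only flagged probes).
#' @export
filter_probes <- function(manifest, presence, min_studies = 2) {
  manifest <- validate_manifest(manifest)
  ids <- names(presence)
  if (is.null(ids)) stop("presence must be a named vector of study counts")
  m <- manifest[match(ids, manifest$cpg_id), , drop = FALSE]
  unannotated <- is.na(m$cpg_id)
  if (any(unannotated))
    warning(sum(unannotated), " probe(s) absent from the manifest; retained with flag 'unannotated'")

  reason <- rep(NA_character_, length(ids))
  reason[presence < min_studies] <- "single_study"
  on_xy <- !unannotated & m$chr %in% c("X", "Y")
  reason[is.na(reason) & on_xy] <- "xy_chromosome"
  crossr <- !unannotated & m$flag_cross_reactive == 1
  reason[is.na(reason) & crossr] <- "cross_reactive"

  keep <- is.na(reason)
  flags <- character(length(ids))
  add_flag <- function(flags, cond, label)
    ifelse(cond, ifelse(flags == "", label, paste(flags, label, sep = ",")), flags)
  flags <- add_flag(flags, !unannotated & m$flag_snp == 1, "snp")
  flags <- add_flag(flags, !unannotated & m$flag_indel == 1, "indel")
  flags <- add_flag(flags, !unannotated & m$flag_repeat == 1, "repeat")
  flags <- add_flag(flags, unannotated, "unannotated")

  list(
    retained = ids[keep],
    excluded = data.frame(cpg_id = ids[!keep], reason = reason[!keep],
                          stringsAsFactors = FALSE),
    flags = data.frame(cpg_id = ids[keep & flags != ""],
                       flags = flags[keep & flags != ""],
                       stringsAsFactors = FALSE)
  )
}

#' Validate a beta matrix and report missingness
#'
#' Asserts that all non-missing values lie in \[0, 1\] (an out-of-range
#' value is an error naming the probe and sample) and reports missingness
#' per probe and per sample. All-missing probes are reported, not fatal.
#'
#' @param betas numeric matrix, CpGs in rows, samples in columns.
#' @return a list with `probe_missing` and `sample_missing` (named counts)
#'   and `all_missing_probes` (character vector).
#' @export
validate_betas <- function(betas) {
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("beta value out of [0,1] at probe ",
         rownames(betas)[bad[1, 1]] %||% bad[1, 1], ", sample ",
         colnames(betas)[bad[1, 2]] %||% bad[1, 2])
  }
  probe_missing <- rowSums(is.na(betas))
  sample_missing <- colSums(is.na(betas))
  list(probe_missing = probe_missing,
       sample_missing = sample_missing,
       all_missing_probes = rownames(betas)[probe_missing == ncol(betas)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
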