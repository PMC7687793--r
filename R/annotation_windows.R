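#' CpGs within a genomic window around a position
#'
#' Returns all manifest probes on the same chromosome whose position lies
#' within `half_width` base pairs of the center (bounds inclusive at
#' exactly +/- half_width), excluding the center probe itself, sorted by
#' position. Coordinates are 1-based, as in array manifests.
#'
#' @param manifest probe manifest (see [read_manifest()]).
#' @param cpg_id center the window on this probe; alternatively give
#'   `chr` and `pos` directly.
#' @param chr,pos explicit window center (ignored when `cpg_id` is given).
#' @param half_width window half-width in bp (default 5000, i.e. a 10-kb
#'   window).
#' @return manifest rows of the neighbors, with a `distance` column (bp).
#' @export
cpg_neighbors <- function(manifest, cpg_id = NULL, chr = NULL, pos = NULL,
                          half_width = 5000) {
  if (half_width <= 0) stop("half_width must be > 0")
  exclude <- NULL
  if (!is.null(cpg_id)) {
    row <- manifest[manifest$cpg_id == cpg_id, , drop = FALSE]
    if (nrow(row) == 0) stop("cpg_id '", cpg_id, "' not in manifest")
    chr <- row$chr[1]; pos <- row$pos[1]; exclude <- cpg_id
  }
  hits <- manifest[manifest$chr == chr &
                     abs(manifest$pos - pos) <= half_width, , drop = FALSE]
  if (!is.null(exclude))
    hits <- hits[hits$cpg_id != exclude, , drop = FALSE]
  if (nrow(hits) == 0 && !chr %in% manifest$chr)
    warning("chromosome '", chr, "' not present in manifest")
  hits$distance <- abs(hits$pos - pos)
  hits <- hits[order(hits$pos), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Proximity of CpGs to known GWAS loci
#'
#' Tests whether each CpG lies within `half_width` bp of any same-
#' chromosome locus (default 2 Mb, i.e. a 4-Mb window). Loci files are
#' BED-like tab-separated `(chrom, pos)` records but with 1-based single
#' positions, matching the manifest convention rather than BED's 0-based
#' half-open intervals.
#'
#' @param manifest probe manifest rows for the CpGs of interest.
#' @param loci data.frame with columns `chr` and `pos` (1-based).
#' @param half_width window half-width in bp (default 2e6).
#' @return a data.frame with `cpg_id`, `near_locus` (logical), and
#'   `nearest_distance` (bp; `Inf` when no same-chromosome locus exists).
#' @export
near_gwas_loci <- function(manifest, loci, half_width = 2e6) {
  if (nrow(loci) == 0) stop("loci must be non-empty")
  nearest <- vapply(seq_len(nrow(manifest)), function(i) {
    same <- loci$chr == manifest$chr[i]
    if (!any(same)) return(Inf)
    min(abs(loci$pos[same] - manifest$pos[i]))
  }, numeric(1))
  data.frame(cpg_id = manifest$cpg_id,
             near_locus = nearest <= half_width,
             nearest_distance = nearest,
             stringsAsFactors = FALSE)
}

#' Summarize meta-analysis results for the neighbors of a CpG
#'
#' Counts the CpGs within the window around a center CpG, how many are
#' nominally associated (P strictly below `alpha`), and the fraction whose
#' effect sign agrees with the center's.
#'
#' @param cpg_id center CpG (must be present in `meta`).
#' @param meta a meta-result table from [run_meta()].
#' @param manifest probe manifest.
#' @param half_width window half-width in bp (default 5000).
#' @param alpha nominal significance level (default 0.05, strict `<`).
#' @return a list with `n_neighbors`, `n_nominal`, `sign_agreement`
#'   (fraction, `NA` when there are no neighbors with results).
#' @export
nominal_neighbor_summary <- function(cpg_id, meta, manifest,
                                     half_width = 5000, alpha = 0.05) {
  center <- meta[meta$cpg_id == cpg_id, , drop = FALSE]
  if (nrow(center) == 0) stop("center CpG absent from the meta table")
  nb <- cpg_neighbors(manifest, cpg_id = cpg_id, half_width = half_width)
  idx <- match(nb$cpg_id, meta$cpg_id)
  present <- !is.na(idx)
  n_neighbors <- sum(present)
  if (n_neighbors == 0)
    return(list(n_neighbors = 0L, n_nominal = 0L, sign_agreement = NA_real_))
  p <- meta$p[idx[present]]
  eff <- meta$beta[idx[present]]
  list(n_neighbors = n_neighbors,
       n_nominal = sum(p < alpha),
       sign_agreement = mean(sign(eff) == sign(center$beta)))
}
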