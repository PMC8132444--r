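#' Filter cells on sequencing quality metrics
#'
#' Removes cells that fail any of four QC rules: too few total reads, low
#' mapping rate, too few detected genes, or an excessive intergenic fraction.
#' These mirror the metrics reported by RNA-SeQC-style tools; the package only
#' consumes the table, it does not compute the metrics.
#'
#' @param qc data frame with columns `cell_id`, `total_reads`, `mapping_rate`,
#'   `detected_genes`, `intergenic_fraction` (see [read_qc_table()]).
#' @param min_total_reads minimum total read count (default 3e5).
#' @param min_mapping_rate minimum mapping rate in `[0, 1]` (default 0.5).
#' @param min_detected_genes minimum number of detected genes (default 2000).
#' @param max_intergenic_fraction maximum intergenic fraction (default 0.3).
#' @return A list with `kept` (cell ids passing all rules, input order) and
#'   `removed` (data frame of removed cells with the first failing rule).
#' @examples
#' qc <- data.frame(cell_id = c("a", "b"),
#'                  total_reads = c(1e6, 2.5e5), mapping_rate = c(0.9, 0.9),
#'                  detected_genes = c(5000, 5000),
#'                  intergenic_fraction = c(0.1, 0.1))
#' filter_cells_by_qc(qc)$kept
#' @export
filter_cells_by_qc <- function(qc, min_total_reads = 3e5,
                               min_mapping_rate = 0.5,
                               min_detected_genes = 2000,
                               max_intergenic_fraction = 0.3) {
  if (!is.data.frame(qc) || nrow(qc) == 0)
    stop("QC table is empty")
  id <- as.character(qc$cell_id)
  if (anyDuplicated(id))
    stop("duplicate cell_id in QC table: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(qc$total_reads < 0) || any(qc$detected_genes < 0))
    stop("counts must be nonnegative")
  if (any(qc$mapping_rate < 0 | qc$mapping_rate > 1) ||
      any(qc$intergenic_fraction < 0 | qc$intergenic_fraction > 1))
    stop("rates must lie in [0, 1]")
  # first failing rule, in the order the rules are stated
  rule <- rep(NA_character_, nrow(qc))
  rule[is.na(rule) & qc$total_reads < min_total_reads] <- "total_reads"
  rule[is.na(rule) & qc$mapping_rate < min_mapping_rate] <- "mapping_rate"
  rule[is.na(rule) & qc$detected_genes < min_detected_genes] <- "detected_genes"
  rule[is.na(rule) & qc$intergenic_fraction > max_intergenic_fraction] <- "intergenic_fraction"
  drop <- !is.na(rule)
  list(kept = id[!drop],
       removed = data.frame(cell_id = id[drop], rule = rule[drop],
                            stringsAsFactors = FALSE))
}

#' Threshold, log-transform and filter genes
#'
#' The gene-level preprocessing applied to a raw TPM matrix:
#' values below `min_tpm` are regarded as unreliable and set to 0, every
#' value is then replaced by `log2(value + 1)`, and genes detected (nonzero)
#' in fewer than `min_expressed_fraction` of the cells are discarded.
#'
#' @param expr an `expr_matrix` at stage `"raw_tpm"`.
#' @param min_tpm TPM detection threshold (default 1).
#' @param min_expressed_fraction minimum fraction of cells in which a gene must
#'   be detected to be kept (default 0.10).
#' @return A list with `expr` (stage `"log2_tpm1"`, kept genes in input order)
#'   and `dropped_genes` (character vector).
#' @export
filter_and_transform_genes <- function(expr, min_tpm = 1,
                                       min_expressed_fraction = 0.10) {
  expr <- as_expr_matrix(expr, stage = "raw_tpm")
  if (expr_stage(expr) != "raw_tpm")
    stop("expected stage 'raw_tpm', got '", expr_stage(expr), "'")
  v <- unclass(expr)
  if (any(v < 0)) stop("negative expression values in raw TPM matrix")
  v[v < min_tpm] <- 0
  v <- log2(v + 1)
  frac <- rowMeans(v > 0)
  keep <- frac >= min_expressed_fraction
  if (!any(keep))
    stop("all genes dropped; lower min_tpm or min_expressed_fraction")
  list(expr = expression_matrix(v[keep, , drop = FALSE], stage = "log2_tpm1"),
       dropped_genes = rownames(v)[!keep])
}

#' Center and variance-scale genes
#'
#' Each gene row is centered by its mean across cells and divided by its
#' sample variance (denominator `n - 1`); `scale = "sd"` divides by the
#' standard deviation instead, giving conventional z-scores. Genes with zero
#' variance are removed (their rank correlation contribution is undefined)
#' and reported.
#'
#' @param expr an `expr_matrix` at stage `"log2_tpm1"`.
#' @param scale `"variance"` (default) or `"sd"`.
#' @return A list with `expr` (stage `"normalized"`) and `zero_variance_genes`.
#' @export
normalize_genes <- function(expr, scale = c("variance", "sd")) {
  scale <- match.arg(scale)
  expr <- as_expr_matrix(expr, stage = "log2_tpm1")
  if (expr_stage(expr) != "log2_tpm1")
    stop("expected stage 'log2_tpm1', got '", expr_stage(expr), "'")
  if (ncol(expr) < 2) stop("normalization needs at least 2 cells")
  v <- unclass(expr)
  mu <- rowMeans(v)
  va <- apply(v, 1L, stats::var)
  zero <- va == 0
  v <- v[!zero, , drop = FALSE]
  if (nrow(v) == 0) stop("all genes have zero variance")
  denom <- if (scale == "variance") va[!zero] else sqrt(va[!zero])
  v <- (v - mu[!zero]) / denom
  list(expr = expression_matrix(v, stage = "normalized"),
       zero_variance_genes = names(va)[zero])
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: cell QC filtering (skipped with a message when no QC
#' table is supplied — processed public datasets typically arrive
#' pre-filtered), TPM thresholding + `log2(x + 1)`, the gene detection-rate
#' filter, and per-gene normalization.
#'
#' @param expr an `expr_matrix` at stage `"raw_tpm"`.
#' @param qc optional QC data frame (see [filter_cells_by_qc()]).
#' @param min_tpm,min_expressed_fraction see [filter_and_transform_genes()].
#' @param scale see [normalize_genes()].
#' @param ... further arguments passed to [filter_cells_by_qc()].
#' @return A list with `expr` (stage `"normalized"`), `removed_cells`,
#'   `dropped_genes` and `zero_variance_genes`.
#' @export
preprocess <- function(expr, qc = NULL, min_tpm = 1,
                       min_expressed_fraction = 0.10,
                       scale = "variance", ...) {
  expr <- as_expr_matrix(expr, stage = "raw_tpm")
  removed <- data.frame(cell_id = character(), rule = character())
  if (is.null(qc)) {
    message("no QC table supplied; skipping cell quality filtering")
  } else {
    flt <- filter_cells_by_qc(qc, ...)
    removed <- flt$removed
    keep <- colnames(expr) %in% flt$kept
    if (!any(keep)) stop("all cells removed by QC filtering")
    expr <- expr[, keep]
  }
  gt <- filter_and_transform_genes(expr, min_tpm = min_tpm,
                                   min_expressed_fraction = min_expressed_fraction)
  nm <- normalize_genes(gt$expr, scale = scale)
  list(expr = nm$expr, removed_cells = removed,
       dropped_genes = gt$dropped_genes,
       zero_variance_genes = nm$zero_variance_genes)
}
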