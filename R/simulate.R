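# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulate a planted-cluster single-cell expression matrix
#'
#' Generates a nonnegative genes x cells TPM-scale matrix with `k` planted
#' cell types, controllable mean within-type Spearman correlation and
#' (optionally negative) cross-type Spearman correlation, plus
#' expression-dependent dropout. The construction works on the log2 scale: each cluster receives a
#' gene-signature profile, the `k` profiles built with exact target pairwise
#' correlation `cross_corr / within_corr` through a deflated-mean factor
#' model (genes up in one type are pushed down in the others, which is what
#' induces negative cross-type rank correlation); each cell adds independent
#' Gaussian noise whose variance is set from `within_corr` using the Gaussian
#' rank-correlation relation `rho_pearson = 2 sin(pi * rho_spearman / 6)`.
#' The monotone map to the TPM scale preserves all ranks, so the targets
#' carry over before dropout. Dropout is expression-dependent, as in real
#' scRNA-seq: the zeroing probability decreases linearly with a gene's
#' within-cell expression percentile and averages `dropout_rate`, so mostly
#' low-expressed values are zeroed and the planted rank structure survives.
#'
#' The defaults are the reference study conditions used throughout the
#' package's tests: 3 balanced types of 150 cells over 500 genes, within-type
#' Spearman 0.6, cross-type -0.2, 30% dropout.
#'
#' @param n_cells number of cells (at least `2 * k`).
#' @param n_genes number of genes.
#' @param k number of planted cell types.
#' @param cluster_props length-`k` proportions summing to 1 (default equal).
#' @param within_corr target mean within-type Spearman, in `(0, 1)`.
#' @param cross_corr target mean cross-type Spearman, below `within_corr`;
#'   must satisfy `cross_corr / within_corr > -1 / (k - 1)` (the feasibility
#'   bound for `k` equicorrelated profiles) when `k > 1`.
#' @param dropout_rate mean per-cell zeroing probability in `[0, 1)`.
#' @param seed RNG seed; output is bit-identical for equal seeds.
#' @param base_log2_tpm,log2_spread location and scale of the log2 TPM
#'   marginal (defaults 4 and 2: median 16 TPM).
#' @return A list with `expr` (an [expression_matrix()] at stage
#'   `"raw_tpm"`) and `labels` (data frame `cell_id`, `label` of the planted
#'   types).
#' @examples
#' sim <- simulate_expression(n_cells = 30, n_genes = 100, k = 2, seed = 1)
#' table(sim$labels$label)
#' @export
simulate_expression <- function(n_cells = 150, n_genes = 500, k = 3,
                                cluster_props = rep(1 / k, k),
                                within_corr = 0.6, cross_corr = -0.2,
                                dropout_rate = 0.3, seed = 0,
                                base_log2_tpm = 4, log2_spread = 2) {
  if (within_corr <= 0 || within_corr >= 1)
    stop("within_corr must lie in (0, 1)")
  if (cross_corr >= within_corr)
    stop("cross_corr must be below within_corr")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (length(cluster_props) != k || abs(sum(cluster_props) - 1) > 1e-9)
    stop("cluster_props must have length k and sum to 1")
  if (n_cells < 2 * k) stop("need n_cells >= 2 * k")
  # Gaussian rank-correlation correction: target Spearman -> latent Pearson
  w_p <- 2 * sin(pi * within_corr / 6)
  b_p <- 2 * sin(pi * cross_corr / 6)
  r <- b_p / w_p                      # required profile-profile correlation
  if (k > 1 && r <= -1 / (k - 1) + 1e-12)
    stop("infeasible correlation targets: cross_corr too negative for k = ", k)

  sizes <- diff(round(cumsum(c(0, cluster_props)) * n_cells))
  sizes[k] <- n_cells - sum(sizes[-k])
  membership <- rep(seq_len(k), sizes)

  with_seed(seed, {
    e <- matrix(stats::rnorm(n_genes * k), n_genes, k)
    if (k > 1) {
      u <- r / (1 - r)
      lambda <- 1 - sqrt(1 + k * u)   # equicorrelated profiles, corr = r
      x <- (e - lambda * rowMeans(e)) / sqrt(1 + u)
    } else {
      x <- e
    }
    tau <- sqrt(w_p)
    sigma <- sqrt(1 - w_p)
    latent <- tau * x[, membership] +
      sigma * matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells)
    tpm <- 2^(base_log2_tpm + log2_spread * latent)
    if (dropout_rate > 0) {
      # expression-dependent dropout: the zeroing probability falls linearly
      # with the within-cell expression percentile (low-expressed genes drop
      # out most), averaging dropout_rate per cell
      pct <- apply(latent, 2L, function(col) rank(col) / (n_genes + 1))
      p_drop <- pmin(2 * dropout_rate * (1 - pct), 1)
      mask <- matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) >= p_drop
      tpm <- tpm * mask
    }
    cell_ids <- sprintf("cell%03d", seq_len(n_cells))
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    dimnames(tpm) <- list(gene_ids, cell_ids)
    list(expr = expression_matrix(tpm, stage = "raw_tpm"),
         labels = data.frame(cell_id = cell_ids,
                             label = paste0("type", membership),
                             stringsAsFactors = FALSE))
  })
}

#' Simulate a per-cell quality-control table
#'
#' Builds a QC table in which exactly `n_fail` cells violate exactly one QC
#' rule each (chosen uniformly at random) and every other cell passes all
#' rules with at least a 10% margin. Useful for exercising
#' [filter_cells_by_qc()] without real sequencing metrics.
#'
#' @param cell_ids character vector of cell identifiers.
#' @param n_fail number of failing cells (`<= length(cell_ids)`); failing
#'   cells are the first `n_fail` after a seeded shuffle.
#' @param min_total_reads,min_mapping_rate,min_detected_genes,max_intergenic_fraction
#'   thresholds the table is built against (defaults as in
#'   [filter_cells_by_qc()]).
#' @param seed RNG seed.
#' @return Data frame with columns `cell_id`, `total_reads`, `mapping_rate`,
#'   `detected_genes`, `intergenic_fraction`, in the input cell order.
#' @export
simulate_qc <- function(cell_ids, n_fail = 0, min_total_reads = 3e5,
                        min_mapping_rate = 0.5, min_detected_genes = 2000,
                        max_intergenic_fraction = 0.3, seed = 0) {
  n <- length(cell_ids)
  if (n_fail > n) stop("n_fail exceeds the number of cells")
  with_seed(seed, {
    # all-pass baseline, >= 10% margin on every rule
    qc <- data.frame(
      cell_id = as.character(cell_ids),
      total_reads = round(min_total_reads * stats::runif(n, 1.1, 4)),
      mapping_rate = pmin(stats::runif(n, min_mapping_rate * 1.1 + 0.05, 0.99), 0.99),
      detected_genes = round(min_detected_genes * stats::runif(n, 1.1, 3)),
      intergenic_fraction = stats::runif(n, 0.01, max_intergenic_fraction * 0.9),
      stringsAsFactors = FALSE)
    if (n_fail > 0) {
      fail_idx <- sample.int(n, n_fail)
      rule <- sample(c("total_reads", "mapping_rate", "detected_genes",
                       "intergenic_fraction"), n_fail, replace = TRUE)
      for (j in seq_len(n_fail)) {
        i <- fail_idx[j]
        switch(rule[j],
          total_reads = {qc$total_reads[i] <- round(min_total_reads * stats::runif(1, 0.2, 0.9))},
          mapping_rate = {qc$mapping_rate[i] <- min_mapping_rate * stats::runif(1, 0.3, 0.9)},
          detected_genes = {qc$detected_genes[i] <- round(min_detected_genes * stats::runif(1, 0.2, 0.9))},
          intergenic_fraction = {qc$intergenic_fraction[i] <-
            min(max_intergenic_fraction * stats::runif(1, 1.15, 2), 1)})
      }
    }
    qc
  })
}
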