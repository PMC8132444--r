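#' Improved spectral clustering of single cells
#'
#' Fits the signed-graph spectral clustering model to a preprocessed
#' genes x cells expression matrix: cell-cell Spearman correlations are split
#' into a top-`h` similarity graph S and a top-`q` dissimilarity graph DS,
#' fused into the signed incidence matrix `W = (1 - omega) S + omega DS`,
#' and the cells are embedded with the eigenvectors of the `k` algebraically
#' smallest eigenvalues of the generalized Laplacian `L' = D' - W`, then
#' partitioned by k-means. With `omega = 0` (or `dissimilarity = FALSE`) the
#' fit is conventional spectral clustering on the similarity graph alone.
#'
#' @param x an `expr_matrix` at stage `"normalized"` (see [preprocess()]), or
#'   a plain genes x cells numeric matrix assumed already normalized.
#' @param k number of clusters (the true cluster number, when known).
#' @param omega similarity/dissimilarity trade-off in `[0, 1]`; 0 = similarity
#'   only (conventional spectral clustering), 1 = dissimilarity only.
#' @param h width of the similar neighbourhood (top-h positive correlations).
#' @param q width of the dissimilar neighbourhood (top-q negative
#'   correlations); defaults to `h`.
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @param seed RNG seed for k-means (default 0).
#' @param restarts k-means restarts (default 50).
#' @param dissimilarity if `FALSE`, the dissimilarity graph is never built and
#'   the fit follows the conventional spectral clustering path (requires
#'   `omega = 0`).
#' @return An object of class `"isc"`: a list with `labels` (integer cluster
#'   per cell), `cell_ids`, `k`, `omega`, `h`, `q`, `embedding` (n x k
#'   feature matrix), `eigenvalues`, `W`, `objective` (k-means within-cluster
#'   sum of squares), `method`, `seed`, `restarts` and `call`.
#' @examples
#' sim <- simulate_expression(n_cells = 60, n_genes = 200, k = 2, seed = 1)
#' pp <- preprocess(sim$expr)
#' fit <- isc(pp$expr, k = 2, omega = 0.3, h = 10)
#' table(fit$labels, sim$labels$label)
#' @seealso [preprocess()], [isc_sweep()], [cluster_metrics()]
#' @export
isc <- function(x, k, omega = 0.4, h, q = h,
                method = c("spearman", "pearson"),
                seed = 0, restarts = 50, dissimilarity = TRUE) {
  method <- match.arg(method)
  if (missing(h)) stop("'h' (similar neighbourhood width) is required")
  if (!dissimilarity && omega != 0)
    stop("dissimilarity = FALSE requires omega = 0")
  rho <- pairwise_correlation(x, method = method)
  parts <- split_similarity_dissimilarity(rho)
  s <- build_similarity_matrix(parts$s, h)
  if (dissimilarity) {
    ds <- build_dissimilarity_matrix(parts$ds, q)
    w <- build_incidence_matrix(s, ds, omega)
  } else {
    w <- s
    attr(w, "omega") <- 0
    attr(w, "q") <- NA_integer_
  }
  lap <- build_generalized_laplacian(w)
  emb <- spectral_embed(lap, k)
  asg <- kmeans_assign(emb, k, seed = seed, restarts = restarts)
  structure(list(labels = asg$labels, cell_ids = asg$cell_ids,
                 k = as.integer(k), omega = omega, h = as.integer(h),
                 q = if (dissimilarity) as.integer(q) else NA_integer_,
                 embedding = unclass(emb),
                 eigenvalues = attr(emb, "eigenvalues"),
                 W = w, objective = asg$objective, method = method,
                 seed = seed, restarts = restarts, call = match.call()),
            class = "isc")
}

#' @export
print.isc <- function(x, ...) {
  cat("Improved spectral clustering fit\n")
  cat(sprintf("  %d cells, k = %d, omega = %s, h = %d, q = %s, %s correlation\n",
              length(x$labels), x$k, format(x$omega), x$h,
              ifelse(is.na(x$q), "-", x$q), x$method))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
summary.isc <- function(object, truth = NULL, ...) {
  nz <- sum(object$W != 0) / 2
  neg <- sum(object$W < 0) / 2
  res <- list(
    n = length(object$labels), k = object$k, omega = object$omega,
    h = object$h, q = object$q,
    cluster_sizes = as.integer(table(object$labels)),
    edges = nz, negative_edges = neg,
    eigenvalues = object$eigenvalues,
    objective = object$objective,
    metrics = if (!is.null(truth)) cluster_metrics(
      stats::setNames(object$labels, object$cell_ids), truth))
  class(res) <- "summary.isc"
  res
}

#' @export
print.summary.isc <- function(x, ...) {
  cat("Improved spectral clustering\n")
  cat(sprintf("  cells: %d   clusters: %d   omega: %s   h: %d   q: %s\n",
              x$n, x$k, format(x$omega), x$h, ifelse(is.na(x$q), "-", x$q)))
  cat(sprintf("  graph edges: %d (%d negative)\n", x$edges, x$negative_edges))
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("  smallest eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  cat("  k-means objective:", format(x$objective, digits = 6), "\n")
  if (!is.null(x$metrics))
    cat(sprintf("  purity %.4f  RI %.4f  ARI %.4f  NMI %.4f\n",
                x$metrics$purity, x$metrics$ri, x$metrics$ari, x$metrics$nmi))
  invisible(x)
}

#' Plot an improved spectral clustering fit
#'
#' Scatter of the cells in two embedding dimensions, coloured by assigned
#' cluster.
#'
#' @param x an `"isc"` fit.
#' @param dims which two embedding columns to show (default the two smallest
#'   nontrivial directions available).
#' @param ... passed to [graphics::plot()].
#' @export
plot.isc <- function(x, dims = NULL, ...) {
  emb <- x$embedding
  if (is.null(dims)) dims <- if (ncol(emb) >= 3) c(2L, 3L) else c(1L, min(2L, ncol(emb)))
  if (ncol(emb) == 1) emb <- cbind(emb, emb)
  pal <- grDevices::hcl.colors(x$k, "Dark 3")
  graphics::plot(emb[, dims[1]], emb[, dims[2]],
                 col = pal[x$labels], pch = 19,
                 xlab = sprintf("eigenvector %d", dims[1]),
                 ylab = sprintf("eigenvector %d", dims[2]),
                 main = sprintf("ISC embedding (omega = %s)", format(x$omega)), ...)
  graphics::legend("topright", legend = seq_len(x$k), col = pal, pch = 19,
                   title = "cluster", bty = "n")
  invisible(x)
}

#' Conventional spectral clustering
#'
#' The similarity-only path: identical to [isc()] with `omega = 0` but never
#' constructs the dissimilarity graph. Useful as the baseline the signed
#' variant is compared against.
#'
#' @inheritParams isc
#' @return An `"isc"` object with `omega = 0` and `q = NA`.
#' @export
conventional_sc <- function(x, k, h, method = "spearman",
                            seed = 0, restarts = 50) {
  isc(x, k = k, omega = 0, h = h, method = method, seed = seed,
      restarts = restarts, dissimilarity = FALSE)
}

#' Run one improved-spectral-clustering pipeline stage by stage
#'
#' Thin functional wrapper over [isc()] returning just the cluster
#' assignment, convenient inside sweeps.
#'
#' @inheritParams isc
#' @return An `isc_assignment` (see [kmeans_assign()]).
#' @export
run_isc <- function(x, k, omega, h, q = h, seed = 0, restarts = 50,
                    method = "spearman") {
  fit <- isc(x, k = k, omega = omega, h = h, q = q, method = method,
             seed = seed, restarts = restarts)
  structure(list(cell_ids = fit$cell_ids, labels = fit$labels, k = fit$k,
                 seed = seed, objective = fit$objective),
            class = "isc_assignment")
}
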