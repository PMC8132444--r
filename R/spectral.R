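#' Generalized graph Laplacian of a signed incidence matrix
#'
#' `L' = D' - W` where `D'` is the diagonal matrix of row sums of `W`. For a
#' nonnegative `W` this is the ordinary unnormalized graph Laplacian and is
#' positive semidefinite; with negative edges (`omega > 0`) `L'` can be
#' indefinite, which is why downstream eigenvalue selection is algebraic,
#' not by magnitude.
#'
#' @param w symmetric signed incidence matrix.
#' @param tol asymmetry tolerance (default 1e-12).
#' @return A symmetric matrix whose rows sum to 0, with the degree vector
#'   attached as attribute `"degree"`.
#' @export
build_generalized_laplacian <- function(w, tol = 1e-12) {
  w <- as.matrix(w)
  if (max(abs(w - t(w))) > tol)
    stop("incidence matrix is not symmetric (tolerance ", tol, ")")
  deg <- rowSums(w)
  lap <- diag(deg, nrow = nrow(w)) - w
  dimnames(lap) <- dimnames(w)
  attr(lap, "degree") <- deg
  lap
}

#' Spectral embedding from the smallest Laplacian eigenvalues
#'
#' Extracts the unit eigenvectors belonging to the `k` algebraically smallest
#' eigenvalues of the generalized Laplacian; row i of the returned matrix is
#' the k-dimensional feature vector of cell i. The columns are an orthonormal
#' minimizer of `tr(U' L U)` over n x k orthonormal frames. No row
#' normalization is applied, and the (near-)constant trivial eigenvector is
#' kept among the first k.
#'
#' @param lap generalized Laplacian from [build_generalized_laplacian()].
#' @param k number of feature dimensions, `1 <= k < n`.
#' @return n x k matrix of class `"isc_embedding"` with ascending
#'   `"eigenvalues"` attached as an attribute.
#' @export
spectral_embed <- function(lap, k) {
  lap <- as.matrix(lap)
  n <- nrow(lap)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  es <- eigen(lap, symmetric = TRUE)   # eigenvalues in decreasing order
  sel <- n:(n - k + 1)                 # smallest k, ascending after reversal
  vals <- es$values[sel]
  vecs <- es$vectors[, sel, drop = FALSE]
  rownames(vecs) <- rownames(lap)
  structure(vecs, eigenvalues = vals, class = c("isc_embedding", "matrix", "array"))
}

#' @export
print.isc_embedding <- function(x, ...) {
  cat(sprintf("<isc_embedding> %d cells x %d features\n", nrow(x), ncol(x)))
  cat("eigenvalues:", format(attr(x, "eigenvalues"), digits = 4), "\n")
  invisible(x)
}

#' Cluster embedded cells with k-means
#'
#' Runs `stats::kmeans` (squared-Euclidean objective) on the rows of the
#' embedding with `restarts` random initializations and keeps the best run.
#' Deterministic given `(seed, restarts)`.
#'
#' @param emb embedding matrix (cells in rows).
#' @param k number of clusters.
#' @param seed RNG seed (default 0).
#' @param restarts number of random restarts (default 50).
#' @return A list of class `"isc_assignment"` with `cell_ids`, integer
#'   `labels` in `1..k`, `k`, `seed` and the achieved within-cluster sum of
#'   squares `objective`.
#' @export
kmeans_assign <- function(emb, k, seed = 0, restarts = 50) {
  emb <- as.matrix(emb)
  n <- nrow(emb)
  if (k > n) stop("k must not exceed the number of cells")
  if (nrow(unique(emb)) < k)
    stop("embedding has fewer than k distinct rows")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (k == n) {
    # singleton optimum; stats::kmeans rejects centers == nrow
    km <- list(cluster = seq_len(n), tot.withinss = 0)
  } else {
    # individual Hartigan-Wong restarts on near-duplicate rows emit benign
    # Quick-TRANSfer/convergence warnings; the best-of-restarts result stands
    km <- withCallingHandlers(
      stats::kmeans(emb, centers = k, nstart = restarts, iter.max = 100),
      warning = function(w) {
        if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  labels <- as.integer(km$cluster)
  if (length(unique(labels)) < k)
    warning("empty cluster(s): ",
            paste(setdiff(seq_len(k), unique(labels)), collapse = ", "))
  ids <- rownames(emb)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(cell_ids = ids, labels = labels, k = as.integer(k),
                 seed = seed, objective = km$tot.withinss),
            class = "isc_assignment")
}

#' @export
print.isc_assignment <- function(x, ...) {
  cat(sprintf("<isc_assignment> %d cells in %d clusters (seed %s)\n",
              length(x$labels), x$k, format(x$seed)))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Write a cluster assignment as a label table
#' @param x an `isc_assignment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assignment <- function(x, path) {
  write_labels(x$cell_ids, x$labels, path)
}
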