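#' Pairwise rank correlation between cells
#'
#' Computes the cell-by-cell Spearman (or Pearson) correlation matrix across
#' all genes. Spearman uses average ranks for ties (midranks), which reduces
#' to the classical closed form `1 - 6*sum(d^2) / (m*(m^2 - 1))` on tie-free
#' data; ties are pervasive in scRNA-seq because of dropout zeros, so the
#' midrank form is the one computed.
#'
#' @param expr an `expr_matrix` at stage `"normalized"` (or any genes x cells
#'   numeric matrix).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A symmetric n x n correlation matrix with unit diagonal, cell ids
#'   as dimnames and a `method` attribute.
#' @examples
#' m <- matrix(rnorm(60), 6, 10)
#' rho <- pairwise_correlation(m)
#' @export
pairwise_correlation <- function(expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- if (inherits(expr, "expr_matrix")) unclass(expr) else as.matrix(expr)
  if (ncol(v) < 2) stop("need at least 2 cells")
  if (nrow(v) < 3) stop("need at least 3 genes")
  const <- apply(v, 2L, function(col) max(col) == min(col))
  if (any(const))
    stop("correlation undefined for constant cell column(s): ",
         paste(colnames(v)[const], collapse = ", "))
  rho <- stats::cor(v, method = method)
  rho <- (rho + t(rho)) / 2          # enforce exact symmetry
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  attr(rho, "method") <- method
  rho
}

#' Split a correlation matrix into similarity and dissimilarity parts
#'
#' Positive correlations become similarities, negative correlations become
#' (nonpositive) dissimilarities; zeros mean "irrelevant". Diagonals are
#' forced to 0 in both parts, so off the diagonal `s + ds` reconstructs the
#' correlation matrix.
#'
#' @param rho symmetric correlation matrix (see [pairwise_correlation()]).
#' @return A list with dense matrices `s` (entries `>= 0`) and `ds`
#'   (entries `<= 0`).
#' @export
split_similarity_dissimilarity <- function(rho) {
  rho <- as.matrix(rho)
  s <- rho * (rho > 0)
  ds <- rho * (rho < 0)
  diag(s) <- 0
  diag(ds) <- 0
  list(s = s, ds = ds)
}

# union-rule top-k sparsification shared by the similarity and dissimilarity
# builders. `better` orders candidate weights best-first; eligibility is
# strict (> 0 or < 0), ties broken by ascending cell index.
.topk_union <- function(dense, k, eligible, decreasing) {
  n <- ncol(dense)
  chosen <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    v <- dense[i, ]
    cand <- which(eligible(v))
    cand <- setdiff(cand, i)
    if (length(cand)) {
      ord <- if (decreasing) order(-v[cand], cand) else order(v[cand], cand)
      top <- cand[ord][seq_len(min(k, length(cand)))]
      chosen[i, top] <- TRUE
    }
  }
  mask <- chosen | t(chosen)
  out <- dense * mask
  diag(out) <- 0
  dimnames(out) <- dimnames(dense)
  out
}

#' Sparsify the similarity part to each cell's top-h neighbours
#'
#' Keeps `s(i, j)` iff cell j is among cell i's `h` largest positive
#' similarities or vice versa (union symmetrization). Only strictly positive
#' similarities are eligible neighbours; a cell with fewer than `h` positive
#' partners keeps all of them. Ties in a sorted list are broken by ascending
#' cell index.
#'
#' @param s_part dense nonnegative similarity part from
#'   [split_similarity_dissimilarity()].
#' @param h neighbourhood width, `1 <= h <= n - 1`.
#' @return Sparse (mostly zero) symmetric matrix with `h` attached as an
#'   attribute.
#' @export
build_similarity_matrix <- function(s_part, h) {
  s_part <- as.matrix(s_part)
  n <- ncol(s_part)
  if (h < 1 || h >= n) stop("h must satisfy 1 <= h <= n - 1")
  out <- .topk_union(s_part, as.integer(h), function(v) v > 0, decreasing = TRUE)
  attr(out, "h") <- as.integer(h)
  out
}

#' Sparsify the dissimilarity part to each cell's top-q neighbours
#'
#' Mirror of [build_similarity_matrix()]: dissimilarities are sorted
#' ascending (most negative first) and only strictly negative values are
#' eligible. `q = 0` returns the zero matrix.
#'
#' @param ds_part dense nonpositive dissimilarity part.
#' @param q neighbourhood width, `0 <= q <= n - 1`.
#' @return Sparse symmetric nonpositive matrix with `q` attached.
#' @export
build_dissimilarity_matrix <- function(ds_part, q) {
  ds_part <- as.matrix(ds_part)
  n <- ncol(ds_part)
  if (q < 0 || q >= n) stop("q must satisfy 0 <= q <= n - 1")
  out <- if (q == 0) {
    z <- array(0, dim(ds_part), dimnames = dimnames(ds_part))
    z
  } else {
    .topk_union(ds_part, as.integer(q), function(v) v < 0, decreasing = FALSE)
  }
  attr(out, "q") <- as.integer(q)
  out
}

#' Combine similarity and dissimilarity into the signed incidence matrix
#'
#' `W = (1 - omega) * S + omega * DS`. A positive entry marks a similar pair,
#' a negative entry a distant pair, zero an irrelevant pair. `omega = 0`
#' recovers the input of conventional spectral clustering; `omega = 1` uses
#' dissimilarities only.
#'
#' @param s sparse similarity matrix from [build_similarity_matrix()].
#' @param ds sparse dissimilarity matrix from [build_dissimilarity_matrix()].
#' @param omega trade-off parameter in `[0, 1]`.
#' @return Symmetric signed matrix with `omega`, `h`, `q` attributes.
#' @export
build_incidence_matrix <- function(s, ds, omega) {
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0 || omega > 1)
    stop("omega must be a single value in [0, 1]")
  if (!all(dim(s) == dim(ds))) stop("S and DS dimensions differ")
  w <- (1 - omega) * s + omega * ds
  diag(w) <- 0
  attr(w, "omega") <- omega
  attr(w, "h") <- attr(s, "h")
  attr(w, "q") <- attr(ds, "q")
  w
}

#' Export a signed affinity matrix as a weighted edge list
#'
#' Writes the strictly-upper-triangle nonzero entries as a 3-column TSV
#' (`cell_i`, `cell_j`, `weight`), or MatrixMarket coordinate format when
#' `path` ends in `.mtx`.
#'
#' @param w symmetric matrix (S, DS or W).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(w, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(as.matrix(unclass(w)), sparse = TRUE), path)
    return(invisible(path))
  }
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  ids <- colnames(w)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(w)))
  df <- data.frame(cell_i = ids[idx[, 1]], cell_j = ids[idx[, 2]],
                   weight = w[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
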