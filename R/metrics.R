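#' Contingency table of predicted vs true partitions
#'
#' Cross-tabulates two labelings of the same cells. Rows are predicted
#' clusters, columns are true classes, both ordered by first appearance in
#' their respective inputs.
#'
#' @param pred an `isc_assignment`, or a vector of predicted labels named (or
#'   accompanied) by cell ids.
#' @param truth a label data frame (`cell_id`, `label`, see [read_labels()]),
#'   or a vector of true labels parallel to `pred` when `pred` is a plain
#'   vector.
#' @return Integer matrix of counts with class `"contingency_table"`.
#' @examples
#' contingency_table(c(1, 1, 2, 2), c("a", "a", "a", "b"))
#' @export
contingency_table <- function(pred, truth) {
  if (inherits(pred, "isc_assignment")) {
    ids <- pred$cell_ids
    p <- pred$labels
  } else if (!is.null(names(pred))) {
    ids <- names(pred)
    p <- unname(pred)
  } else {
    ids <- NULL
    p <- pred
  }
  if (is.data.frame(truth)) {
    if (is.null(ids))
      stop("pred carries no cell ids; cannot align against a label table")
    extra <- setdiff(ids, truth$cell_id)
    miss <- setdiff(truth$cell_id, ids)
    if (length(extra) || length(miss))
      stop("cell_id mismatch; only in pred: [",
           paste(extra, collapse = ", "), "]; only in truth: [",
           paste(miss, collapse = ", "), "]")
    t_lab <- truth$label[match(ids, truth$cell_id)]
  } else {
    if (length(truth) != length(p))
      stop("pred and truth have different lengths")
    t_lab <- truth
  }
  pf <- factor(p, levels = unique(p))
  tf <- factor(t_lab, levels = unique(t_lab))
  t <- unclass(table(pf, tf))
  dimnames(t) <- list(pred = levels(pf), truth = levels(tf))
  structure(t, class = c("contingency_table", "matrix", "array"))
}

.as_ct <- function(t) {
  t <- unclass(as.matrix(t))
  storage.mode(t) <- "double"
  if (any(t < 0) || sum(t) < 1) stop("invalid contingency table")
  t
}

#' Purity of a clustering
#'
#' Each predicted cluster is assigned to its majority true class; purity is
#' the fraction of cells covered by those majorities,
#' `sum_i max_j t_ij / N`. Note purity is not symmetric in its arguments:
#' swapping predicted and true partitions generally changes the value.
#'
#' @param t a [contingency_table()].
#' @return Purity in `(0, 1]`.
#' @export
purity <- function(t) {
  t <- .as_ct(t)
  sum(apply(t, 1L, max)) / sum(t)
}

# pair counts shared by RI and ARI: n11 = co-clustered in both,
# n00 = separated in both, via the usual binomial identities.
.pair_counts <- function(t) {
  N <- sum(t)
  sum_ij <- sum(choose(t, 2))
  sum_i <- sum(choose(rowSums(t), 2))
  sum_j <- sum(choose(colSums(t), 2))
  n11 <- sum_ij
  n00 <- choose(N, 2) - sum_i - sum_j + sum_ij
  list(N = N, n11 = n11, n00 = n00, sum_i = sum_i, sum_j = sum_j)
}

#' Rand index
#'
#' Fraction of the `N(N-1)/2` cell pairs on which the two partitions agree:
#' both co-cluster the pair or both separate it.
#'
#' @param t a [contingency_table()].
#' @return RI in `[0, 1]`.
#' @export
rand_index <- function(t) {
  t <- .as_ct(t)
  pc <- .pair_counts(t)
  if (pc$N < 2) stop("Rand index needs at least 2 cells")
  2 * (pc$n00 + pc$n11) / (pc$N * (pc$N - 1))
}

#' Adjusted Rand index
#'
#' The Rand index corrected for chance under the generalized hypergeometric
#' null with fixed marginals; 1 for identical partitions, about 0 for random
#' agreement, can be negative. When numerator and denominator both vanish
#' (identical trivial partitions: all singletons vs all singletons, or one
#' cluster vs one cluster) the value is 1 by convention.
#'
#' @param t a [contingency_table()].
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(t) {
  t <- .as_ct(t)
  pc <- .pair_counts(t)
  if (pc$N < 2) stop("adjusted Rand index needs at least 2 cells")
  expected <- pc$sum_i * pc$sum_j * 2 / (pc$N * (pc$N - 1))
  num <- pc$n11 - expected
  den <- (pc$sum_i + pc$sum_j) / 2 - expected
  if (den == 0) {
    # den = 0 only for identical trivial partitions, where num = 0 too
    if (abs(num) > 1e-9)
      stop("adjusted Rand index undefined: zero denominator with nonzero numerator")
    return(1)
  }
  num / den
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions divided by the larger of the
#' two partition entropies (natural logarithms; the ratio is base-invariant).
#' Terms with `t_ij = 0` contribute 0. A single-cluster partition has zero
#' entropy and zero mutual information, and the value is defined as 0.
#'
#' @param t a [contingency_table()].
#' @return NMI in `[0, 1]`.
#' @export
normalized_mutual_information <- function(t) {
  t <- .as_ct(t)
  N <- sum(t)
  ri <- rowSums(t)
  cj <- colSums(t)
  nz <- t > 0
  mi <- sum(t[nz] * log(N * t[nz] / outer(ri, cj)[nz]))
  h_row <- -sum(ifelse(ri > 0, ri * log(ri / N), 0))
  h_col <- -sum(ifelse(cj > 0, cj * log(cj / N), 0))
  den <- max(h_row, h_col)
  if (den == 0) return(0)
  val <- mi / den
  min(max(val, 0), 1)
}

#' All four external validation indices
#'
#' Convenience wrapper computing purity, Rand index, adjusted Rand index and
#' normalized mutual information from a predicted and a true partition.
#'
#' @inheritParams contingency_table
#' @return Named list with `purity`, `ri`, `ari`, `nmi`.
#' @export
cluster_metrics <- function(pred, truth) {
  t <- contingency_table(pred, truth)
  list(purity = purity(t), ri = rand_index(t),
       ari = adjusted_rand_index(t), nmi = normalized_mutual_information(t))
}
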