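# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid the code paths they check.

# midranks computed from first principles (no rank()): average position of
# tied values in the sorted order
naive_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman as the product-moment correlation of midranks, written out
naive_spearman <- function(a, b) {
  ra <- naive_midrank(a)
  rb <- naive_midrank(b)
  da <- ra - mean(ra)
  db <- rb - mean(rb)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# tie-free closed form 1 - 6*sum(d^2)/(m(m^2-1))
spearman_closed_form <- function(a, b) {
  d <- rank(a) - rank(b)
  m <- length(a)
  1 - 6 * sum(d^2) / (m * (m^2 - 1))
}

# all-pairs O(N^2) pair counting for RI/ARI
pair_counts_brute <- function(pred, truth) {
  n <- length(pred)
  n11 <- n00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sp <- pred[i] == pred[j]
      st <- truth[i] == truth[j]
      if (sp && st) n11 <- n11 + 1
      if (!sp && !st) n00 <- n00 + 1
    }
  }
  list(n11 = n11, n00 = n00, pairs = n * (n - 1) / 2)
}

rand_index_brute <- function(pred, truth) {
  pc <- pair_counts_brute(pred, truth)
  (pc$n11 + pc$n00) / pc$pairs
}

ari_brute <- function(pred, truth) {
  pc <- pair_counts_brute(pred, truth)
  t <- table(pred, truth)
  a <- sum(choose(rowSums(t), 2))
  b <- sum(choose(colSums(t), 2))
  expected <- a * b / pc$pairs
  max_index <- (a + b) / 2
  if (max_index == expected) return(1)
  (pc$n11 - expected) / (max_index - expected)
}

# NMI from entropy / mutual information first principles
nmi_brute <- function(pred, truth) {
  n <- length(pred)
  pu <- table(pred) / n
  pv <- table(truth) / n
  hu <- -sum(pu * log(pu))
  hv <- -sum(pv * log(pv))
  if (max(hu, hv) == 0) return(0)
  mi <- 0
  for (u in names(pu)) {
    for (v in names(pv)) {
      p <- mean(pred == u & truth == v)
      if (p > 0) mi <- mi + p * log(p / (pu[[u]] * pv[[v]]))
    }
  }
  mi / max(hu, hv)
}

random_partition <- function(n, kmax = 5) {
  sample.int(sample.int(kmax, 1), n, replace = TRUE)
}

# brute-force union-rule reference for top-h/top-q sparsification
topk_union_brute <- function(dense, k, positive = TRUE) {
  n <- ncol(dense)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      in_top <- function(a, b) {
        v <- dense[a, ]
        v[a] <- 0
        cand <- if (positive) which(v > 0) else which(v < 0)
        if (!(b %in% cand)) return(FALSE)
        ord <- if (positive) cand[order(-v[cand], cand)] else cand[order(v[cand], cand)]
        b %in% ord[seq_len(min(k, length(ord)))]
      }
      if (in_top(i, j) || in_top(j, i)) out[i, j] <- dense[i, j]
    }
  }
  dimnames(out) <- dimnames(dense)
  out
}

# random n x k orthonormal frame
random_frame <- function(n, k) {
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

# small normalized expression fixture with planted structure
small_normalized_fixture <- function(n_cells = 40, n_genes = 120, k = 2, seed = 7) {
  sim <- simulate_expression(n_cells = n_cells, n_genes = n_genes, k = k,
                             dropout_rate = 0.2, seed = seed)
  pp <- suppressMessages(preprocess(sim$expr))
  list(expr = pp$expr, labels = sim$labels)
}
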