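test_that("pairwise Spearman matches the midrank oracle and the tie-free closed form", {
  # monotone pair -> 1; reversed ranks -> -1; classic hand case -> 0.6
  m1 <- cbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8))
  expect_equal(pairwise_correlation(m1)["A", "B"], 1)
  m2 <- cbind(A = c(1, 2, 3), B = c(3, 2, 1))
  expect_equal(pairwise_correlation(m2)["A", "B"], -1)
  m3 <- cbind(A = c(1, 2, 3, 4), B = c(2, 1, 4, 3))
  expect_equal(pairwise_correlation(m3)["A", "B"], 0.6)
  expect_equal(spearman_closed_form(m3[, 1], m3[, 2]), 0.6)

  set.seed(42)
  for (rep in 1:30) {
    g <- sample(5:25, 1)
    n <- sample(3:8, 1)
    # integer values force ties, exercising the midrank path
    m <- matrix(sample(0:5, g * n, replace = TRUE), g, n)
    m <- m + matrix(rnorm(g * n, sd = 1e-6), g, n) * (runif(1) < 0.5)
    if (any(apply(m, 2, function(c) max(c) == min(c)))) next
    rho <- pairwise_correlation(m)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      expect_equal(rho[i, j], naive_spearman(m[, i], m[, j]), tolerance = 1e-12)
    expect_identical(rho, t(rho))
    expect_true(all(diag(rho) == 1))
  }
})

test_that("Spearman is invariant under strictly increasing per-cell transforms", {
  set.seed(1)
  m <- matrix(rexp(200), 20, 10)
  rho <- pairwise_correlation(m)
  m2 <- m
  m2[, 3] <- exp(m2[, 3])          # monotone transform of one cell
  m2[, 7] <- m2[, 7]^3 + 5
  expect_equal(pairwise_correlation(m2), rho, tolerance = 1e-12,
               ignore_attr = TRUE)
  # Pearson alternative is exercised and differs on nonlinear data
  expect_false(isTRUE(all.equal(pairwise_correlation(m2, method = "pearson"),
                                rho, check.attributes = FALSE)))
})

test_that("correlation preconditions reject degenerate input", {
  m <- cbind(A = c(1, 1, 1), B = c(1, 2, 3))
  expect_error(pairwise_correlation(m), "constant.*A")
  expect_error(pairwise_correlation(matrix(1:4, 2, 2)), "3 genes")
  expect_error(pairwise_correlation(matrix(1:3, 3, 1)), "2 cells")
})

test_that("sign split sends positives to s, negatives to ds, zero diagonal", {
  rho <- matrix(c(1, 0.9, -0.5, 0,
                  0.9, 1, 0.2, -0.1,
                  -0.5, 0.2, 1, 0,
                  0, -0.1, 0, 1), 4, 4)
  parts <- split_similarity_dissimilarity(rho)
  expect_true(all(parts$s >= 0))
  expect_true(all(parts$ds <= 0))
  expect_true(all(diag(parts$s) == 0) && all(diag(parts$ds) == 0))
  off <- !diag(4)
  expect_equal((parts$s + parts$ds)[off], rho[off])
  # exactly one of s, ds nonzero (or both zero), entrywise
  expect_true(all(parts$s * parts$ds == 0))
})

test_that("top-h similarity sparsification follows the union rule", {
  rho <- matrix(c(1, 0.9, -0.5,
                  0.9, 1, 0.2,
                  -0.5, 0.2, 1), 3, 3)
  parts <- split_similarity_dissimilarity(rho)
  s <- build_similarity_matrix(parts$s, h = 1)
  # cell 2 is cell 3's only positive partner, so s23 survives the union rule
  expect_equal(unclass(s),
               matrix(c(0, 0.9, 0, 0.9, 0, 0.2, 0, 0.2, 0), 3, 3),
               ignore_attr = TRUE)
  ds <- build_dissimilarity_matrix(parts$ds, q = 1)
  expect_equal(unclass(ds),
               matrix(c(0, 0, -0.5, 0, 0, 0, -0.5, 0, 0), 3, 3),
               ignore_attr = TRUE)

  # h = n - 1 keeps the whole positive part; all-negative rho gives zero S
  full <- build_similarity_matrix(parts$s, h = 2)
  expect_equal(unclass(full), parts$s, ignore_attr = TRUE)
  neg <- -abs(matrix(rnorm(16), 4, 4)); diag(neg) <- 1
  np <- split_similarity_dissimilarity((neg + t(neg)) / 2)
  expect_true(all(build_similarity_matrix(np$s, h = 2) == 0))
  expect_true(all(build_dissimilarity_matrix(np$s * 0, q = 0) == 0))

  expect_error(build_similarity_matrix(parts$s, h = 0), "h must")
  expect_error(build_similarity_matrix(parts$s, h = 3), "h must")
  expect_error(build_dissimilarity_matrix(parts$ds, q = 3), "q must")
})

test_that("sparsification agrees with a brute-force union-rule oracle", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    rho <- matrix(runif(n * n, -1, 1), n, n)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    parts <- split_similarity_dissimilarity(rho)
    h <- sample(n - 1, 1)
    q <- sample(0:(n - 1), 1)
    expect_equal(unclass(build_similarity_matrix(parts$s, h)),
                 topk_union_brute(parts$s, h, positive = TRUE),
                 ignore_attr = TRUE)
    if (q > 0)
      expect_equal(unclass(build_dissimilarity_matrix(parts$ds, q)),
                   topk_union_brute(parts$ds, q, positive = FALSE),
                   ignore_attr = TRUE)
  }
})

test_that("incidence matrix is the omega-affine mix of S and DS", {
  rho <- matrix(c(1, 0.9, -0.5,
                  0.9, 1, 0.2,
                  -0.5, 0.2, 1), 3, 3)
  parts <- split_similarity_dissimilarity(rho)
  s <- build_similarity_matrix(parts$s, h = 1)
  ds <- build_dissimilarity_matrix(parts$ds, q = 1)
  w <- build_incidence_matrix(s, ds, omega = 0.4)
  expect_equal(w[1, 2], 0.54)
  expect_equal(w[1, 3], -0.2)
  expect_equal(w[2, 3], 0.12)
  expect_equal(unclass(build_incidence_matrix(s, ds, 0)), unclass(s),
               ignore_attr = TRUE)
  expect_equal(unclass(build_incidence_matrix(s, ds, 1)), unclass(ds),
               ignore_attr = TRUE)
  # affine in omega
  w0 <- unclass(build_incidence_matrix(s, ds, 0))
  w1 <- unclass(build_incidence_matrix(s, ds, 1))
  for (om in c(0.25, 0.7)) {
    expect_equal(unclass(build_incidence_matrix(s, ds, om)),
                 (1 - om) * w0 + om * w1, ignore_attr = TRUE)
  }
  expect_error(build_incidence_matrix(s, ds, 1.2), "omega")
})

test_that("edge-list and MatrixMarket exports round-trip the sparsity pattern", {
  fx <- small_normalized_fixture()
  rho <- pairwise_correlation(fx$expr)
  parts <- split_similarity_dissimilarity(rho)
  s <- build_similarity_matrix(parts$s, h = 5)
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(s, tsv)
  el <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(nrow(el), sum(s != 0) / 2)
  mtx <- tempfile(fileext = ".mtx")
  write_edge_list(s, mtx)
  back <- as.matrix(Matrix::readMM(mtx))
  expect_equal(back, unclass(s), tolerance = 1e-12, ignore_attr = TRUE)
})
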