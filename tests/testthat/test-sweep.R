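test_that("parameter grid matches the benchmark dataset grids", {
  # dendritic cells: 251 cells, 3 types -> step 3, h = 3..42
  expect_equal(make_parameter_grid(251, 3)$h_values, seq(3, 42, by = 3))
  # mixed cell populations: 249 cells, 11 types -> step 2, h = 2..12
  expect_equal(make_parameter_grid(249, 11)$h_values, seq(2, 12, by = 2))
  # embryonic stem cells: 704 cells, 3 conditions -> step 7, h = 7..119
  expect_equal(make_parameter_grid(704, 3)$h_values, seq(7, 119, by = 7))
  # neuronal cells: 622 cells, 4 types -> step 6, h = 6..78
  expect_equal(make_parameter_grid(622, 4)$h_values, seq(6, 78, by = 6))

  g <- make_parameter_grid(515, 3)
  expect_identical(g$ss, 5)
  # q pairs each h with h and floor(h/2); odd h uses the floor
  expect_true(all(g$combos$q[g$combos$h == 15] %in% c(15, 7)))
  # explicit override for grids the step-size rule cannot produce
  g2 <- make_parameter_grid(515, 3, h_values = seq(5, 85, by = 5))
  expect_equal(max(g2$h_values), 85)

  expect_error(make_parameter_grid(40, 3), "h_values explicitly")
  expect_error(make_parameter_grid(10, 6), "ns >= 2")
})

test_that("omega = 0 reduces to the conventional spectral clustering path", {
  fx <- small_normalized_fixture()
  a0 <- run_isc(fx$expr, k = 2, omega = 0, h = 8, q = 8, seed = 5)
  sc <- conventional_sc(fx$expr, k = 2, h = 8, seed = 5)
  expect_identical(a0$labels, sc$labels)
  # determinism: same seed twice gives identical labels
  a1 <- run_isc(fx$expr, k = 2, omega = 0.3, h = 8, q = 8, seed = 5)
  a2 <- run_isc(fx$expr, k = 2, omega = 0.3, h = 8, q = 8, seed = 5)
  expect_identical(a1$labels, a2$labels)
})

test_that("sweep records every grid point and best-per-metric is the argmax", {
  fx <- small_normalized_fixture()
  grid <- make_parameter_grid(nrow(fx$labels), 2, h_values = c(6, 9),
                              omega_values = c(0, 0.4))
  csv <- tempfile(fileext = ".csv")
  sw <- isc_sweep(fx$expr, k = 2, grid = grid, truth = fx$labels,
                  seed = 1, restarts = 10, csv = csv)
  # row count = |omega| x sum over h of |q choices|
  n_combo <- nrow(grid$combos)
  expect_identical(nrow(sw$records), n_combo * 2L)
  expect_true(all(is.na(sw$records$error)))
  got <- read.csv(csv)
  expect_identical(nrow(got), nrow(sw$records))
  expect_identical(names(got), c("omega", "h", "q", "purity", "ri", "ari",
                                 "nmi", "seed"))
  # best-per-metric equals exhaustive argmax over the recorded runs
  for (m in c("purity", "ri", "ari", "nmi")) {
    for (i in seq_len(nrow(sw$best[sw$best$metric == m, ]))) {
      b <- sw$best[sw$best$metric == m, ][i, ]
      sub <- sw$records[sw$records$h == b$h & sw$records$q == b$q, ]
      expect_equal(b$sc_best, max(sub[[m]][sub$omega == 0]))
      expect_equal(b$isc_best, max(sub[[m]][sub$omega > 0]))
    }
  }
  # supremum property: max over the full omega set >= the omega = 0 value
  for (key in split(sw$records, sw$records[c("h", "q")], drop = TRUE)) {
    expect_gte(max(key$ari), key$ari[key$omega == 0])
  }
})

test_that("degenerate omega grid yields a conventional-only summary", {
  fx <- small_normalized_fixture()
  grid <- make_parameter_grid(nrow(fx$labels), 2, h_values = 6,
                              omega_values = 0)
  sw <- isc_sweep(fx$expr, k = 2, grid = grid, truth = fx$labels,
                  seed = 1, restarts = 10)
  expect_true(all(is.na(sw$best$isc_best)))
  expect_true(all(!is.na(sw$best$sc_best)))
})

test_that("exact Wilcoxon enumeration gives the rank-sum tail probability", {
  # separated samples: the treatment group holds the top 3 of 6 ranks, the
  # unique maximal rank sum among the C(6,3) = 20 assignments
  wc <- wilcoxon_compare(c(0.9, 0.8, 0.85), c(0.5, 0.4, 0.45))
  expect_equal(wc$p_value, 1 / 20)
  expect_identical(wc$method, "exact")
  expect_equal(wc$exceedance, 0)
  # wilcox.test as an independent reference on tie-free data
  ref <- wilcox.test(c(0.9, 0.8, 0.85), c(0.5, 0.4, 0.45),
                     alternative = "greater", exact = TRUE)
  expect_equal(wc$p_value, ref$p.value)

  # identical samples: all assignments give the same midrank sum, so the
  # observed statistic sits at (and is) the whole null mass
  expect_equal(wilcoxon_compare(c(1, 1, 1), c(1, 1, 1))$p_value, 1)

  # one-sided complement: p(x, y) + p(y, x) = 1 + P(W* = W_obs)
  x <- c(0.9, 0.8, 0.85); y <- c(0.5, 0.4, 0.45)
  expect_equal(wilcoxon_compare(x, y)$p_value +
               wilcoxon_compare(y, x)$p_value, 1 + 1 / 20)

  expect_error(wilcoxon_compare(1:3, 1:2), "equal length")
  expect_error(wilcoxon_compare(1, 1), "at least 2")
})

test_that("large-sample Wilcoxon branch matches the normal approximation", {
  set.seed(20)
  x <- runif(10, 0.5, 1)
  y <- runif(10, 0, 0.6)
  wc <- wilcoxon_compare(x, y)
  expect_identical(wc$method, "normal")
  ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                     correct = TRUE)
  expect_equal(wc$p_value, ref$p.value, tolerance = 1e-10)
  # ties engage the tie-corrected variance
  xt <- c(x, 0.7, 0.7); yt <- c(y, 0.7, 0.7)
  reft <- suppressWarnings(wilcox.test(xt, yt, alternative = "greater",
                                       exact = FALSE, correct = TRUE))
  expect_equal(wilcoxon_compare(xt, yt)$p_value, reft$p.value,
               tolerance = 1e-10)
})

test_that("sweep significance reports per-metric and pooled comparisons", {
  fx <- small_normalized_fixture()
  grid <- make_parameter_grid(nrow(fx$labels), 2, h_values = c(6, 9, 12),
                              omega_values = c(0, 0.3, 0.6))
  sw <- isc_sweep(fx$expr, k = 2, grid = grid, truth = fx$labels,
                  seed = 3, restarts = 10)
  sig <- sweep_significance(sw)
  expect_setequal(sig$metric, c("purity", "ri", "ari", "nmi", "pooled"))
  expect_true(all(sig$p_value > 0 & sig$p_value <= 1))
  expect_true(all(sig$exceedance >= 0 & sig$exceedance <= 1))
})
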