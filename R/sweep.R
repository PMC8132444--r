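#' Parameter grid for the neighbourhood-width sweep
#'
#' Builds the (omega, h, q) grid used to profile the method's sensitivity to
#' its neighbourhood widths. The step size is `ss = ns` rounded to the
#' nearest hundred (ties up) divided by 100; `h` runs from `ss` in steps of
#' `ss` up to the smallest multiple of `ss` at or above `0.5 * ns / nt`; for
#' each `h`, `q` is `h` and `floor(h / 2)`; omega runs over
#' `{0, 0.1, ..., 1}`.
#'
#' @param ns number of cells.
#' @param nt number of cell types (clusters).
#' @param h_values optional explicit h list overriding the step-size rule.
#' @param omega_values omega grid (default `seq(0, 1, 0.1)`).
#' @param q_rule which q choices to pair with each h: `"both"` (default,
#'   `q = h` and `q = floor(h/2)`), `"equal_h"`, `"half_h"`, or `"zero"`.
#' @return A list of class `"isc_grid"` with `ss`, `h_values`,
#'   `omega_values`, and `combos`, a data frame of all (h, q) pairs.
#' @examples
#' make_parameter_grid(251, 3)$h_values   # 3, 6, ..., 42
#' @export
make_parameter_grid <- function(ns, nt, h_values = NULL,
                                omega_values = seq(0, 1, by = 0.1),
                                q_rule = c("both", "equal_h", "half_h", "zero")) {
  q_rule <- match.arg(q_rule)
  if (ns < 2 * nt) stop("need ns >= 2 * nt")
  if (nt < 2) stop("need at least 2 cell types")
  if (any(omega_values < 0 | omega_values > 1))
    stop("omega values must lie in [0, 1]")
  ss <- floor(ns / 100 + 0.5)   # nearest hundred, ties up, then /100
  if (is.null(h_values)) {
    if (ss == 0)
      stop("fewer than 50 cells gives step size 0; supply h_values explicitly")
    H <- ss * ceiling(0.5 * ns / nt / ss)
    h_values <- seq(ss, H, by = ss)
  } else {
    h_values <- sort(unique(as.integer(h_values)))
  }
  if (any(h_values < 1 | h_values >= ns))
    stop("h values must lie in [1, ns - 1]")
  qs <- switch(q_rule,
               both = function(h) unique(c(h, h %/% 2L)),
               equal_h = function(h) h,
               half_h = function(h) h %/% 2L,
               zero = function(h) 0L)
  combos <- do.call(rbind, lapply(h_values, function(h)
    data.frame(h = h, q = qs(h))))
  structure(list(ss = ss, h_values = h_values,
                 omega_values = omega_values, combos = combos,
                 ns = ns, nt = nt),
            class = "isc_grid")
}

#' @export
print.isc_grid <- function(x, ...) {
  cat(sprintf("<isc_grid> ns = %d, nt = %d, step size %d\n", x$ns, x$nt, x$ss))
  cat("  h:", paste(x$h_values, collapse = ", "), "\n")
  cat("  omega:", paste(format(x$omega_values), collapse = ", "), "\n")
  cat(sprintf("  %d (h, q) pairs x %d omega values = %d runs\n",
              nrow(x$combos), length(x$omega_values),
              nrow(x$combos) * length(x$omega_values)))
  invisible(x)
}

#' Sweep the (omega, h, q) grid and select the best runs
#'
#' Runs the full pipeline for every (h, q, omega) combination, evaluates each
#' run against the true labels, and summarizes for every (h, q) the best
#' omega per metric, separately for `omega = 0` (conventional spectral
#' clustering, SC) and `omega > 0` (the signed variant, ISC). Failed runs are
#' recorded with an error message rather than dropped.
#'
#' @param x normalized expression matrix (see [isc()]).
#' @param k number of clusters.
#' @param grid an [make_parameter_grid()] object.
#' @param truth true labels: a data frame (`cell_id`, `label`) covering all
#'   cells.
#' @param seed global seed; per-run seeds are `seed + run index`.
#' @param restarts k-means restarts per run.
#' @param method correlation method.
#' @param csv optional path: the per-run records are written there, sorted by
#'   (h, q, omega), columns `omega,h,q,purity,ri,ari,nmi,seed`.
#' @return A list of class `"isc_sweep"` with `records` (one row per run),
#'   `best` (per (h, q) and metric, the best SC and ISC values and the omega
#'   achieving them) and the `grid`.
#' @export
isc_sweep <- function(x, k, grid, truth, seed = 0, restarts = 50,
                      method = "spearman", csv = NULL) {
  stopifnot(inherits(grid, "isc_grid"))
  runs <- merge(grid$combos, data.frame(omega = grid$omega_values))
  runs <- runs[order(runs$h, runs$q, runs$omega), c("omega", "h", "q")]
  rownames(runs) <- NULL
  rec <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run_seed <- seed + i
    res <- tryCatch({
      asg <- run_isc(x, k = k, omega = runs$omega[i], h = runs$h[i],
                     q = runs$q[i], seed = run_seed, restarts = restarts,
                     method = method)
      m <- cluster_metrics(asg, truth)
      data.frame(omega = runs$omega[i], h = runs$h[i], q = runs$q[i],
                 purity = m$purity, ri = m$ri, ari = m$ari, nmi = m$nmi,
                 seed = run_seed, error = NA_character_)
    }, error = function(e)
      data.frame(omega = runs$omega[i], h = runs$h[i], q = runs$q[i],
                 purity = NA_real_, ri = NA_real_, ari = NA_real_,
                 nmi = NA_real_, seed = run_seed,
                 error = conditionMessage(e)))
    rec[[i]] <- res
  }
  records <- do.call(rbind, rec)
  if (!is.null(csv))
    utils::write.csv(records[, c("omega", "h", "q", "purity", "ri", "ari",
                                 "nmi", "seed")],
                     csv, row.names = FALSE, quote = FALSE)
  metrics <- c("purity", "ri", "ari", "nmi")
  best <- do.call(rbind, lapply(split(records, records[c("h", "q")], drop = TRUE),
    function(g) {
      do.call(rbind, lapply(metrics, function(m) {
        sc <- g[g$omega == 0 & !is.na(g[[m]]), ]
        ic <- g[g$omega > 0 & !is.na(g[[m]]), ]
        data.frame(h = g$h[1], q = g$q[1], metric = m,
                   sc_best = if (nrow(sc)) max(sc[[m]]) else NA_real_,
                   isc_best = if (nrow(ic)) max(ic[[m]]) else NA_real_,
                   isc_omega = if (nrow(ic)) ic$omega[which.max(ic[[m]])] else NA_real_)
      }))
    }))
  rownames(best) <- NULL
  best <- best[order(best$h, best$q, best$metric), ]
  structure(list(records = records, best = best, grid = grid, seed = seed),
            class = "isc_sweep")
}

#' @export
print.isc_sweep <- function(x, ...) {
  ok <- sum(is.na(x$records$error))
  cat(sprintf("<isc_sweep> %d runs (%d ok, %d failed)\n",
              nrow(x$records), ok, nrow(x$records) - ok))
  for (m in c("purity", "ri", "ari", "nmi")) {
    b <- x$best[x$best$metric == m, ]
    i <- which.max(b$isc_best)
    cat(sprintf("  best %-6s ISC %.4f (h=%d, q=%d, omega=%s)  SC %.4f\n",
                m, b$isc_best[i], b$h[i], b$q[i], format(b$isc_omega[i]),
                max(b$sc_best, na.rm = TRUE)))
  }
  invisible(x)
}

#' Metric-vs-omega profile plot
#'
#' Line chart of the four validation indices against omega at a fixed (h, q),
#' mirroring the usual way the trade-off parameter is profiled.
#'
#' @param sweep an `"isc_sweep"` object.
#' @param h,q which combination to display (defaults to the first in the
#'   grid).
#' @export
plot_omega_profile <- function(sweep, h = NULL, q = NULL) {
  r <- sweep$records[is.na(sweep$records$error), ]
  if (is.null(h)) h <- r$h[1]
  if (is.null(q)) q <- r$q[r$h == h][1]
  r <- r[r$h == h & r$q == q, ]
  r <- r[order(r$omega), ]
  cols <- c(purity = "#1b9e77", ri = "#d95f02", ari = "#7570b3", nmi = "#e7298a")
  graphics::matplot(r$omega, as.matrix(r[, names(cols)]), type = "b", pch = 19,
                    lty = 1, col = cols, xlab = expression(omega),
                    ylab = "metric value",
                    main = sprintf("h = %d, q = %d", h, q))
  graphics::legend("bottomleft", legend = names(cols), col = cols, lty = 1,
                   pch = 19, bty = "n")
  invisible(r)
}

#' One-tailed Wilcoxon rank-sum comparison of paired best metrics
#'
#' Tests whether the signed-variant best-metric values are stochastically
#' greater than the conventional baseline's, one value per (h, q)
#' combination. For a combined sample size of at most 12 the null is
#' enumerated exactly over all assignments of the observed midranks to the
#' two groups and the p-value is `P(W* >= W_obs)`; larger samples use the
#' normal approximation with tie correction and continuity correction. An
#' auxiliary exceedance proportion — the fraction of pairs where the baseline
#' value strictly exceeds the signed variant's — is also returned.
#'
#' @param isc_best numeric vector of best metric values of the signed variant.
#' @param sc_best numeric vector of baseline values, parallel to `isc_best`.
#' @return List with `p_value` (one-sided, H1: isc > sc), `statistic` (rank
#'   sum of the `isc_best` group), `method` (`"exact"` or `"normal"`), and
#'   `exceedance` (fraction of pairs with `sc_best > isc_best`).
#' @examples
#' wilcoxon_compare(c(0.9, 0.8, 0.85), c(0.5, 0.4, 0.45))$p_value  # 0.05
#' @export
wilcoxon_compare <- function(isc_best, sc_best) {
  if (length(isc_best) != length(sc_best))
    stop("isc_best and sc_best must have equal length")
  n1 <- length(isc_best)
  if (n1 < 2) stop("need at least 2 paired values")
  combined <- c(isc_best, sc_best)
  n <- length(combined)
  r <- rank(combined)           # midranks
  W <- sum(r[seq_len(n1)])
  if (n <= 12) {
    sums <- utils::combn(n, n1, function(idx) sum(r[idx]))
    p <- mean(sums >= W - 1e-12)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * (n - n1) / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (W - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  list(p_value = min(max(p, .Machine$double.xmin), 1),
       statistic = W, method = method,
       exceedance = mean(sc_best > isc_best))
}

#' Compare best ISC vs best SC across a sweep
#'
#' Applies [wilcoxon_compare()] per metric to the best-per-(h, q) values of a
#' sweep, and optionally pooled across all four metrics.
#'
#' @param sweep an `"isc_sweep"` object.
#' @param pooled also test all metrics pooled into one pair of samples.
#' @return Data frame with one row per metric (plus `"pooled"`), columns
#'   `metric`, `p_value`, `exceedance`, `method`.
#' @export
sweep_significance <- function(sweep, pooled = TRUE) {
  out <- lapply(c("purity", "ri", "ari", "nmi"), function(m) {
    b <- sweep$best[sweep$best$metric == m &
                    !is.na(sweep$best$isc_best) & !is.na(sweep$best$sc_best), ]
    wc <- wilcoxon_compare(b$isc_best, b$sc_best)
    data.frame(metric = m, p_value = wc$p_value,
               exceedance = wc$exceedance, method = wc$method)
  })
  if (pooled) {
    b <- sweep$best[!is.na(sweep$best$isc_best) & !is.na(sweep$best$sc_best), ]
    wc <- wilcoxon_compare(b$isc_best, b$sc_best)
    out <- c(out, list(data.frame(metric = "pooled", p_value = wc$p_value,
                                  exceedance = wc$exceedance,
                                  method = wc$method)))
  }
  do.call(rbind, out)
}
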