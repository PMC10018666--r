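# Wilcoxon signed-rank test for paired plan comparison.
#
# Exact two-sided p for effective n <= 25 by dynamic programming over the
# null distribution of the positive-rank sum (ranks doubled so average ranks
# under ties stay integral); normal approximation with tie correction and
# continuity correction above. Zero differences are dropped (Wilcoxon's
# original procedure); the Pratt variant keeps them for ranking.

#' Wilcoxon signed-rank test
#'
#' Paired two-sided test of `a` vs `b`. Differences `d = a - b`; zeros
#' dropped (or kept for ranking with `zero_method = "pratt"`); |d| ranked
#' with average ranks for ties; `W` is the sum of ranks of positive
#' differences. The exact null distribution is enumerated for effective
#' n <= `exact_limit`; beyond that a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param a,b Equal-length numeric vectors of paired observations
#'   (1 <= n <= 50).
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"` (rank with zeros, then drop their ranks from W).
#' @param exact_limit Largest effective n for the exact distribution
#'   (default 25).
#' @return List with `W`, `p`, `n_effective`, `method` (`"exact"` or
#'   `"normal"`), and `note` (non-empty when all differences are zero).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p # 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b, zero_method = c("wilcox", "pratt"),
                                 exact_limit = 25) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(a) == length(b), length(a) >= 1, length(a) <= 50)
  d <- as.numeric(a) - as.numeric(b)
  if (all(d == 0)) {
    return(list(W = 0, p = 1.0, n_effective = 0L, method = "degenerate",
                note = "all paired differences are zero"))
  }
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    ranks_used <- r
  } else {
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    ranks_used <- r[d != 0]
    d <- d[d != 0]
  }
  n_eff <- length(d)

  if (n_eff <= exact_limit) {
    # DP over the distribution of 2*W under random signs on the used ranks
    r2 <- as.integer(round(2 * ranks_used))
    total <- sum(r2)
    dist <- numeric(total + 1) # index s+1 = count of sign vectors with 2W = s
    dist[1] <- 1
    for (rk in r2) {
      shifted <- c(numeric(rk), dist[seq_len(total + 1 - rk)])
      dist <- dist + shifted
    }
    probs <- dist / 2^n_eff
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(W = W, p = p, n_effective = n_eff, method = "exact", note = "")
  } else {
    mu <- n_eff * (n_eff + 1) / 4
    tie_tab <- table(ranks_used)
    sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(W = W, p = p, n_effective = n_eff, method = "normal", note = "")
  }
}

#' Compare paired plan cohorts on one metric
#'
#' Wilcoxon signed-rank comparison of two equal-length paired value lists
#' (e.g. manual vs automated plans), with significance at p < 0.05.
#'
#' @param metric_label Metric name for reporting.
#' @param a,b Equal-length numeric vectors (cohort A and B, paired).
#' @param alpha Significance level (default 0.05).
#' @return A `cohort_comparison`: list with `metric`, `a`, `b`, `differences`
#'   (`a - b`), `mean_difference`, `median_difference`, `W`, `p`,
#'   `significant`.
#' @export
compare_cohorts <- function(metric_label, a, b, alpha = 0.05) {
  if (length(a) != length(b)) {
    stop(sprintf("cohort length mismatch for '%s': %d vs %d",
                 metric_label, length(a), length(b)), call. = FALSE)
  }
  w <- wilcoxon_signed_rank(a, b)
  structure(
    list(
      metric = metric_label, a = as.numeric(a), b = as.numeric(b),
      differences = as.numeric(a) - as.numeric(b),
      mean_difference = mean(a - b), median_difference = stats::median(a - b),
      W = w$W, p = w$p, significant = w$p < alpha
    ),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %s: mean diff %.3f, W = %g, p = %.4g%s\n",
              x$metric, x$mean_difference, x$W, x$p,
              if (x$significant) " (significant)" else ""))
  invisible(x)
}

#' One-row summary of a cohort comparison
#'
#' Columns mirror a clinical comparison table: metric, per-cohort mean (sd),
#' difference and p.
#'
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @return One-row tibble: `metric`, `n`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `mean_difference`, `W`, `p`, `significant`.
#' @method tidy cohort_comparison
#' @export
tidy.cohort_comparison <- function(x, ...) {
  tibble::tibble(
    metric = x$metric, n = length(x$a),
    mean_a = mean(x$a), sd_a = stats::sd(x$a),
    mean_b = mean(x$b), sd_b = stats::sd(x$b),
    mean_difference = x$mean_difference,
    W = x$W, p = x$p, significant = x$significant
  )
}

#' Compare two metric tables cohort-wise
#'
#' Joins two long metric tables (as written by the pipeline's `metrics.csv`,
#' one row per case/structure/metric) and runs [compare_cohorts()] per
#' structure/metric pair present in both.
#'
#' @param metrics_a,metrics_b Data frames with columns `case_id`,
#'   `structure_id`, `metric`, `value`.
#' @return Tibble of [tidy.cohort_comparison()] rows, one per
#'   structure/metric.
#' @export
compare_metric_tables <- function(metrics_a, metrics_b) {
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(metrics_a), "case_id", "structure_id", "metric", "value"),
    dplyr::select(tibble::as_tibble(metrics_b), "case_id", "structure_id", "metric", "value"),
    by = c("case_id", "structure_id", "metric"), suffix = c("_a", "_b")
  )
  groups <- dplyr::distinct(joined, .data$structure_id, .data$metric)
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- joined[joined$structure_id == g$structure_id & joined$metric == g$metric, ]
    out <- tidy(compare_cohorts(paste(g$structure_id, g$metric), sub$value_a, sub$value_b))
    dplyr::bind_cols(tibble::tibble(structure_id = g$structure_id, metric = g$metric), out)
  })
}
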