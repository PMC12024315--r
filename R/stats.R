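#' Result of a rank-based two-sample comparison
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p_value two-sided p-value.
#' @param relative_effect the relative effect (see [relative_effect()]).
#' @param n1,n2 sample sizes.
#' @param method `"exact"` or `"normal approximation"`.
#' @return A list of class `stat_result` (with `p_adjusted = NA` until a
#'   multiplicity correction is applied).
#' @export
stat_result <- function(test, statistic, p_value, relative_effect,
                        n1, n2, method) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 p_adjusted = NA_real_, relative_effect = relative_effect,
                 n1 = n1, n2 = n2, method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s, p_rel = %.3g (n1 = %d, n2 = %d, %s)\n",
              x$test, x$statistic, x$p_value,
              if (is.na(x$p_adjusted)) "" else
                sprintf(" (adj. %.4g)", x$p_adjusted),
              x$relative_effect, x$n1, x$n2, x$method))
  invisible(x)
}

#' Relative effect between two samples
#'
#' The probability that a randomly selected value from `sample2` exceeds a
#' randomly selected value from `sample1`, with ties counted half:
#' `(#\{x2 > x1\} + 0.5 #\{x2 = x1\}) / (n1 * n2)`. A value of 0.5 means
#' stochastic equality; above 0.5, `sample2` tends to be larger.
#'
#' @param sample1,sample2 numeric vectors, both nonempty.
#' @return Relative effect in `[0, 1]`.
#' @export
relative_effect <- function(sample1, sample2) {
  if (!length(sample1) || !length(sample2)) {
    stop("relative_effect: both samples must be nonempty", call. = FALSE)
  }
  cmp <- outer(sample1, sample2, function(a, b) (b > a) + 0.5 * (b == a))
  sum(cmp) / (length(sample1) * length(sample2))
}

# exact null distribution of the signed-rank statistic W for ranks 1..n
# (counts over W = 0..n(n+1)/2), by the usual generating-function recursion
signed_rank_counts <- function(n) {
  counts <- 1
  for (k in seq_len(n)) {
    ext <- c(counts, numeric(k))
    counts <- ext + c(numeric(k), counts)
  }
  counts  # index i holds the count of W = i - 1; total 2^n
}

# exact null counts of the rank sum of a size-m subset of ranks 1..N
# (subset-sum DP); returns counts over sums m(m+1)/2 .. m(2N-m+1)/2
rank_sum_counts <- function(m, N) {
  smax <- sum((N - m + 1):N)
  # A[k+1, s+1] = number of k-subsets of {1..j} with sum s
  A <- matrix(0, nrow = m + 1, ncol = smax + 1)
  A[1, 1] <- 1
  for (j in seq_len(N)) {
    for (k in min(j, m):1) {
      s_idx <- (j + 1):(smax + 1)
      A[k + 1, s_idx] <- A[k + 1, s_idx] + A[k, s_idx - j]
    }
  }
  A[m + 1, ]  # index i holds count of sum = i - 1; total choose(N, m)
}

# two-sided p from a discrete symmetric null: double the smaller tail
# (including the observed value), capped at 1
two_sided_discrete <- function(stat, counts) {
  total <- sum(counts)
  vals <- seq_along(counts) - 1
  lower <- sum(counts[vals <= stat + 1e-9]) / total
  upper <- sum(counts[vals >= stat - 1e-9]) / total
  min(1, 2 * min(lower, upper))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests whether the paired differences `y - x` are symmetric about zero.
#' Zero differences are dropped (Wilcoxon's original convention); absolute
#' differences are ranked with mid-ranks for ties and the statistic `W` is
#' the sum of ranks of positive differences. The p-value is exact (full
#' null distribution) when there are no tied absolute differences and the
#' effective n is at most 25; otherwise a tie-corrected normal approximation
#' with continuity correction is used. Two-sided throughout.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return A [stat_result()]; its `relative_effect` is
#'   `relative_effect(x, y)`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("wilcoxon_signed_rank: x and y must have equal length",
         call. = FALSE)
  }
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  p_rel <- relative_effect(x, y)
  if (n == 0) {
    return(stat_result("Wilcoxon signed-rank", 0, 1, p_rel,
                       length(x), length(y), "degenerate (all ties)"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties && n <= 25) {
    p <- two_sided_discrete(W, signed_rank_counts(n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- sign(W - mu) * 0.5
    z <- (W - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  stat_result("Wilcoxon signed-rank", W, p, p_rel,
              length(x), length(y), method)
}

#' Wilcoxon-Mann-Whitney test for independent samples
#'
#' The reported statistic is `U = #\{(i, j) : x2_j > x1_i\} + 0.5 #ties`,
#' i.e. the number of pairs in which `sample2` exceeds `sample1` — so
#' `U / (n1 * n2)` equals [relative_effect()] and `U + U' = n1 * n2`. The
#' p-value is exact (subset-sum enumeration of the rank-sum null) when the
#' pooled data have no ties and `n1 * n2 <= 10000`; otherwise a
#' tie-corrected normal approximation with continuity correction. Two-sided.
#'
#' @param sample1,sample2 numeric vectors, both nonempty.
#' @return A [stat_result()].
#' @export
mann_whitney_u <- function(sample1, sample2) {
  if (!length(sample1) || !length(sample2)) {
    stop("mann_whitney_u: both samples must be nonempty", call. = FALSE)
  }
  n1 <- length(sample1)
  n2 <- length(sample2)
  pooled <- c(sample1, sample2)
  r <- rank(pooled)
  R2 <- sum(r[(n1 + 1):(n1 + n2)])
  U <- R2 - n2 * (n2 + 1) / 2  # pairs with sample2 higher (+ half ties)
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && n1 * n2 <= 10000) {
    # null distribution of the sample-2 rank sum; shift to the U scale
    counts <- rank_sum_counts(n2, n1 + n2)
    offset <- n2 * (n2 + 1) / 2
    u_counts <- counts[(offset + 1):length(counts)]
    p <- two_sided_discrete(U, u_counts)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(pooled)
    sigma2 <- (n1 * n2 / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  stat_result("Wilcoxon-Mann-Whitney", U, p, U / (n1 * n2),
              n1, n2, method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment: sort ascending, scale
#' `p_(i) * m / i`, enforce monotonicity from the largest down, cap at 1,
#' and return in the input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  if (m <= 1) return(p_values)
  o <- order(p_values)
  scaled <- p_values[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Median summary of a cohort results table
#'
#' Computes, for each metric present, the median across patients per
#' (valve size class, activity state) cell — the layout of the usual
#' size-stratified and rest/stress summary tables. The table must be
#' complete: every patient must contribute all six (size, state) cells.
#'
#' @param results long data frame with `patient_id`, `size_class`
#'   (`smaller`/`reference`/`larger`), `state` (`rest`/`stress`) and metric
#'   columns.
#' @param metrics metric columns to summarize; default: those of
#'   `dp_mmhg, vmax_mps, nfd, wpd, angle_deg` present in `results`.
#' @return Data frame `metric, size_class, state, median, n`.
#' @export
summarize_cohort <- function(results,
                             metrics = intersect(c("dp_mmhg", "vmax_mps",
                                                   "nfd", "wpd",
                                                   "angle_deg"),
                                                 names(results))) {
  need <- c("patient_id", "size_class", "state")
  if (!all(need %in% names(results))) {
    stop("summarize_cohort: results must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!length(metrics)) {
    stop("summarize_cohort: no metric columns found", call. = FALSE)
  }
  cells <- expand.grid(size_class = c("smaller", "reference", "larger"),
                       state = c("rest", "stress"),
                       stringsAsFactors = FALSE)
  patients <- unique(results$patient_id)
  for (i in seq_len(nrow(cells))) {
    sel <- results$size_class == cells$size_class[i] &
      results$state == cells$state[i]
    missing <- setdiff(patients, results$patient_id[sel])
    if (length(missing)) {
      stop(sprintf("summarize_cohort: missing cell (%s, %s) for patient %s",
                   cells$size_class[i], cells$state[i],
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  out <- do.call(rbind, lapply(metrics, function(metric) {
    do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- results$size_class == cells$size_class[i] &
        results$state == cells$state[i]
      v <- results[[metric]][sel]
      data.frame(metric = metric, size_class = cells$size_class[i],
                 state = cells$state[i], median = stats::median(v),
                 n = sum(sel), row.names = NULL)
    }))
  }))
  out
}

# pivot one metric of a long results table to a patient x cell matrix
metric_by_patient <- function(results, metric, size_class, state) {
  sel <- results$size_class == size_class & results$state == state
  v <- results[[metric]][sel]
  v[order(results$patient_id[sel])]
}

#' Paired size comparisons for one metric (smaller/larger vs reference)
#'
#' Runs the signed-rank test of each non-reference size against the
#' reference valve at a given activity state, reporting the relative effect
#' oriented as (reference, comparison size) and Benjamini-Hochberg adjusted
#' p-values within the returned family.
#'
#' @param results long cohort results table.
#' @param metric metric column name.
#' @param state `"rest"` (default) or `"stress"`.
#' @return Data frame with one row per comparison.
#' @export
compare_valve_sizes <- function(results, metric = "dp_mmhg",
                                state = "rest") {
  ref <- metric_by_patient(results, metric, "reference", state)
  rows <- lapply(c("smaller", "larger"), function(size_class) {
    other <- metric_by_patient(results, metric, size_class, state)
    res <- wilcoxon_signed_rank(ref, other)
    data.frame(metric = metric, comparison = paste0(size_class, " vs reference"),
               state = state, statistic = res$statistic,
               p_value = res$p_value, relative_effect = res$relative_effect,
               method = res$method, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Paired rest-vs-stress comparisons for one metric, per valve size
#'
#' @param results long cohort results table.
#' @param metric metric column name.
#' @return Data frame with one signed-rank comparison per size class,
#'   relative effect oriented as (rest, stress), BH-adjusted within the
#'   family.
#' @export
compare_stress <- function(results, metric = "dp_mmhg") {
  rows <- lapply(c("smaller", "reference", "larger"), function(size_class) {
    rest <- metric_by_patient(results, metric, size_class, "rest")
    stress <- metric_by_patient(results, metric, size_class, "stress")
    res <- wilcoxon_signed_rank(rest, stress)
    data.frame(metric = metric, comparison = "rest vs stress",
               size_class = size_class, statistic = res$statistic,
               p_value = res$p_value, relative_effect = res$relative_effect,
               method = res$method, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Compare a patient cohort against an independent healthy sample
#'
#' Wilcoxon-Mann-Whitney test of the per-size patient values versus healthy
#' controls for one metric, BH-adjusted across the three size classes.
#'
#' @param results long cohort results table.
#' @param healthy numeric vector of healthy-control values for the metric.
#' @param metric metric column name.
#' @param state activity state to compare at (default `"rest"`).
#' @return Data frame with one row per size class.
#' @export
compare_to_healthy <- function(results, healthy, metric = "dp_mmhg",
                               state = "rest") {
  rows <- lapply(c("smaller", "reference", "larger"), function(size_class) {
    pat <- metric_by_patient(results, metric, size_class, state)
    res <- mann_whitney_u(pat, healthy)
    data.frame(metric = metric, comparison = "patients vs healthy",
               size_class = size_class, state = state,
               statistic = res$statistic, p_value = res$p_value,
               relative_effect = res$relative_effect, method = res$method,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}
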