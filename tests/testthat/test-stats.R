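test_that("relative effect: ties, separation, complement property", {
  expect_equal(relative_effect(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(relative_effect(c(1, 2), c(3, 4)), 1)
  expect_equal(relative_effect(c(3, 4), c(1, 2)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- sample(0:5, sample(2:8, 1), replace = TRUE)
    b <- sample(0:5, sample(2:8, 1), replace = TRUE)
    expect_equal(relative_effect(a, b) + relative_effect(b, a), 1)
  }
  expect_error(relative_effect(numeric(0), 1), "nonempty")
})

test_that("signed-rank: all-positive W, degenerate ties, swap symmetry", {
  set.seed(5)
  x <- 1:10
  y <- x + runif(10, 1, 2)  # strictly positive differences
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, 55)
  expect_lt(res$p_value, 0.01)

  degen <- wilcoxon_signed_rank(x, x)
  expect_equal(degen$statistic, 0)
  expect_equal(degen$p_value, 1)

  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("signed-rank exact p matches sign-flip enumeration at n <= 8", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    x <- runif(n, 0, 10)
    y <- x + rnorm(n, 0.5)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_wsr_p(x, y))
    # two-sided p unchanged when the paired columns are swapped
    expect_equal(wilcoxon_signed_rank(y, x)$p_value, res$p_value)
  }
})

test_that("signed-rank falls back to a tie-corrected approximation", {
  x <- rep(1, 10)
  y <- c(2, 2, 2, 3, 3, 4, 4, 4, 5, 6)  # tied absolute differences
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$method, "normal approximation")
  expect_equal(res$statistic, 55)
  expect_lt(res$p_value, 0.01)
})

test_that("Mann-Whitney: separation, ties, U complement, U oracle", {
  res <- mann_whitney_u(rnorm(10), rnorm(36) + 100)
  expect_equal(res$statistic, 360)  # complete separation, n1 * n2
  expect_lt(res$p_value, 0.01)

  same <- mann_whitney_u(5, 5)
  expect_equal(same$statistic, 0.5)  # n1 * n2 / 2 under a full tie

  set.seed(7)
  for (i in 1:10) {
    a <- sample(0:8, 5, replace = TRUE)
    b <- sample(0:8, 5, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$statistic, oracle_u(a, b))
    expect_equal(res$statistic + oracle_u(b, a), 25)  # U + U' = n1 n2
    expect_equal(res$relative_effect, relative_effect(a, b))
  }
})

test_that("Mann-Whitney exact p matches assignment enumeration at small n", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- runif(sample(3:5, 1))
    b <- runif(sample(3:5, 1)) + runif(1, -0.3, 0.3)
    res <- mann_whitney_u(a, b)
    expect_equal(res$method, "exact")
    expect_equal(res$p_value, oracle_mwu_p(a, b))
  }
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(11)
  a <- runif(8, 1, 2)
  b <- runif(9, 1, 2.5)
  base <- mann_whitney_u(a, b)
  logged <- mann_whitney_u(log(a), log(b))
  cubed <- mann_whitney_u(a^3, b^3)
  expect_equal(logged$p_value, base$p_value)
  expect_equal(cubed$p_value, base$p_value)
  expect_equal(logged$statistic, base$statistic)
})

test_that("Benjamini-Hochberg step-up: hand case, oracle, properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)                 # single p unchanged
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))  # equal ps unchanged
  set.seed(3)
  for (i in 1:10) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in sort order
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("summarize_cohort: medians, constant table, missing cell", {
  t4 <- load_fixture("table4")
  s <- summarize_cohort(t4)
  med <- function(metric, sc, st) {
    s$median[s$metric == metric & s$size_class == sc & s$state == st]
  }
  expect_equal(med("dp_mmhg", "larger", "stress"), 14)
  expect_equal(med("nfd", "reference", "rest"), 0.12)
  expect_true(all(s$n == 10))

  const <- t4
  const$dp_mmhg <- 7
  expect_true(all(summarize_cohort(const)$median[
    summarize_cohort(const)$metric == "dp_mmhg"] == 7))

  incomplete <- t4[-1, ]  # drop patient 1 smaller/rest
  expect_error(summarize_cohort(incomplete), "smaller, rest.*patient 1")
})

test_that("cohort comparison wrappers orient relative effects as documented", {
  t4 <- load_fixture("table4")
  sizes <- compare_valve_sizes(t4, "dp_mmhg", state = "rest")
  expect_equal(sizes$relative_effect[sizes$comparison == "smaller vs reference"],
               0.68)
  expect_equal(sizes$relative_effect[sizes$comparison == "larger vs reference"],
               0.32)
  expect_true(all(sizes$p_adjusted >= sizes$p_value))

  stress <- compare_stress(t4, "dp_mmhg")
  expect_equal(stress$statistic, rep(55, 3))  # stress raises DP in everyone
  expect_true(all(stress$relative_effect > 0.5))

  set.seed(2)
  healthy <- rnorm(36, 0.03, 0.02)  # healthy NFD sits far below patients
  vs <- compare_to_healthy(t4, healthy, metric = "nfd")
  expect_equal(nrow(vs), 3)
  expect_true(all(vs$relative_effect < 0.5))  # healthy (sample2) lower
  expect_true(all(vs$p_adjusted <= 1 & vs$p_adjusted >= vs$p_value))
})
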