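test_that("normality gate: operating rate on normal samples, discrete data, degenerate input", {
  # on standard-normal samples the gate should pass ~95% of seeds
  set.seed(100)
  hits <- mean(replicate(400, {
    as.character(normality_gate(rnorm(20))) == "parametric"
  }))
  expect_gt(hits, 0.90)
  expect_lt(hits, 0.99)

  # heavily discrete sample: direct Shapiro-Wilk oracle says nonparametric
  x <- c(0, 0, 0, 1)
  expect_lt(stats::shapiro.test(x)$p.value, 0.05)
  expect_equal(as.character(normality_gate(x)), "nonparametric")

  expect_warning(g <- normality_gate(c(2, 2, 2, 2)), "zero variance")
  expect_equal(as.character(g), "nonparametric")
  expect_warning(g2 <- normality_gate(c(1, 2)), "n < 3")
  expect_equal(as.character(g2), "nonparametric")
})

test_that("two-group test: identical groups, closed-form t, monotone p under shift", {
  a <- c(1, 2, 3, 4, 5)
  res_id <- two_group_test(a, a, gate = "parametric")
  expect_equal(res_id$statistic, 0)
  expect_equal(res_id$p_value, 1)

  # closed-form oracle for a = {1,2,3}, b = {2,3,4}: pooled sd = 1,
  # t = (2 - 3) / sqrt(1 * (1/3 + 1/3)) = -1.224745, df = 4
  res <- two_group_test(c(1, 2, 3), c(2, 3, 4), gate = "parametric")
  expect_equal(res$statistic, -sqrt(3 / 2), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value,
               2 * stats::pt(-sqrt(3 / 2), df = 4), tolerance = 1e-10)

  # shifting one group strictly decreases p for growing shifts
  set.seed(8)
  base <- rnorm(8); other <- rnorm(8)
  ps <- vapply(c(0.5, 1, 2, 4), function(cc) {
    two_group_test(base, other + cc, gate = "parametric")$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # nonparametric branch reports the test name
  res_np <- two_group_test(c(1, 2, 3, 10), c(2, 3, 4, 60),
                           gate = "nonparametric")
  expect_match(res_np$test, "Wilcoxon")
  expect_error(two_group_test(numeric(0), a), "non-empty")
})

test_that("one-sample test vs unity: exact mean, closed-form t, degenerate rejection", {
  r0 <- one_sample_vs_unity(c(0.9, 1.0, 1.1))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # closed form: mean 0.7, sd 0.1, se = 0.1/sqrt(3), t = -0.3/se = -5.196
  r <- one_sample_vs_unity(c(0.6, 0.7, 0.8))
  expect_equal(r$statistic, -0.3 / (0.1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r$statistic, -5.196152, tolerance = 1e-6)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * stats::pt(-5.196152, 2), tolerance = 1e-6)

  expect_error(one_sample_vs_unity(c(1, 1, 1)), "zero variance")
  expect_error(one_sample_vs_unity(1), "n >= 2")
})

test_that("two-way ANOVA: null design, injected effect power, correction property", {
  # identical constants in all cells: all effect sums of squares are 0
  d <- expand.grid(g = c("wt", "ko"), tr = c("ctl", "cpz"), rep = 1:3)
  res0 <- suppressWarnings(two_way_anova_mc(rep(5, nrow(d)), d$g, d$tr))
  expect_true(all(res0$anova_table$sum_sq[1:3] < 1e-20))

  # a genotype shift of 2 sd with n = 6/cell: power oracle says > 0.8
  oracle_power <- stats::power.t.test(n = 12, delta = 2, sd = 1)$power
  expect_gt(oracle_power, 0.8)
  set.seed(77)
  rej <- mean(replicate(200, {
    d$y <- rnorm(nrow(d)) + ifelse(d$g == "ko", 2, 0)
    d2 <- d[rep(seq_len(nrow(d)), 2), ]      # 6 per cell
    d2$y <- rnorm(nrow(d2)) + ifelse(d2$g == "ko", 2, 0)
    out <- two_way_anova_mc(d2$y, d2$g, d2$tr)
    out$anova_table$p_value[out$anova_table$term == "genotype"] < 0.05
  }))
  expect_gte(rej, 0.8)

  # corrected pairwise p >= uncorrected
  set.seed(11)
  y <- rnorm(24)
  d3 <- expand.grid(g = c("wt", "ko"), tr = c("ctl", "cpz"), rep = 1:6)
  cor_p <- two_way_anova_mc(y, d3$g, d3$tr, correction = "sidak")$pairwise$p.value
  unc_p <- two_way_anova_mc(y, d3$g, d3$tr, correction = "none")$pairwise$p.value
  expect_true(all(cor_p >= unc_p - 1e-12))

  expect_error(two_way_anova_mc(1:4, factor(c("a", "a", "a", "a")),
                                factor(c("x", "x", "y", "y"))), "2 levels")
  expect_error(
    two_way_anova_mc(1:6, factor(c("a", "a", "a", "b", "b", "b")),
                     factor(c("x", "y", "x", "x", "x", "x"))),
    "empty design cell")
})

test_that("Gaussian histogram fits and the extra-sum-of-squares F test", {
  mids <- seq(-4, 4, by = 0.25)
  gauss <- function(A, m, s) A * exp(-(mids - m)^2 / (2 * s^2))

  # identical noiseless histograms: F = 0, p = 1
  h <- data.frame(mid = mids, count = gauss(30, 0.3, 1.1))
  same <- gaussian_fit_compare(h, h)
  expect_equal(same$f_statistic, 0)
  expect_equal(same$p_value, 1)
  # parameters recovered exactly on the noiseless histogram
  expect_equal(unname(same$fit_a["m"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(same$fit_a["s"]), 1.1, tolerance = 1e-6)

  # well-separated means: the shared fit is rejected
  set.seed(14)
  ha <- data.frame(mid = mids,
                   count = pmax(gauss(30, 0, 1) + rnorm(length(mids), 0, 0.5), 0))
  hb <- data.frame(mid = mids,
                   count = pmax(gauss(30, 2, 1) + rnorm(length(mids), 0, 0.5), 0))
  diff_fit <- gaussian_fit_compare(ha, hb)
  expect_lt(diff_fit$p_value, 0.01)
  expect_gte(diff_fit$rss_shared, diff_fit$rss_separate)

  expect_error(gaussian_fit_compare(h, data.frame(mid = mids + 1,
                                                  count = h$count)),
               "common bins")
  expect_error(
    gaussian_fit_compare(data.frame(mid = 1:5, count = c(1, 0, 0, 0, 0)), h),
    "4 bins")
})

test_that("tests are invariant to input ordering", {
  set.seed(20)
  a <- rnorm(10); b <- rnorm(10, 1)
  r1 <- two_group_test(a, b, gate = "parametric")
  r2 <- two_group_test(sample(a), sample(b), gate = "parametric")
  expect_equal(r1$statistic, r2$statistic)
  fc <- runif(6, 0.5, 1.5)
  expect_equal(one_sample_vs_unity(fc)$p_value,
               one_sample_vs_unity(rev(fc))$p_value)
})

test_that("per-animal aggregation collapses FOVs before testing", {
  df <- data.frame(animal = rep(c("m1", "m2", "m3"), each = 4),
                   group = "ctl",
                   y = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  agg <- aggregate_per_animal(df, "y", "animal", "group")
  expect_equal(nrow(agg), 3L)
  expect_equal(sort(agg$y), c(2.5, 6.5, 10.5))
})
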