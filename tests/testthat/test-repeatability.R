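test_that("delta and percent delta follow their definitions", {
  expect_equal(test_retest_delta(2, 3), 1)
  expect_equal(test_retest_delta(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(test_retest_delta(c(1, 2), c(4, 1)),
               -test_retest_delta(c(4, 1), c(1, 2)))
  expect_equal(test_retest_pct_delta(2, 3), 40)
  expect_equal(test_retest_pct_delta(1, 3), 100)
  expect_equal(test_retest_pct_delta(5, 5), 0)
  expect_error(test_retest_pct_delta(1, -1), "zero pair mean")
  expect_error(test_retest_delta(1:3, 1:2), "equal length")
})

test_that("percent delta is antisymmetric; its magnitude is not", {
  e <- c(2, 5, 9)
  l <- c(3, 4, 12)
  expect_equal(test_retest_pct_delta(e, l), -test_retest_pct_delta(l, e))
  expect_equal(abs_pct_delta(test_retest_pct_delta(e, l)),
               abs_pct_delta(test_retest_pct_delta(l, e)))
  # the motivating cancellation case
  pct <- c(-40, 40)
  expect_equal(mean(pct), 0)
  expect_equal(stats::median(abs_pct_delta(pct)), 40)
})

test_that("limits of repeatability use the n-1 sample deviation", {
  lor <- limits_of_repeatability(c(-2, 0, 2))
  expect_equal(lor$mu, 0)
  expect_equal(lor$sigma, 2) # sd with n-1 denominator: sqrt(8/2)
  expect_equal(lor$lor_low, -4)
  expect_equal(lor$lor_high, 4)
  const <- limits_of_repeatability(rep(3, 5))
  expect_equal(c(const$mu, const$sigma, const$lor_low, const$lor_high),
               c(3, 0, 3, 3))
  # always symmetric about the mean
  set.seed(1)
  x <- stats::rnorm(50)
  lr <- limits_of_repeatability(x)
  expect_equal(lr$lor_high - lr$mu, lr$mu - lr$lor_low)
  expect_error(limits_of_repeatability(1), "at least 2")
})

test_that("limits of repeatability cover about 95% of Gaussian deltas", {
  set.seed(2024)
  d <- stats::rnorm(10000, mean = 1, sd = 3)
  lor <- limits_of_repeatability(d)
  coverage <- mean(d >= lor$lor_low & d <= lor$lor_high)
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("ICC(A,1) matches a two-way ANOVA oracle", {
  set.seed(5)
  for (shift in c(0, 1, 4)) {
    e <- stats::rnorm(25, mean = 10, sd = 2)
    l <- e + shift + stats::rnorm(25, sd = 0.5)
    icc <- icc_absolute_agreement(e, l)
    df <- data.frame(y = c(e, l), subj = factor(rep(seq_len(25), 2)),
                     rater = factor(rep(1:2, each = 25)))
    ms <- stats::anova(stats::aov(y ~ subj + rater, df))[["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3] + (2 / 25) * (ms[2] - ms[3]))
    expect_equal(icc, oracle, tolerance = 1e-10)
  }
})

test_that("ICC penalizes a systematic shift that Pearson r ignores", {
  set.seed(6)
  e <- stats::rnorm(40, mean = 5, sd = 1)
  l <- e + 6 + stats::rnorm(40, sd = 0.2)
  expect_gt(r_squared(e, l), 0.9)
  expect_lt(icc_absolute_agreement(e, l), 0.3)
  # perfect agreement
  expect_equal(icc_absolute_agreement(e, e), 1)
  # monotone decrease as the bias grows, scatter fixed
  iccs <- vapply(c(0, 1, 2, 4, 8), function(s) {
    icc_absolute_agreement(e, e + s + 0.1 * sin(seq_along(e)))
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_true(all(iccs <= 1))
})

test_that("r_squared is 1 on exact linear relations and matches OLS", {
  e <- c(1, 2, 4, 8)
  expect_equal(r_squared(e, -3 * e + 7), 1)
  set.seed(7)
  x <- stats::rnorm(30)
  y <- 0.5 * x + stats::rnorm(30)
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::resid(fit)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(r_squared(x, y), 1 - sse / sst, tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), 1:5), "zero variance")
})

test_that("uncorrelated pairs give near-zero r_squared", {
  set.seed(8)
  n <- 4000
  expect_lt(r_squared(stats::rnorm(n), stats::rnorm(n)), (3 / sqrt(n))^2)
})

test_that("exact signed-rank p matches brute-force enumeration", {
  # n = 5, all positive, no ties: the textbook minimum two-sided p
  e <- c(1, 2, 3, 4, 5)
  l <- e + c(0.5, 1.2, 0.7, 2.1, 1.7)
  expect_equal(wilcoxon_signed_rank(e, l)$p_value, 0.0625)

  set.seed(9)
  for (rep in 1:3) {
    n <- 12
    e <- stats::rnorm(n)
    l <- e + stats::rnorm(n, 0.4)
    res <- wilcoxon_signed_rank(e, l, mode = "exact")
    d <- l - e
    r <- rank(abs(d))
    mu <- n * (n + 1) / 4
    W <- sum(r[d > 0])
    allW <- vapply(0:(2^n - 1), function(m) {
      sum(r[as.logical(bitwAnd(m, 2^(0:(n - 1))))])
    }, numeric(1))
    p_brute <- mean(abs(allW - mu) >= abs(W - mu) - 1e-9)
    expect_equal(res$p_value, p_brute, tolerance = 1e-12)
  }
})

test_that("signed-rank handles ties, zeros, and the degenerate case", {
  # zeros dropped
  e <- c(1, 2, 3, 4, 5, 6)
  l <- c(1, 3, 5, 2, 9, 6) # two zero differences
  res <- wilcoxon_signed_rank(e, l)
  expect_equal(res$n_nonzero, 4L)
  # tied |d|: mid-ranks keep the exact path consistent with brute force
  e2 <- c(0, 0, 0, 0, 0)
  l2 <- c(1, 1, -1, 2, 3)
  r <- rank(abs(l2 - e2))
  W <- sum(r[l2 > e2])
  allW <- vapply(0:(2^5 - 1), function(m) {
    sum(r[as.logical(bitwAnd(m, 2^(0:4)))])
  }, numeric(1))
  mu <- sum(r) / 2
  p_brute <- mean(abs(allW - mu) >= abs(W - mu) - 1e-9)
  expect_equal(wilcoxon_signed_rank(e2, l2, mode = "exact")$p_value, p_brute)
  # identical series
  expect_warning(res0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(res0$p_value, 1)
})

test_that("normal approximation tracks the exact p for moderate n", {
  set.seed(10)
  e <- stats::rnorm(20)
  l <- e + stats::rnorm(20, 0.3)
  pe <- wilcoxon_signed_rank(e, l, mode = "exact")$p_value
  pn <- wilcoxon_signed_rank(e, l, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.02)
})

test_that("summarize_metric agrees with its componentwise oracles", {
  set.seed(11)
  e <- stats::rlnorm(20, 1, 0.4)
  l <- e * stats::rlnorm(20, 0.2, 0.2)
  s <- summarize_metric(e, l, "demo")
  expect_equal(s$n, 20L)
  expect_equal(s$median_early, stats::median(e))
  expect_equal(s$q1_late, unname(stats::quantile(l, 0.25)))
  expect_equal(s$mean_delta, mean(l - e))
  expect_equal(s$sd_delta, stats::sd(l - e))
  expect_equal(s$lor_high, mean(l - e) + 2 * stats::sd(l - e))
  pct <- 100 * (l - e) / ((l + e) / 2)
  expect_equal(s$mean_pct_delta, mean(pct))
  expect_equal(s$median_abs_pct_delta, stats::median(abs(pct)))
  expect_equal(s$icc, icc_absolute_agreement(e, l))
  expect_equal(s$r_squared, stats::cor(e, l)^2)
  expect_equal(s$p_wilcoxon, wilcoxon_signed_rank(e, l)$p_value)
})

test_that("degenerate constant series fail loudly in the summary", {
  suppressWarnings(expect_error(summarize_metric(rep(2, 5), rep(2, 5))))
})

test_that("summary rows round-trip through CSV", {
  set.seed(12)
  e <- stats::rlnorm(10)
  l <- e * 1.3
  s <- summarize_metric(e, l, "m")
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(s, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back$icc, s$icc, tolerance = 1e-12)
  expect_equal(back$lor_pct_low, s$lor_pct_low, tolerance = 1e-12)
})

test_that("summarize_repeatability warns and skips tiny tracer groups", {
  metrics <- tibble::tibble(
    tracer = rep("FDG", 4), lesion_id = rep(c("L1", "L2"), each = 2),
    timepoint = rep(c("early", "late"), 2),
    ki_max = c(1, 1.1, 2, 2.2)
  )
  expect_warning(out <- summarize_repeatability(metrics,
                                                metric_cols = "ki_max"),
                 "fewer than 3")
  expect_equal(nrow(out), 0)
})
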