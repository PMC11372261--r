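#' Test--retest differences
#'
#' `test_retest_delta()` is the element-wise late - early difference;
#' `test_retest_pct_delta()` expresses it relative to the pair mean,
#' \eqn{100 (late - early) / ((late + early)/2)}, so metrics of different
#' magnitude can be compared; `abs_pct_delta()` takes the magnitude, which
#' avoids cancellation of large positive and negative changes when
#' averaging.
#'
#' @param early,late Paired numeric vectors of equal length.
#' @return Numeric vector of differences (`delta`), percent differences
#'   (`pct_delta`), or magnitudes.
#' @export
test_retest_delta <- function(early, late) {
  check_paired(early, late)
  late - early
}

#' @rdname test_retest_delta
#' @export
test_retest_pct_delta <- function(early, late) {
  check_paired(early, late)
  m <- (early + late) / 2
  if (any(m == 0)) {
    stop("zero pair mean at index ", paste(which(m == 0), collapse = ", "),
         call. = FALSE)
  }
  100 * (late - early) / m
}

#' @rdname test_retest_delta
#' @param pct_series A percent-difference series.
#' @export
abs_pct_delta <- function(pct_series) {
  if (length(pct_series) == 0) stop("series is empty", call. = FALSE)
  abs(pct_series)
}

check_paired <- function(early, late) {
  if (length(early) != length(late)) {
    stop("`early` and `late` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(early)) || any(!is.finite(late))) {
    stop("paired series must be finite with no missing entries",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' 95% limits of repeatability
#'
#' Bland--Altman style limits: with \eqn{\mu} the sample mean and
#' \eqn{\sigma} the sample standard deviation (n-1 denominator) of a
#' test--retest difference series, the 95% limits of repeatability are
#' \eqn{\mu \pm 2\sigma}.
#'
#' @param delta_series Numeric difference series (n >= 2).
#' @return Tibble with `mu`, `sigma`, `lor_low`, `lor_high`.
#' @export
limits_of_repeatability <- function(delta_series) {
  if (length(delta_series) < 2) {
    stop("need at least 2 differences", call. = FALSE)
  }
  mu <- mean(delta_series)
  sigma <- stats::sd(delta_series)
  tibble::tibble(mu = mu, sigma = sigma,
                 lor_low = mu - 2 * sigma, lor_high = mu + 2 * sigma)
}

#' Absolute-agreement intraclass correlation for paired measurements
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (ICC(A,1)) for k = 2 raters (early/late), computed from the two-way
#' ANOVA mean squares:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + MS_E + \frac{2}{n}(MS_C - MS_E)}}
#' Unlike a consistency coefficient (or Pearson's r), this penalizes a
#' systematic early-to-late shift, which is exactly what separates the
#' uptake-time-dependent metrics (high R-squared, low ICC) from the
#' corrected ones.
#'
#' @param early,late Paired numeric vectors (n >= 3).
#' @return ICC in `[-1, 1]`.
#' @export
icc_absolute_agreement <- function(early, late) {
  check_paired(early, late)
  n <- length(early)
  if (n < 3) stop("ICC requires at least 3 pairs", call. = FALSE)
  x <- cbind(early, late)
  gm <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  k <- 2
  msr <- k * sum((row_m - gm)^2) / (n - 1)
  msc <- n * sum((col_m - gm)^2) / (k - 1)
  res <- x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm
  mse <- sum(res^2) / ((n - 1) * (k - 1))
  denom <- msr + mse + (k / n) * (msc - mse)
  if (denom <= 0) stop("degenerate series: zero total variance",
                       call. = FALSE)
  (msr - mse) / denom
}

#' Squared Pearson correlation of paired measurements
#'
#' @param early,late Paired numeric vectors (n >= 3, nonzero variance).
#' @return R-squared in `[0, 1]`; equals the OLS coefficient of
#'   determination of `late` regressed on `early`.
#' @export
r_squared <- function(early, late) {
  check_paired(early, late)
  if (length(early) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(early) == 0 || stats::sd(late) == 0) {
    stop("zero variance in a series", call. = FALSE)
  }
  stats::cor(early, late)^2
}

#' Two-tailed Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; ties in the absolute differences receive
#' mid-ranks. For `n <= 25` non-zero differences (or `mode = "exact"`) the
#' two-sided p-value is computed by exact enumeration of the signed-rank
#' null distribution (a subset-sum convolution over the, possibly tied,
#' ranks); otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param early,late Paired numeric vectors.
#' @param mode `"auto"`, `"exact"`, or `"normal"`.
#' @return One-row tibble with `statistic` (W+, the positive-rank sum),
#'   `p_value`, `n_nonzero`, `method`.
#' @export
wilcoxon_signed_rank <- function(early, late,
                                 mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  check_paired(early, late)
  d <- late - early
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1")
    return(tibble::tibble(statistic = 0, p_value = 1, n_nonzero = 0L,
                          method = "degenerate"))
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  use_exact <- mode == "exact" || (mode == "auto" && n <= 25)
  if (use_exact) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble::tibble(statistic = w, p_value = p, n_nonzero = as.integer(n),
                 method = method)
}

# Exact two-sided p for W+ = w given (possibly mid-ranked) ranks r.
# Doubles ranks to integers, builds the null distribution of 2*W+ by
# convolution, and sums the symmetric tails |W - mu| >= |w - mu|.
signed_rank_exact_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  cnt <- numeric(total + 1) # counts for 2W+ = 0..total
  cnt[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), cnt[seq_len(total + 1 - ri)])
    cnt <- cnt + shifted
  }
  support <- 0:total
  mu2 <- total / 2 # null mean of 2W+
  dev <- abs(2 * w - mu2)
  sel <- abs(support - mu2) >= dev - 1e-9
  sum(cnt[sel]) / 2^length(r2)
}

#' Summarize intrascan repeatability of one metric
#'
#' Produces the full per-metric summary block: early/late medians with
#' quartiles (linear-interpolation "type 7" quantiles), Wilcoxon signed-rank
#' p, R-squared, ICC(A,1), the test--retest difference and percent
#' difference distributions with 95% limits of repeatability, and the
#' absolute percent difference quartiles.
#'
#' @param early,late Paired numeric vectors.
#' @param metric_name Label carried into the output.
#' @return A one-row tibble (class `repeatability_summary`).
#' @export
summarize_metric <- function(early, late, metric_name = "metric") {
  check_paired(early, late)
  n <- length(early)
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                   type = 7)
  qe <- q(early)
  ql <- q(late)
  delta <- test_retest_delta(early, late)
  pct <- test_retest_pct_delta(early, late)
  apct <- abs_pct_delta(pct)
  qa <- q(apct)
  lor <- limits_of_repeatability(delta)
  lorp <- limits_of_repeatability(pct)
  wt <- wilcoxon_signed_rank(early, late)
  out <- tibble::tibble(
    metric = metric_name, n = as.integer(n),
    median_early = qe[2], q1_early = qe[1], q3_early = qe[3],
    median_late = ql[2], q1_late = ql[1], q3_late = ql[3],
    p_wilcoxon = wt$p_value,
    r_squared = r_squared(early, late),
    icc = icc_absolute_agreement(early, late),
    mean_delta = lor$mu, sd_delta = lor$sigma,
    lor_low = lor$lor_low, lor_high = lor$lor_high,
    mean_pct_delta = lorp$mu, sd_pct_delta = lorp$sigma,
    lor_pct_low = lorp$lor_low, lor_pct_high = lorp$lor_high,
    median_abs_pct_delta = qa[2], q1_abs_pct_delta = qa[1],
    q3_abs_pct_delta = qa[3]
  )
  class(out) <- c("repeatability_summary", class(out))
  out
}

#' Repeatability summary across all metrics of a lesion table
#'
#' Pairs each lesion's early and late rows and applies [summarize_metric()]
#' to every metric column, one tracer at a time (tracers are analyzed
#' separately). Tracers with fewer than 3 complete lesion pairs are skipped
#' with a warning.
#'
#' @param metrics Long lesion metrics table (one row per lesion x
#'   timepoint) as produced by [run_analyze()].
#' @param metric_cols Metric columns to summarize.
#' @return Tibble with one row per tracer x metric.
#' @export
summarize_repeatability <- function(metrics,
                                    metric_cols = c("ki_max", "ki_peak",
                                                    "suv_max", "suv_peak",
                                                    "csuv_max", "csuv_peak",
                                                    "sur_max", "sur_peak",
                                                    "csur_max", "csur_peak")) {
  metric_cols <- intersect(metric_cols, names(metrics))
  out <- list()
  for (tr in unique(metrics$tracer)) {
    sub <- metrics[metrics$tracer == tr, ]
    wide <- tidyr::pivot_wider(
      sub[, c("lesion_id", "timepoint", metric_cols)],
      names_from = "timepoint", values_from = dplyr::all_of(metric_cols)
    )
    if (nrow(wide) < 3) {
      warning("tracer ", tr, " has fewer than 3 lesions; skipped")
      next
    }
    for (mc in metric_cols) {
      e <- wide[[paste0(mc, "_early")]]
      l <- wide[[paste0(mc, "_late")]]
      ok <- is.finite(e) & is.finite(l)
      if (sum(ok) < 3) next
      s <- summarize_metric(e[ok], l[ok], metric_name = mc)
      s <- dplyr::mutate(s, tracer = tr, .before = 1)
      out[[paste(tr, mc)]] <- s
    }
  }
  dplyr::bind_rows(out)
}
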