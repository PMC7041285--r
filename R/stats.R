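# Statistical reporting: Welch two-sample t tests with a capped Bonferroni
# correction, squared Pearson correlation, and the two-way absolute-agreement
# intraclass correlation used for rater reliability.

#' Independent-sample t test with capped Bonferroni correction
#'
#' Two-sided Welch t test. The raw p-value is multiplied by `n_comparisons`
#' and capped at 1 (Bonferroni over a family of pairwise comparisons), which
#' reproduces the p = 1.000 entries seen in multiply-compared method tables.
#'
#' @param x,y numeric samples (each at least 2 values; at least one with
#'   nonzero variance).
#' @param n_comparisons size of the comparison family (1 = no correction).
#' @return List with `statistic`, `df`, `p_raw` and `p_adjusted`.
#' @export
t_test_independent <- function(x, y, n_comparisons = 1L) {
  if (length(x) < 2L || length(y) < 2L)
    stopf("each sample needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, df = NA_real_, p_raw = 1, p_adjusted = 1))
    stopf("both samples are constant; t test is degenerate")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  p_adj <- min(1, tt$p.value * n_comparisons)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_raw = tt$p.value, p_adjusted = p_adj)
}

#' Squared Pearson correlation
#'
#' @param x,y paired numeric samples (at least 3 pairs, nonzero variances).
#' @return R-squared in `[0, 1]`.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 paired values")
  if (var(x) == 0 || var(y) == 0) stopf("zero variance in x or y")
  cor(x, y)^2
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Single-measures ICC(A,1) from the two-way mean squares
#' (McGraw & Wong): `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`
#' with n subjects and k raters; the absolute-agreement form penalises
#' systematic rater offsets. `form = "average"` returns the average-measures
#' ICC(A,k).
#'
#' @param table data frame with columns `subject`, `rater`, `value`; a
#'   complete crossed design (every subject x rater cell exactly once). For
#'   intra-rater reliability pass measurement occasions as the raters.
#' @param form `"single"` (default) or `"average"`.
#' @return List with `icc`, the mean squares, and an `interpretation` band
#'   (poor < 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9).
#' @export
icc_absolute_agreement <- function(table, form = c("single", "average")) {
  form <- match.arg(form)
  if (!all(c("subject", "rater", "value") %in% names(table)))
    stopf("table needs columns subject, rater, value")
  tab <- stats::xtabs(value ~ subject + rater, data = table)
  cnt <- stats::xtabs(~ subject + rater, data = table)
  if (any(cnt != 1L))
    stopf("incomplete or replicated design: every subject x rater cell must appear exactly once")
  n <- nrow(tab)
  k <- ncol(tab)
  if (k < 2L) stopf("need at least 2 raters")
  if (n < 5L) stopf("need at least 5 subjects")
  grand <- mean(tab)
  row_m <- rowMeans(tab)
  col_m <- colMeans(tab)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((tab - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  band <- if (icc < 0.5) "poor" else if (icc <= 0.75) "moderate"
          else if (icc <= 0.9) "good" else "excellent"
  list(icc = icc, ms_subject = msr, ms_rater = msc, ms_error = mse,
       n_subjects = n, n_raters = k, form = form, interpretation = band)
}
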