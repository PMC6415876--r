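#' Ordinary least-squares method-comparison regression
#'
#' Regresses the device measurement on the reference (reference on the
#' x-axis, the convention for method-comparison scatter plots), with 95%
#' confidence intervals from the t distribution on n - 2 degrees of
#' freedom and the coefficient of determination.
#'
#' @param table a [measurement_table()].
#' @param confidence confidence level (default 0.95).
#' @return object of class `regression_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `r_squared`, `n`.
#' @export
ols_regression <- function(table, confidence = 0.95) {
  x <- table$reference; y <- table$device
  n <- length(x)
  if (n < 3L) stop_spermfx("need at least 3 pairs", "insufficient_data_error")
  if (var(x) == 0)
    stop_spermfx("reference values are constant", "degenerate_predictor_error")
  fit <- lm(y ~ x)
  # perfect fits (zero residual) are legitimate here; silence summary.lm's note
  ci <- suppressWarnings(confint(fit, level = confidence))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
                 r_squared = 1 - ss_res / ss_tot, n = n,
                 confidence = confidence),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.2f (%.2f to %.2f), intercept %.2f (%.2f to %.2f), R2 %.2f, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2],
              x$r_squared, x$n))
  invisible(x)
}

#' Passing--Bablok regression
#'
#' Nonparametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes S_ij = (y_j - y_i)/(x_j - x_i) (i < j,
#' x_i != x_j; slopes of exactly -1 discarded), shifted by K = #\{S_ij < -1\}
#' so the estimator is invariant to exchanging the methods. The slope CI
#' comes from the rank bounds M1 = round((N - C)/2), M2 = N - M1 + 1 with
#' C = z * sqrt(n(n-1)(2n+5)/18), shifted by K; the intercept is
#' median(y - b x), its CI evaluated at the slope CI bounds. The cusum
#' linearity test p-value is attached.
#'
#' @param table a [measurement_table()].
#' @param confidence confidence level (default 0.95).
#' @return object of class `passing_bablok_fit`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `K`, `cusum_p`, `n`.
#' @export
passing_bablok <- function(table, confidence = 0.95) {
  x <- table$reference; y <- table$device
  n <- length(x)
  if (n < 3L) stop_spermfx("need at least 3 pairs", "insufficient_data_error")
  if (var(x) == 0)
    stop_spermfx("reference values are constant", "degenerate_predictor_error")
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  ok <- dx != 0
  S <- dy[ok] / dx[ok]
  S <- S[S != -1]
  if (length(S) == 0L)
    stop_spermfx("no finite pairwise slope", "degenerate_predictor_error")
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  b <- shifted_median(S, K)
  a <- median(y - b * x)

  z <- qnorm((1 + confidence) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  slope_ci <- c(NA_real_, NA_real_)
  if (M1 + K >= 1 && M2 + K <= N)
    slope_ci <- c(S[M1 + K], S[M2 + K])
  intercept_ci <- if (anyNA(slope_ci)) c(NA_real_, NA_real_) else
    sort(c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x)))
  fit <- structure(list(slope = b, intercept = a, slope_ci = slope_ci,
                        intercept_ci = intercept_ci, K = K, n = n,
                        n_slopes = N, confidence = confidence),
                   class = "passing_bablok_fit")
  fit$cusum_p <- cusum_linearity_p(table, fit)
  fit
}

# Median of sorted slopes shifted by the offset K (mean of the two middle
# order statistics when the count is even).
shifted_median <- function(S_sorted, K) {
  N <- length(S_sorted)
  if (N %% 2L == 1L) S_sorted[(N + 1L) / 2L + K]
  else mean(S_sorted[N / 2L + K + c(0L, 1L)])
}

#' @export
print.passing_bablok_fit <- function(x, ...) {
  cat(sprintf("<passing_bablok_fit> slope %.2f (%.2f to %.2f), intercept %.2f (%.2f to %.2f), n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$n))
  cat(sprintf("  cusum linearity test P = %.2f\n", x$cusum_p))
  invisible(x)
}

#' Cusum test for linearity of a Passing--Bablok fit
#'
#' Scores each point by its side of the fitted line (above: +sqrt(L/l),
#' below: -sqrt(l/L), on-line: 0, where l and L are the above/below
#' counts), accumulates the scores in order of the points' projection along
#' the fitted line, and refers the maximal absolute cusum, standardized by
#' sqrt(L + l + 1), to the Kolmogorov--Smirnov distribution.
#'
#' @param table the [measurement_table()] the fit was computed on.
#' @param fit a `passing_bablok_fit` (only `slope` and `intercept` are used).
#' @return two-sided p-value; values near 1 indicate no detectable
#'   deviation from linearity.
#' @export
cusum_linearity_p <- function(table, fit) {
  x <- table$reference; y <- table$device
  r <- y - fit$intercept - fit$slope * x
  above <- r > 0; below <- r < 0
  l <- sum(above); L <- sum(below)
  if (l == 0L || L == 0L) return(1)
  score <- numeric(length(x))
  score[above] <- sqrt(L / l)
  score[below] <- -sqrt(l / L)
  ord <- order(x + fit$slope * y)   # projection onto the fitted line
  cusum <- cumsum(score[ord])
  stat <- max(abs(cusum)) / sqrt(l + L + 1)
  ks_survival(stat)
}

# Two-sided Kolmogorov-Smirnov survival function Q(t) = 2 sum (-1)^(k-1) exp(-2 k^2 t^2)
ks_survival <- function(t) {
  if (t < 1e-3) return(1)
  k <- seq_len(1000)
  clamp(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2)), 0, 1)
}

#' Bland--Altman agreement analysis
#'
#' Differences are device - reference; the bias is their mean, the limits
#' of agreement bias +/- `loa_multiplier` times their sample standard
#' deviation (n - 1 denominator).
#'
#' @param table a [measurement_table()].
#' @param loa_multiplier multiplier for the limits of agreement
#'   (default 1.96, the 95% limits).
#' @return object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, plus `means`/`differences` for plotting.
#' @export
bland_altman <- function(table, loa_multiplier = 1.96) {
  d <- table$device - table$reference
  n <- length(d)
  if (n < 2L) stop_spermfx("need at least 2 pairs", "insufficient_data_error")
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_multiplier * sd_diff,
                 loa_high = bias + loa_multiplier * sd_diff,
                 loa_multiplier = loa_multiplier, n = n,
                 means = (table$device + table$reference) / 2,
                 differences = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman_result> bias %.2f, SD %.2f, LOA %.2f to %.2f, n = %d\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Confusion matrix at a score threshold
#'
#' Both methods classify a sample positive when its score lies strictly
#' below the threshold; the reference (manual) classification is the truth.
#'
#' @param table a [measurement_table()].
#' @param threshold score cutoff (default 80).
#' @return object of class `confusion_matrix`: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(table, threshold = 80) {
  truth <- table$reference < threshold
  pred <- table$device < threshold
  confusion_matrix(tp = sum(truth & pred), fp = sum(!truth & pred),
                   fn = sum(truth & !pred), tn = sum(!truth & !pred))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,fn,tn non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_spermfx("confusion counts must be non-negative integers", "parameter_error")
  structure(as.list(counts), class = "confusion_matrix")
}

#' Exact (Clopper--Pearson) binomial confidence interval
#'
#' Inverts the binomial tails via Beta quantiles:
#' lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with lower = 0 at k = 0 and upper = 1 at k = n.
#'
#' @param k successes (0..n).
#' @param n trials (>= 1).
#' @param confidence confidence level (default 0.95).
#' @return length-2 vector (lower, upper) on the 0--1 scale.
#' @export
clopper_pearson <- function(k, n, confidence = 0.95) {
  if (n < 1 || k < 0 || k > n)
    stop_spermfx("require 0 <= k <= n, n >= 1", "parameter_error")
  a <- 1 - confidence
  lower <- if (k == 0) 0 else qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - a / 2, k + 1, n - k)
  c(lower, upper)
}

#' Diagnostic metrics with exact confidence intervals
#'
#' Sensitivity, specificity and accuracy (percent) with exact
#' Clopper--Pearson confidence intervals. A metric whose margin is empty
#' (e.g. sensitivity with no positive samples) is returned as `NA` with a
#' warning; the remaining metrics are still computed.
#'
#' @param cm a [confusion_matrix()].
#' @param confidence confidence level (default 0.95).
#' @return object of class `diagnostic_metrics`: for each of
#'   `sensitivity`, `specificity`, `accuracy` the estimate (percent) and
#'   `*_ci` (percent).
#' @export
diagnostic_metrics <- function(cm, confidence = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  if (n == 0) stop_spermfx("empty confusion matrix", "insufficient_data_error")
  met <- function(k, m, what) {
    if (m == 0) {
      warning(sprintf("%s undefined: empty margin", what), call. = FALSE)
      return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    }
    list(est = 100 * k / m, ci = 100 * clopper_pearson(k, m, confidence))
  }
  sens <- met(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- met(cm$tn, cm$tn + cm$fp, "specificity")
  acc <- met(cm$tp + cm$tn, n, "accuracy")
  structure(list(sensitivity = sens$est, sensitivity_ci = sens$ci,
                 specificity = spec$est, specificity_ci = spec$ci,
                 accuracy = acc$est, accuracy_ci = acc$ci,
                 n = n, confidence = confidence),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(e, ci) sprintf("%.2f%% (%.2f to %.2f)", e, ci[1], ci[2])
  cat("<diagnostic_metrics>\n")
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  cat("  accuracy:   ", fmt(x$accuracy, x$accuracy_ci), "\n")
  invisible(x)
}

#' ROC AUC with DeLong confidence interval
#'
#' Truth labels come from the reference score (< threshold is positive);
#' the predictor is oriented as 100 - device score, so a lower device score
#' ranks a sample as more likely positive. The AUC is the Mann--Whitney
#' statistic (ties counted 1/2, via midranks); its variance is estimated by
#' the DeLong placement method and the CI truncated to \[0, 1\].
#'
#' @param table a [measurement_table()].
#' @param threshold_for_truth reference cutoff defining the positive class
#'   (default 80).
#' @param confidence confidence level (default 0.95).
#' @return object of class `roc_auc_result`: `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(table, threshold_for_truth = 80, confidence = 0.95) {
  truth <- table$reference < threshold_for_truth
  if (all(truth) || !any(truth))
    stop_spermfx("both classes must be present", "undefined_auc_error")
  pred <- 100 - table$device
  pos <- pred[truth]; neg <- pred[!truth]
  n1 <- length(pos); n2 <- length(neg)
  r_all <- rank(c(pos, neg))
  # DeLong placements
  V10 <- (r_all[seq_len(n1)] - rank(pos)) / n2
  V01 <- 1 - (r_all[n1 + seq_len(n2)] - rank(neg)) / n1
  # rank-sum form: numerator is the exact pair count (ties worth 1/2)
  auc <- (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  se <- sqrt(var(V10) / n1 + var(V01) / n2)
  z <- qnorm((1 + confidence) / 2)
  ci <- clamp(auc + c(-1, 1) * z * se, 0, 1)
  structure(list(auc = auc, auc_ci = ci, se = se, n_pos = n1, n_neg = n2,
                 confidence = confidence),
            class = "roc_auc_result")
}

#' @export
print.roc_auc_result <- function(x, ...) {
  cat(sprintf("<roc_auc_result> AUC %.2f (%.2f to %.2f); %d positive, %d negative\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Full method-comparison report for a paired-measurement table
#'
#' Runs the selected analyses and bundles them into one
#' [analysis_report()]-backed object.
#'
#' @param table a [measurement_table()].
#' @param analyses subset of `c("ols", "pb", "ba", "diag", "roc")`.
#' @param threshold classification/truth threshold (default 80).
#' @param confidence confidence level (default 0.95).
#' @return object of class `method_comparison_report` holding the
#'   individual fit objects plus a flat `report`.
#' @export
compare_methods <- function(table, analyses = c("ols", "pb", "ba", "diag", "roc"),
                            threshold = 80, confidence = 0.95) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  out <- list(n = nrow(table))
  results <- list(n = nrow(table))
  if ("ols" %in% analyses) {
    out$ols <- ols_regression(table, confidence)
    results <- c(results, list(ols_slope = out$ols$slope,
                               ols_intercept = out$ols$intercept,
                               ols_r_squared = out$ols$r_squared))
  }
  if ("pb" %in% analyses) {
    out$pb <- passing_bablok(table, confidence)
    results <- c(results, list(pb_slope = out$pb$slope,
                               pb_intercept = out$pb$intercept,
                               pb_cusum_p = out$pb$cusum_p))
  }
  if ("ba" %in% analyses) {
    out$ba <- bland_altman(table)
    results <- c(results, list(ba_bias = out$ba$bias, ba_sd = out$ba$sd_diff,
                               ba_loa_low = out$ba$loa_low,
                               ba_loa_high = out$ba$loa_high))
  }
  if ("diag" %in% analyses) {
    out$confusion <- confusion_at_threshold(table, threshold)
    out$diag <- diagnostic_metrics(out$confusion, confidence)
    results <- c(results, list(sensitivity = out$diag$sensitivity,
                               specificity = out$diag$specificity,
                               accuracy = out$diag$accuracy))
  }
  if ("roc" %in% analyses) {
    out$roc <- tryCatch(roc_auc(table, threshold, confidence),
                        spermfx_undefined_auc_error = function(e) NULL)
    if (!is.null(out$roc)) results <- c(results, list(auc = out$roc$auc))
  }
  out$report <- analysis_report(
    "comparison",
    parameters = list(analyses = analyses, threshold = threshold,
                      confidence = confidence),
    results = results)
  structure(out, class = "method_comparison_report")
}

#' @export
print.method_comparison_report <- function(x, ...) {
  cat(sprintf("<method_comparison_report> n = %d\n", x$n))
  for (nm in intersect(c("ols", "pb", "ba", "diag", "roc"), names(x)))
    print(x[[nm]])
  invisible(x)
}
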