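#' Mean absolute error
#'
#' @param y,y_hat equal-length numeric vectors of actual and predicted values.
#' @return `mean(|y - y_hat|)`.
#' @export
mae <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) == 0L) stop("empty input")
  mean(abs(y - y_hat))
}

#' Normalized mean squared error
#'
#' Squared prediction error relative to the target's variance around its
#' mean: `sum((y - y_hat)^2) / sum((y - mean(y))^2)`. The mean predictor
#' scores exactly 1.
#'
#' @inheritParams mae
#' @return The NMSE.
#' @export
nmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2L) stop("need at least 2 observations")
  denom <- sum((y - mean(y))^2)
  if (denom == 0) stop("constant targets: NMSE undefined")
  sum((y - y_hat)^2) / denom
}

#' Coefficient of determination
#'
#' Defined as `1 - nmse(y, y_hat)` exactly, so the identity `r2 + nmse = 1`
#' holds for every input.
#'
#' @inheritParams mae
#' @return The R-squared (can be negative for predictors worse than the
#'   mean).
#' @export
r2_score <- function(y, y_hat) 1 - nmse(y, y_hat)

#' Bland-Altman agreement
#'
#' Differences `d = y_hat - y`; bias is their mean, the limits of agreement
#' are `bias +/- 1.96 * sd(d)` (sample sd), and coverage is the fraction of
#' differences inside the closed limits.
#'
#' @inheritParams mae
#' @return List with `bias`, `lower`, `upper`, `coverage`.
#' @export
bland_altman <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 3L) stop("need at least 3 observations")
  d <- y_hat - y
  bias <- mean(d)
  s <- stats::sd(d)
  lower <- bias - 1.96 * s
  upper <- bias + 1.96 * s
  list(bias = bias, lower = lower, upper = upper,
       coverage = mean(d >= lower & d <= upper))
}

#' Full evaluation report
#'
#' MAE, NMSE, R2 (the exact complement of NMSE), Bland-Altman agreement and
#' a Shapiro-Wilk residual-normality p-value (reported descriptively, never
#' used as a gate).
#'
#' @inheritParams mae
#' @return An object of class `dstage_eval_report`.
#' @export
eval_report <- function(y, y_hat) {
  ba <- bland_altman(y, y_hat)
  d <- y_hat - y
  sw <- if (length(d) >= 3L && length(d) <= 5000L && stats::sd(d) > 0)
    tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  else NA_real_
  rep <- list(mae = mae(y, y_hat), nmse = nmse(y, y_hat),
              r2 = r2_score(y, y_hat), bland_altman = ba,
              shapiro_p = sw, n = length(y))
  class(rep) <- "dstage_eval_report"
  rep
}

#' @export
print.dstage_eval_report <- function(x, ...) {
  cat(sprintf("n=%d  MAE=%.4g  NMSE=%.4g  R2=%.4g\n", x$n, x$mae, x$nmse, x$r2))
  cat(sprintf("Bland-Altman: bias=%.4g, limits [%.4g, %.4g], coverage %.1f%%\n",
              x$bland_altman$bias, x$bland_altman$lower, x$bland_altman$upper,
              100 * x$bland_altman$coverage))
  if (!is.na(x$shapiro_p))
    cat(sprintf("Shapiro-Wilk residual normality p=%.4g\n", x$shapiro_p))
  invisible(x)
}

#' Paired multi-seed comparison of two models
#'
#' Paired t-test on per-seed metric differences with Bonferroni adjustment
#' over the declared family of comparisons. Zero-variance differences are
#' flagged degenerate and yield no decision.
#'
#' @param metric_a,metric_b equal-length numeric vectors of a metric,
#'   paired by seed.
#' @param alpha family-wise significance level.
#' @param n_comparisons size of the comparison family for the Bonferroni
#'   adjustment.
#' @return List with `t`, `df`, `p_value`, `alpha_adjusted`, `significant`
#'   (logical or `NA` when degenerate), `degenerate`, `mean_diff`.
#' @export
compare_runs <- function(metric_a, metric_b, alpha = 0.05, n_comparisons = 1L) {
  if (length(metric_a) != length(metric_b)) stop("length mismatch")
  if (length(metric_a) < 2L) stop("need at least 2 paired runs")
  d <- metric_a - metric_b
  if (stats::sd(d) == 0) {
    if (all(d == 0))   # identical runs: no difference to test
      return(list(t = 0, df = length(d) - 1L, p_value = 1,
                  alpha_adjusted = alpha / n_comparisons, significant = FALSE,
                  degenerate = FALSE, mean_diff = 0))
    return(list(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                alpha_adjusted = alpha / n_comparisons, significant = NA,
                degenerate = TRUE, mean_diff = mean(d)))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  adj <- alpha / n_comparisons
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, alpha_adjusted = adj,
       significant = tt$p.value < adj, degenerate = FALSE,
       mean_diff = mean(d))
}
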