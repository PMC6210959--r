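#' Root-mean-square error
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n}\sum_i (\hat Y_i - Y_i)^2}}, in the
#' units of the target (ug/L for chlorophyll-a).
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) == 0L)
    stop("rmse(): lengths must match and be nonzero", call. = FALSE)
  sqrt(mean((yhat - y)^2))
}

#' Model efficiency (Nash-Sutcliffe form R-squared)
#'
#' \eqn{R^2 = 1 - \sum_i (Y_i - \hat Y_i)^2 / \sum_i (Y_i - \bar Y)^2}: the
#' coefficient of determination computed against predictions, the standard
#' skill score in hydrology. It equals 1 for perfect prediction, 0 for a
#' model no better than the observed mean, and can be negative. A
#' squared-Pearson-correlation variant is available via
#' `method = "pearson"`.
#'
#' @param y observed values (length >= 2, not constant).
#' @param yhat predicted values.
#' @param method `"nse"` (default, 1 - SSE/SStot) or `"pearson"`
#'   (squared product-moment correlation).
#' @return scalar, at most 1 for `"nse"`.
#' @export
r_squared <- function(y, yhat, method = c("nse", "pearson")) {
  method <- match.arg(method)
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("r_squared(): need equal lengths >= 2", call. = FALSE)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0)
    stop("r_squared(): observed values are constant (undefined denominator)",
         call. = FALSE)
  if (method == "pearson") return(stats::cor(y, yhat)^2)
  1 - sum((y - yhat)^2) / sstot
}

#' Akaike information criterion (Gaussian least-squares form)
#'
#' \eqn{\mathrm{AIC} = n \ln(\mathrm{SSE}/n) + 2k}, the form appropriate for
#' models fitted by least squares under a Gaussian error likelihood. `k` is
#' the fitted-parameter count: `L` for an ELM (only the output weights are
#' estimated), `d + 1` for multiple linear regression, `r (d + 1)` for a
#' first-order ANFIS with `r` rules (consequent coefficients).
#'
#' @param n number of observations (> 0).
#' @param sse residual sum of squares (> 0; a numerically perfect fit has no
#'   finite AIC in this form and is rejected rather than reported as -Inf).
#' @param k fitted-parameter count (>= 0).
#' @return scalar.
#' @export
aic_score <- function(n, sse, k) {
  if (n <= 0) stop("aic_score(): n must be > 0", call. = FALSE)
  if (!is.finite(sse) || sse <= 0)
    stop("aic_score(): sse must be > 0 (perfect fit is flagged, not -Inf)",
         call. = FALSE)
  if (k < 0) stop("aic_score(): k must be >= 0", call. = FALSE)
  n * log(sse / n) + 2 * k
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] with the domain checks used for the
#' nutrient-vs-chlorophyll screening (n >= 3, non-constant inputs).
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return scalar in `[-1, 1]`.
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("pearson_corr(): need equal lengths >= 3", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("pearson_corr(): constant input (undefined)", call. = FALSE)
  stats::cor(a, b)
}

#' Per-variable descriptive statistics of a site series
#'
#' Mean, minimum and maximum for each weekly variable — the standard
#' "Average (Min.-Max.)" monitoring-summary layout.
#'
#' @param series a `"site_series"`.
#' @return data frame with columns `variable, mean, min, max`.
#' @export
descriptive_stats <- function(series) {
  stopifnot(inherits(series, "site_series"))
  df <- as.data.frame(series)
  if (nrow(df) == 0L) stop("descriptive_stats(): empty series", call. = FALSE)
  rows <- lapply(WEEKLY_COLS, function(v) {
    x <- df[[v]][is.finite(df[[v]])]
    if (length(x) == 0L)
      stop("descriptive_stats(): no data for variable ", v, call. = FALSE)
    data.frame(variable = v, mean = mean(x), min = min(x), max = max(x))
  })
  do.call(rbind, rows)
}
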