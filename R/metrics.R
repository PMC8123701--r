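#' Classification accuracy (percent)
#'
#' Share of predictions matching the observed class, times 100.
#'
#' @param observed,predicted Equal-length vectors of class labels.
#' @return Percentage in [0, 100].
#' @export
accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0)
    stop_input("observed and predicted must be equal-length, non-empty")
  mean(observed == predicted) * 100
}

#' Mean absolute percentage error (percent)
#'
#' MAPE = mean(|observed - predicted| / |observed|) x 100. Undefined when any
#' observed value is zero; this raises an error rather than fudging with an
#' epsilon (risk indices are >= 6, so the regression model is always safe).
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Percentage >= 0.
#' @export
mape <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0)
    stop_input("observed and predicted must be equal-length, non-empty")
  if (any(observed == 0))
    stop_input("MAPE undefined: observed contains zero(s)")
  mean(abs((observed - predicted) / observed)) * 100
}

#' Squared product-moment correlation between observed and predicted
#'
#' The squared Pearson correlation form of R^2. Note the sharp edge this form
#' carries: any affine relation predicted = a * observed + b gives R^2 = 1,
#' including a < 0 (a perfectly anti-correlated predictor also scores 1).
#'
#' @param observed,predicted Equal-length numeric vectors with nonzero
#'   variance each.
#' @return Value in [0, 1].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop_input("observed and predicted must be equal-length, n >= 2")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop_input("R^2 undefined: zero variance in observed or predicted")
  stats::cor(observed, predicted)^2
}

#' Interpretation band for a MAPE value
#'
#' Standard forecasting-quality bands: below 10% highly accurate, 10-20%
#' good, above 20% up to 50% reasonable, above 50% inaccurate. The bands are
#' implemented gap-free — [0, 10), [10, 20], (20, 50], (50, Inf) — so every
#' value maps to exactly one band (a 10.2% MAPE is "good forecasting").
#'
#' @param value MAPE percentage (>= 0).
#' @return One of "highly accurate", "good", "reasonable", "inaccurate".
#' @export
interpret_mape <- function(value) {
  if (value < 0) stop_input("MAPE cannot be negative")
  if (value < 10) "highly accurate"
  else if (value <= 20) "good"
  else if (value <= 50) "reasonable"
  else "inaccurate"
}

#' Aggregate per-experiment metric values
#'
#' Arithmetic mean with a display-rounding convention: half-up at the given
#' number of decimals (matching report tables where e.g. 72.5% prints as
#' 73%). The exact mean is always returned alongside.
#'
#' @param values Numeric vector of per-experiment values.
#' @param digits Display decimals (default 1).
#' @return List with `mean` (exact) and `display` (half-up rounded).
#' @export
aggregate_metric <- function(values, digits = 1) {
  if (length(values) == 0) stop_input("need at least one value")
  m <- mean(values)
  list(mean = m, display = round_half_up(m, digits))
}
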