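# Model evaluation statistics and the standardized water stress index.

#' Root mean squared error
#'
#' `sqrt(mean((predicted - observed)^2))`, in the units of the variable.
#'
#' @param predicted,observed Numeric vectors of equal length (n >= 1).
#' @return RMSE (>= 0, 0 iff the series are identical).
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (length(predicted) < 1) stop("need at least one pair")
  sqrt(mean((predicted - observed)^2))
}

#' Mean residual error (percentage difference)
#'
#' `(simulated - observed) / observed * 100`: positive values are
#' overestimates.
#'
#' @param simulated,observed Scalar (or vector) values; `observed` must be
#'   non-zero.
#' @return Percentage difference.
#' @export
mean_residual_error <- function(simulated, observed) {
  if (any(observed == 0)) stop("observed value of zero: MR undefined")
  (simulated - observed) / observed * 100
}

#' Weighted root mean squared error
#'
#' `sqrt(sum(w * (P - O)^2) / sum(w))`. The square root keeps the statistic
#' in the variable's units (so a WRMSE on yields is reported in kg ha-1);
#' `apply_root = FALSE` gives the plain weighted mean of squared errors
#' instead.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param weights Positive weights, same length.
#' @param apply_root Take the square root (default TRUE).
#' @return WRMSE; equals [rmse()] under equal weights.
#' @export
wrmse <- function(predicted, observed, weights, apply_root = TRUE) {
  if (length(predicted) != length(observed) ||
      length(predicted) != length(weights)) stop("length mismatch")
  if (any(weights <= 0)) stop("weights must be > 0")
  m <- sum(weights * (predicted - observed)^2) / sum(weights)
  if (apply_root) sqrt(m) else m
}

#' Coefficient of variation
#'
#' Sample standard deviation over the mean, as a percentage.
#'
#' @param x Numeric vector (n >= 2, non-zero mean).
#' @return CV in percent.
#' @export
cv <- function(x) {
  if (length(x) < 2) stop("need at least two values")
  m <- mean(x)
  if (m == 0) stop("zero mean: CV undefined")
  stats::sd(x) / m * 100
}

#' Standardized water stress index
#'
#' For each year the water stress is the growing-season transpiration minus
#' precipitation, `WS = Ta - p` (mm yr-1); the index is the z-score of WS
#' against the multi-year baseline, `(WS - mean(WS)) / sd(WS)` (sample
#' standard deviation). Positive values indicate drier-than-average stress
#' conditions (more water lost through transpiration relative to supply).
#'
#' @param annual_ta Growing-season transpiration per year (mm).
#' @param annual_p Growing-season precipitation per year (mm).
#' @return Numeric sWSI series with sample mean 0 and sd 1 over the
#'   baseline.
#' @export
swsi <- function(annual_ta, annual_p) {
  if (length(annual_ta) != length(annual_p)) stop("length mismatch")
  if (length(annual_ta) < 2) stop("need at least two years")
  ws <- annual_ta - annual_p
  s <- stats::sd(ws)
  if (s == 0) stop("degenerate water-stress series: zero standard deviation")
  (ws - mean(ws)) / s
}

#' Correlate an annual outcome with the sWSI
#'
#' Pearson correlation with a two-sided p-value from the t distribution on
#' n - 2 degrees of freedom; significance is flagged at p < 0.05.
#'
#' @param outcome Annual outcome series (yield, AGB, ...).
#' @param swsi Annual sWSI series, same length (>= 3).
#' @return List with `r`, `p_value`, `significant`.
#' @export
correlate_with_swsi <- function(outcome, swsi) {
  if (length(outcome) != length(swsi)) stop("length mismatch")
  if (length(outcome) < 3) stop("need at least three years")
  if (stats::sd(outcome) == 0 || stats::sd(swsi) == 0)
    stop("zero-variance input: correlation undefined")
  ct <- stats::cor.test(outcome, swsi, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       significant = ct$p.value < 0.05)
}
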