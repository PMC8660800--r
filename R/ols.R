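# Closed-form simple linear regression, shared by every decay fit in the
# package (log-linear mRNA/protein decay, tail-length vs time). Kept minimal
# and allocation-free because the RNA-seq pipeline calls it once per
# gene x condition.

#' Ordinary least squares of y on x (single predictor)
#'
#' Returns slope, intercept, coefficient of determination and the standard
#' error of the slope, computed from the normal equations. `r2` is `NA` when
#' the response is constant (zero total sum of squares).
#'
#' @param x,y Numeric vectors of equal length (>= 2 distinct `x`).
#' @return A list with `n`, `intercept`, `slope`, `r2`, `se_slope`.
#' @keywords internal
#' @noRd
ols_fit <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2L)
  xbar <- mean(x)
  ybar <- mean(y)
  dx <- x - xbar
  sxx <- sum(dx * dx)
  if (sxx <= 0) stop("all x values identical; cannot fit a slope")
  slope <- sum(dx * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  ssr <- sum(res * res)
  sst <- sum((y - ybar)^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  se_slope <- if (n > 2L) sqrt(ssr / (n - 2L) / sxx) else NA_real_
  list(n = n, intercept = intercept, slope = slope, r2 = r2,
       se_slope = se_slope)
}

#' Half-life from a first-order decay slope
#'
#' Under first-order kinetics the log-abundance slope `b` (per hour) gives
#' t1/2 = ln(2) / -b. Non-negative slopes (no decay) map to `Inf`.
#'
#' @param slope Slope of log abundance versus time, per hour.
#' @return Half-life in hours; `Inf` when `slope >= 0`.
#' @export
#' @examples
#' halflife_from_slope(-log(2))   # 1 hour
#' halflife_from_slope(0)         # Inf: no decay
halflife_from_slope <- function(slope) {
  ifelse(slope < 0, log(2) / -slope, Inf)
}
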