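# First-order decay fits for low-dimensional time series: qPCR / northern
# chases normalized to a stable reference RNA, and CHX-chase protein decay
# normalized to a loading control.

#' Normalize a target/reference abundance series
#'
#' Computes target/reference ratios and rescales them to 1 at t = 0, the
#' conventional presentation of a chase normalized to 18S rRNA (mRNA) or
#' tubulin (protein).
#'
#' @param series Data frame with columns `time_h`, `target`,
#'   `reference_signal` (all reference signals > 0; a t = 0 point required).
#' @return Data frame with `time_h` and `ratio` (1 at t = 0).
#' @export
normalize_series <- function(series) {
  req <- c("time_h", "target", "reference_signal")
  if (!all(req %in% names(series)))
    stop("series needs columns: ", paste(req, collapse = ", "))
  if (any(series$reference_signal <= 0))
    stop("reference signal must be > 0 at every point")
  i0 <- which(series$time_h == 0)
  if (length(i0) == 0) stop("series has no t = 0 point")
  ratio <- series$target / series$reference_signal
  data.frame(time_h = series$time_h, ratio = ratio / mean(ratio[i0]))
}

#' Fit a first-order decay curve y = a * exp(b * t)
#'
#' Fitted by linear regression of log ratios on time (the log-linear reading
#' of an exponential fit "by linear regression"); `a = exp(intercept)` and
#' t1/2 = ln(2)/-b. Half-lives beyond the observation window are flagged as
#' censored and reported as a bound ("> T h") rather than a point estimate.
#' A nonlinear least-squares alternative (`method = "nls"`, via
#' [stats::nls()]) is available for sensitivity analysis.
#'
#' @param time_h Time in hours.
#' @param ratio Normalized abundance ratios (> 0 for fitted points; zeros are
#'   dropped, >= 3 positive points required).
#' @param method `"loglinear"` (default) or `"nls"`.
#' @return A list of class `exp_fit`: `a`, `b` (per hour), `halflife_h`,
#'   `r2`, `censored`, `label` (e.g. `"> 6 h"` when censored), `n_points`.
#' @export
fit_first_order <- function(time_h, ratio, method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(length(time_h) == length(ratio))
  keep <- ratio > 0
  t <- time_h[keep]
  v <- ratio[keep]
  if (length(v) < 3L)
    stop("need >= 3 positive points to fit a decay curve")
  if (method == "loglinear") {
    fit <- ols_fit(t, log(v))
    a <- exp(fit$intercept)
    b <- fit$slope
    r2 <- fit$r2
  } else {
    start <- ols_fit(t, log(v))
    nl <- stats::nls(v ~ a * exp(b * t),
                     start = list(a = exp(start$intercept), b = start$slope))
    cf <- stats::coef(nl)
    a <- unname(cf["a"])
    b <- unname(cf["b"])
    r2 <- 1 - sum(stats::residuals(nl)^2) / sum((v - mean(v))^2)
  }
  hl <- halflife_from_slope(b)
  censored <- !is.finite(hl) || hl > max(t)
  structure(list(a = a, b = b, halflife_h = hl, r2 = r2, censored = censored,
                 label = if (censored) sprintf("> %g h", max(t))
                         else sprintf("%.3g h", hl),
                 n_points = length(v)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("First-order decay fit: t1/2 = %s (b = %.4g /h, R2 = %.3f, n = %d)\n",
              x$label, x$b, ifelse(is.na(x$r2), NaN, x$r2), x$n_points))
  invisible(x)
}

#' Fit a normalized targeted series end to end
#'
#' Convenience wrapper: [normalize_series()] then [fit_first_order()].
#'
#' @param series See [normalize_series()].
#' @param ... Passed to [fit_first_order()].
#' @return An `exp_fit`.
#' @export
fit_series <- function(series, ...) {
  ns <- normalize_series(series)
  fit_first_order(ns$time_h, ns$ratio, ...)
}
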