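# In vitro deadenylation kinetics from gel lane densitometry: marker
# calibration, most-abundant-intermediate extraction, apparent rate by
# linear regression of tail length on time, and fold inhibition.

#' Calibrate gel migration position to fragment length
#'
#' Builds a strictly monotone piecewise-linear interpolation of total
#' fragment length (nt) against migration position from an RNA size-marker
#' table. Positions outside the marker range are clamped to the endpoint
#' lengths; denaturing PAGE mobility is only locally linear in length, so no
#' global linear model is assumed.
#'
#' @param markers Data frame with columns `position` and `tail_nt` (total
#'   fragment length in nucleotides); >= 2 bands, strictly monotone.
#' @return A list of class `tail_calibration` with `markers`, `map`
#'   (function position -> length nt) and the calibrated `range`.
#' @export
calibrate <- function(markers) {
  if (!all(c("position", "tail_nt") %in% names(markers)))
    stop("marker table needs columns `position` and `tail_nt`")
  if (nrow(markers) < 2) stop("need >= 2 marker bands")
  m <- markers[order(markers$position), , drop = FALSE]
  d <- diff(m$tail_nt)
  if (any(d == 0) || (any(d > 0) && any(d < 0)))
    stop("marker table is not strictly monotone")
  map <- approxfun(m$position, m$tail_nt, rule = 2)
  structure(list(markers = m, map = map,
                 range = range(m$position)),
            class = "tail_calibration")
}

# rolling-minimum baseline, then clamp at zero
subtract_background <- function(intensity, window = 21L) {
  n <- length(intensity)
  if (window <= 1L || n <= window) return(pmax(intensity - min(intensity), 0))
  half <- window %/% 2L
  base <- vapply(seq_len(n), function(i)
    min(intensity[max(1L, i - half):min(n, i + half)]), 0)
  pmax(intensity - base, 0)
}

#' Most abundant deadenylation intermediate in one lane
#'
#' Subtracts a rolling-minimum background from the line scan, restricts to
#' the calibrated region of the gel, takes the global intensity maximum, maps
#' its position to fragment length and subtracts the RNA body length to
#' express the result in adenosines, rounded to the nearest whole A since
#' deadenylation intermediates form a discrete single-nucleotide ladder.
#' Ties in intensity are broken toward the
#' longer tail (the earlier intermediate), a deterministic and conservative
#' rule that underestimates rather than overestimates the rate.
#'
#' @param lane Data frame with columns `position` (strictly increasing) and
#'   `intensity`.
#' @param cal A [calibrate()] result.
#' @param body_nt RNA body length in nucleotides (default 7).
#' @param bg_window Rolling-minimum window (positions) for background
#'   subtraction; 0 disables it.
#' @return Tail length in adenosines (>= 0).
#' @export
most_abundant_tail <- function(lane, cal, body_nt = 7, bg_window = 21L) {
  stopifnot(inherits(cal, "tail_calibration"))
  if (is.unsorted(lane$position, strictly = TRUE))
    stop("lane positions must be strictly increasing")
  inten <- if (bg_window > 0) subtract_background(lane$intensity, bg_window)
           else pmax(lane$intensity, 0)
  in_cal <- lane$position >= cal$range[1] & lane$position <= cal$range[2]
  if (!any(in_cal)) stop("calibrated region does not overlap the profile")
  inten <- inten[in_cal]
  pos <- lane$position[in_cal]
  if (all(inten <= 0)) stop("lane profile is all zero after background subtraction")
  peak <- which(inten == max(inten))
  lens <- cal$map(pos[peak])
  tail_nt <- max(lens)                     # tie -> longer fragment
  round(max(0, tail_nt - body_nt))
}

#' Extract the tail-length time series from a set of lanes
#'
#' @param lanes List of lane data frames, each with a `time_min` attribute
#'   (as produced by [simulate_lane_profiles()]), or provide `times_min`.
#' @param cal A [calibrate()] result.
#' @param times_min Optional numeric vector of lane times, overriding
#'   attributes.
#' @param ... Passed to [most_abundant_tail()].
#' @return Data frame of class `tail_series` with `time_min` and `tail_As`.
#' @export
tail_series <- function(lanes, cal, times_min = NULL, ...) {
  if (is.null(times_min))
    times_min <- vapply(lanes, function(l) attr(l, "time_min"), 0)
  stopifnot(length(times_min) == length(lanes))
  out <- data.frame(
    time_min = times_min,
    tail_As = vapply(lanes, most_abundant_tail, 0, cal = cal, ...))
  class(out) <- c("tail_series", "data.frame")
  out
}

#' Apparent deadenylation rate from a tail-length time series
#'
#' Linear regression of most-abundant tail length on time over the
#' pre-plateau window; the apparent rate (As/min) is the negative slope.
#' Once the substrate is fully deadenylated the modal tail sits at the body
#' band and further lanes carry no kinetic information, so points after the
#' series first reaches `plateau_As` are excluded (the first such point is
#' kept as the end of the linear phase).
#'
#' @param series A [tail_series()] or data frame with `time_min`, `tail_As`.
#' @param plateau_As Tail length (As) at or below which the reaction is
#'   considered complete (default 1).
#' @return A list of class `rate_estimate`: `rate_As_per_min` (>= 0; a
#'   positive slope is clamped to 0 with a warning), `slope`, `intercept`,
#'   `r2`, `se`, `n_points`.
#' @export
estimate_rate <- function(series, plateau_As = 1) {
  t <- series$time_min
  tail <- series$tail_As
  hit <- which(tail <= plateau_As)
  keep <- if (length(hit) > 0) seq_len(min(hit)) else seq_along(t)
  if (length(keep) < 3) stop("need >= 3 pre-plateau points")
  fit <- ols_fit(t[keep], tail[keep])
  rate <- -fit$slope
  if (rate < 0) {
    warning("positive tail-vs-time slope; reporting rate 0")
    rate <- 0
  }
  structure(list(rate_As_per_min = rate, slope = fit$slope,
                 intercept = fit$intercept, r2 = fit$r2, se = fit$se_slope,
                 n_points = fit$n),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Apparent deadenylation rate: %.3g +/- %.2g As/min (R2 = %.3f, n = %d)\n",
              x$rate_As_per_min, x$se, x$r2, x$n_points))
  invisible(x)
}

#' Fold reduction of the deadenylation rate
#'
#' Ratio of a reference (e.g. CCR4-NOT alone) to a test (e.g. plus inhibitor)
#' apparent rate, with the standard error propagated from both fits. A test
#' rate of zero yields a lower bound `reference / se_test` instead of
#' infinity.
#'
#' @param rate_reference,rate_test [estimate_rate()] results, or bare
#'   numeric rates (then no SE is propagated).
#' @return A list of class `fold_inhibition`: `fold`, `se`, `bound`
#'   (`TRUE` when only a lower bound could be computed), `label`.
#' @export
fold_inhibition <- function(rate_reference, rate_test) {
  get <- function(x) if (inherits(x, "rate_estimate"))
    c(x$rate_As_per_min, x$se) else c(as.numeric(x), NA_real_)
  ref <- get(rate_reference)
  tst <- get(rate_test)
  if (tst[1] <= 0) {
    if (is.na(tst[2]) || tst[2] <= 0)
      stop("test rate is zero and has no standard error to bound against")
    bound <- ref[1] / tst[2]
    return(structure(list(fold = bound, se = NA_real_, bound = TRUE,
                          label = sprintf("> %.3g", bound)),
                     class = "fold_inhibition"))
  }
  fold <- ref[1] / tst[1]
  se <- if (any(is.na(c(ref[2], tst[2])))) NA_real_
        else fold * sqrt((ref[2] / ref[1])^2 + (tst[2] / tst[1])^2)
  structure(list(fold = fold, se = se, bound = FALSE,
                 label = sprintf("%.3g-fold", fold)),
            class = "fold_inhibition")
}

#' @export
print.fold_inhibition <- function(x, ...) {
  cat(sprintf("Fold reduction in apparent rate: %s%s\n", x$label,
              if (!is.na(x$se)) sprintf(" +/- %.2g", x$se) else ""))
  invisible(x)
}

#' Quantify a complete simulated or measured deadenylation assay
#'
#' Calibrate, extract the modal tail per lane, and estimate the apparent
#' rate.
#'
#' @param lanes,markers Lane profiles and marker table (see [tail_series()],
#'   [calibrate()]).
#' @param ... Passed to [tail_series()].
#' @return A list with `series` and `rate`.
#' @export
quantify_deadenylation <- function(lanes, markers, ...) {
  cal <- calibrate(markers)
  ser <- tail_series(lanes, cal, ...)
  list(series = ser, rate = estimate_rate(ser))
}
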