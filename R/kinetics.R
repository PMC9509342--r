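# Max-slope estimators for bacterial growth rate and prophage induction
# rate from OD600 time series.

# max (or min) sliding-window least-squares slope of y against t
window_slope <- function(t, y, window_points, which = c("max", "min")) {
  which <- match.arg(which)
  n <- length(t)
  if (n < window_points)
    stop("insufficient data: need at least ", window_points, " points")
  slopes <- vapply(seq_len(n - window_points + 1L), function(i) {
    j <- i:(i + window_points - 1L)
    stats::cov(t[j], y[j]) / stats::var(t[j])
  }, 0)
  k <- if (which == "max") which.max(slopes) else which.min(slopes)
  list(slope = slopes[k], window_start = t[k],
       window_end = t[k + window_points - 1L])
}

kinetics_result <- function(rate, window_start, window_end, n_points) {
  structure(list(rate = rate, window_start = window_start,
                 window_end = window_end, n_points = n_points),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("rate = %.4g per hour (window %.2f-%.2f h, %d points)\n",
              x$rate, x$window_start, x$window_end, x$n_points))
  invisible(x)
}

#' Maximum bacterial growth rate from an OD600 series
#'
#' The natural log of the OD600 readings over time traces the growth
#' curve; the maximum slope over sliding windows of `window_points`
#' consecutive readings is the maximum growth rate (per hour). The
#' estimate is invariant to multiplying all OD values by a positive
#' constant. `window_points = 2` reduces to pairwise differences.
#'
#' @param series an [od_series()].
#' @param window_points points per regression window (default 4, i.e.
#'   1.5 h at 30-min sampling).
#' @return a `"kinetics_result"` with `rate` (per hour) and the window.
#' @export
#' @examples
#' s <- od_series(0:5, 0.05 * 2^(0:5))       # doubling every hour
#' max_growth_rate(s)$rate                   # log(2)
max_growth_rate <- function(series, window_points = 4L) {
  stopifnot(inherits(series, "od_series"))
  w <- window_slope(series$times, log(series$od), window_points, "max")
  kinetics_result(w$slope, w$window_start, w$window_end, window_points)
}

#' Maximal prophage induction rate from a mitomycin-C lysis curve
#'
#' The treated ODs are normalised by the untreated control; the natural
#' log of the ratio over time traces the lysis curve, whose steepest
#' decline is the maximal induction rate, reported as a positive
#' per-hour rate. Identical treated and control series give exactly 0.
#'
#' @param treated [od_series()] grown with mitomycin C.
#' @param control [od_series()] grown without, on the same time grid.
#' @param window_points points per regression window (default 4).
#' @return a `"kinetics_result"` with `rate` (per hour, >= 0) and the
#'   window of steepest decline.
#' @export
induction_rate <- function(treated, control, window_points = 4L) {
  stopifnot(inherits(treated, "od_series"))
  if (missing(control) || !inherits(control, "od_series"))
    stop("a control series (no mitomycin C) is required")
  if (length(treated$times) != length(control$times) ||
      any(abs(treated$times - control$times) > 1e-8))
    stop("treated and control series must share the same time grid")
  lr <- log(treated$od / control$od)
  w <- window_slope(treated$times, lr, window_points, "min")
  kinetics_result(max(0, -w$slope), w$window_start, w$window_end,
                  window_points)
}
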