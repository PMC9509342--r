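# Core p-tau selection test: frequency propagator G(x), sojourn-time
# spectrum T(x), summary statistics p = G(xf)/G(xm), tau = T(xf)/T(xm),
# and classification of the dominant selection mode.

# First generation time at which the interpolated path (g, f) reaches
# level x; exact sample-point hits return the sample time; NA if never.
# "logit" interpolates crossing times on the logit scale (exact for
# logistic selection trajectories, removing the near-fixation bias of
# frequency-linear chords at sparse sampling); segments starting at 0
# (below detection) fall back to frequency-linear. Frequencies are
# clamped to [eps, 1 - eps] before the logit.
first_crossing <- function(g, f, level,
                           interpolation = c("logit", "linear"),
                           eps = 1e-4) {
  interpolation <- match.arg(interpolation)
  if (f[1L] >= level) return(g[1L])
  n <- length(f)
  if (n < 2L) return(NA_real_)
  above <- f >= level
  if (!any(above)) return(NA_real_)
  i <- which(above)[1L]   # f[i-1] < level <= f[i]
  f0 <- f[i - 1L]; f1 <- f[i]
  if (interpolation == "linear" || f0 <= 0)
    return(g[i - 1L] + (g[i] - g[i - 1L]) * (level - f0) / (f1 - f0))
  q <- function(x) stats::qlogis(min(max(x, eps), 1 - eps))
  g[i - 1L] + (g[i] - g[i - 1L]) * (q(level) - q(f0)) / (q(f1) - q(f0))
}

#' Origination time of a trajectory at the establishment threshold
#'
#' The origination time is the generation at which the trajectory crossed
#' the establishment threshold `x0`. With the default
#' `method = "backcast"` it is inferred by backward linear extrapolation
#' of the first observed (detected, i.e. nonzero) trajectory segment,
#' clipped to `[0, first detected day]` — under a pool-seq detection
#' floor the crossing of `x0` typically predates the last
#' sampled-at-zero day, which the extrapolation reconstructs. With
#' `method = "interior"` the crossing is interpolated on the sampled
#' segment that straddles `x0` (the previous sampled day's frequency,
#' possibly 0, is taken at face value), clipped to that segment; backward
#' extrapolation is then used only when the very first sampled day is
#' already above `x0`. Both rules agree when only one detected point is
#' available or when observed points straddle `x0`.
#'
#' @param freq sampled frequencies of one mutation.
#' @param gens generation times of the sampling days (same length).
#' @param x0 establishment threshold (default 0.01).
#' @param method origination rule, `"backcast"` (default) or
#'   `"interior"`.
#' @return Origination time in generations, or `NA` if the trajectory
#'   never reaches `x0` (not established).
#' @export
#' @examples
#' origination_time(c(0, 0.2), c(0, 100))      # 5: crossing of 0.01 on the chord
#' origination_time(c(0.3, 0.5), c(0, 100))    # 0: clipped backward extrapolation
origination_time <- function(freq, gens, x0 = 0.01,
                             method = c("backcast", "interior")) {
  method <- match.arg(method)
  stopifnot(length(freq) == length(gens), x0 > 0, x0 < 1)
  if (max(freq) < x0) return(NA_real_)
  i <- which(freq >= x0)[1L]
  if (method == "backcast") {
    det <- which(freq > 0)
    d1 <- det[1L]
    if (freq[d1] >= x0) {
      # x0 is below the detection window: extrapolate the first observed
      # segment backward (requires a second, higher detected point)
      if (length(det) >= 2L && freq[det[2L]] > freq[d1]) {
        slope <- (freq[det[2L]] - freq[d1]) / (gens[det[2L]] - gens[d1])
        return(min(max(gens[d1] - (freq[d1] - x0) / slope, 0), gens[d1]))
      }
      if (d1 == 1L) return(gens[1L])
      return(gens[d1 - 1L] +
               (gens[d1] - gens[d1 - 1L]) * x0 / freq[d1])
    }
    # observed points straddle x0: interpolate as in "interior"
  }
  if (i == 1L) {
    if (length(freq) < 2L) return(gens[1L])
    slope <- (freq[2L] - freq[1L]) / (gens[2L] - gens[1L])
    if (slope <= 0) return(max(0, gens[1L]))
    return(max(0, gens[1L] - (freq[1L] - x0) / slope))
  }
  t <- gens[i - 1L] +
    (gens[i] - gens[i - 1L]) * (x0 - freq[i - 1L]) / (freq[i] - freq[i - 1L])
  min(max(t, gens[i - 1L]), gens[i])
}

#' First-passage time from origination to a target frequency
#'
#' Time between origination at `x0` and the first occurrence of the
#' interpolated trajectory at frequency `x`.
#'
#' @inheritParams origination_time
#' @param x target frequency, must exceed `x0`.
#' @param interpolation crossing-time interpolation, `"logit"` (default;
#'   exact for logistic trajectories) or `"linear"` (piecewise linear in
#'   frequency).
#' @return First-passage time in generations, or `NA` if the trajectory
#'   never reaches `x` (or is not established).
#' @export
first_passage_time <- function(freq, gens, x, x0 = 0.01,
                               interpolation = c("logit", "linear"),
                               method = c("backcast", "interior")) {
  if (x <= x0) stop("x must exceed x0 (use origination_time for x0 itself)")
  t0 <- origination_time(freq, gens, x0, method = method)
  if (is.na(t0)) return(NA_real_)
  tc <- first_crossing(gens, freq, x, interpolation = interpolation)
  if (is.na(tc)) return(NA_real_)
  tc - t0
}

default_ptau_grid <- function() c(seq(0.05, 0.95, by = 0.05), 0.99)

#' Frequency propagator G(x)
#'
#' `G(x)` is the probability that an established trajectory (one whose
#' interpolated maximum reaches the threshold `x0`) ever reaches frequency
#' `x`, estimated as the fraction of established trajectories whose
#' maximum is at least `x`. By construction `G` is non-increasing and
#' `G(x) = 1` for `x <= x0`.
#'
#' @param set a [trajectory_set()].
#' @param x0 establishment threshold (default 0.01).
#' @param grid increasing frequencies in (0, 1] on which to evaluate G.
#' @return An object of class `"propagator_curve"`: list with `x`, `G`,
#'   and `n_established`.
#' @export
frequency_propagator <- function(set, x0 = 0.01, grid = default_ptau_grid()) {
  stopifnot(inherits(set, "trajectory_set"), all(diff(grid) > 0),
            all(grid > 0), all(grid <= 1))
  if (n_mutations(set) == 0L) stop("empty trajectory set")
  maxf <- apply(set$freq, 1L, max)
  est <- maxf >= x0
  if (!any(est)) stop("no established trajectory (none reaches x0 = ", x0, ")")
  m <- maxf[est]
  G <- vapply(grid, function(x) mean(m >= x), 0)
  structure(list(x = grid, G = G, n_established = sum(est), x0 = x0),
            class = "propagator_curve")
}

#' @export
print.propagator_curve <- function(x, ...) {
  cat(sprintf("Frequency propagator G(x), %d established trajectories\n",
              x$n_established))
  print(data.frame(x = x$x, G = round(x$G, 4)), row.names = FALSE)
  invisible(x)
}

#' Sojourn-time spectrum T(x)
#'
#' `T(x)` is the mean first-passage time from origination at `x0` to
#' frequency `x`, averaged over the established trajectories that reach
#' `x`. Grid points no trajectory reaches carry `NA` and
#' `n_reaching = 0`.
#'
#' @inheritParams frequency_propagator
#' @inheritParams first_passage_time
#' @return An object of class `"sojourn_curve"`: list with `x`, `T`
#'   (generations) and `n_reaching`.
#' @export
sojourn_time_curve <- function(set, x0 = 0.01, grid = default_ptau_grid(),
                               interpolation = c("logit", "linear"),
                               method = c("backcast", "interior")) {
  stopifnot(inherits(set, "trajectory_set"))
  if (n_mutations(set) == 0L) stop("empty trajectory set")
  fps <- passage_matrix(set, grid, x0, match.arg(interpolation),
                        match.arg(method))
  Tm <- suppressWarnings(apply(fps, 2L, mean, na.rm = TRUE))
  Tm[!is.finite(Tm)] <- NA_real_
  structure(list(x = grid, T = Tm, n_reaching = colSums(!is.na(fps)), x0 = x0),
            class = "sojourn_curve")
}

# matrix of first-passage times: established trajectories x grid points
passage_matrix <- function(set, grid, x0, interpolation = "logit",
                          method = "backcast") {
  g <- generations(set)
  maxf <- apply(set$freq, 1L, max)
  est <- which(maxf >= x0)
  out <- matrix(NA_real_, nrow = length(est), ncol = length(grid))
  for (k in seq_along(est)) {
    f <- set$freq[est[k], ]
    t0 <- origination_time(f, g, x0, method = method)
    reach <- grid <= maxf[est[k]]
    for (j in which(reach)) {
      tc <- first_crossing(g, f, grid[j], interpolation = interpolation)
      out[k, j] <- tc - t0
    }
  }
  out
}

#' @export
print.sojourn_curve <- function(x, ...) {
  cat("Sojourn-time spectrum T(x) [generations]\n")
  print(data.frame(x = x$x, T = round(x$T, 1), n = x$n_reaching),
        row.names = FALSE)
  invisible(x)
}

#' The p-tau selection test
#'
#' Fits the joint fixation-probability / sojourn-time summary of a family
#' of mutation-frequency trajectories. `p = G(xf)/G(xm)` is the
#' probability that a mutation established at the intermediate frequency
#' `xm` reaches near-fixation at `xf`; `tau = T(xf)/T(xm)` is the
#' corresponding ratio of mean sojourn times. Under periodic selective
#' sweeps `p` is close to 1 and `tau` close to the logistic reference 2.0
#' (see [logistic_sojourn_ratio()]); under clonal interference `p < 1` and
#' `tau <= 2`; under diversifying (negative frequency-dependent)
#' selection `p << 1` and `tau >> 1`.
#'
#' When no trajectory reaches `xf`, `p = 0` and `tau` is replaced by its
#' end-of-experiment lower bound: the time from the mean origination of
#' the `xm`-reachers to the end of observation, divided by `T(xm)`
#' (`tau_is_lower_bound = TRUE`).
#'
#' @param set a [trajectory_set()].
#' @param x0 establishment threshold (default 0.01).
#' @param xm intermediate frequency (default 0.3).
#' @param xf near-fixation frequency (default 0.95).
#' @param grid frequency grid for the reported G/T curves.
#' @param min_generations_confident observation spans shorter than this
#'   (generations) are flagged `confident = FALSE` and classified
#'   `undetermined` (default 2000).
#' @param thresholds classification thresholds, see [mode_thresholds()].
#' @inheritParams first_passage_time
#' @return An object of class `"ptau"` with components `p`, `tau`,
#'   `tau_is_lower_bound`, `n_established`, `n_reached_xm`,
#'   `n_reached_xf`, `mode`, `confident`, `lambda` (exponential decay
#'   rate of G), the `propagator` and `sojourn` curves, and the
#'   configuration used. Methods: `print`, `summary`, `coef`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' sim <- simulate_directional(wf_params(N = 1e4, U = 1e-6, s_mean = 0.05,
#'                                       T_gen = 3000, seed = 1),
#'                             sampling_scheme(seq(0, 3000, 100),
#'                                             generations_per_day = 1))
#' if (n_mutations(sim) > 0) ptau(sim)
ptau <- function(set, x0 = 0.01, xm = 0.3, xf = 0.95,
                 grid = sort(unique(c(default_ptau_grid(), xm, xf))),
                 min_generations_confident = 2000,
                 thresholds = mode_thresholds(),
                 interpolation = c("logit", "linear"),
                 method = c("backcast", "interior")) {
  stopifnot(inherits(set, "trajectory_set"))
  interpolation <- match.arg(interpolation)
  method <- match.arg(method)
  if (!(x0 < xm && xm < xf && xf <= 1))
    stop("need x0 < xm < xf <= 1")
  g <- generations(set)
  span <- max(g) - min(g)
  confident <- span >= min_generations_confident
  maxf <- if (n_mutations(set)) apply(set$freq, 1L, max) else numeric()
  est <- maxf >= x0
  n_est <- sum(est)
  if (n_est == 0L) stop("no established trajectory (none reaches x0 = ", x0, ")")

  Gcurve <- frequency_propagator(set, x0, grid)
  Tcurve <- sojourn_time_curve(set, x0, grid, interpolation, method)

  esti <- which(est)
  t_orig <- vapply(esti, function(i)
    origination_time(set$freq[i, ], g, x0, method = method), 0)
  t_xm <- vapply(esti, function(i)
    first_passage_time(set$freq[i, ], g, xm, x0, interpolation, method),
    NA_real_)
  t_xf <- vapply(esti, function(i)
    first_passage_time(set$freq[i, ], g, xf, x0, interpolation, method),
    NA_real_)
  n_xm <- sum(!is.na(t_xm)); n_xf <- sum(!is.na(t_xf))

  if (n_xm == 0L) {
    warning("no trajectory reaches xm = ", xm, "; mode undetermined")
    res <- list(p = NA_real_, tau = NA_real_, tau_is_lower_bound = FALSE,
                n_established = n_est, n_reached_xm = 0L, n_reached_xf = 0L,
                mode = "undetermined", confident = confident)
  } else {
    Txm <- mean(t_xm, na.rm = TRUE)
    p <- n_xf / n_xm
    if (n_xf == 0L) {
      tau <- (max(g) - mean(t_orig[!is.na(t_xm)])) / Txm
      lb <- TRUE
    } else {
      tau <- mean(t_xf, na.rm = TRUE) / Txm
      lb <- FALSE
    }
    mode <- classify_mode(p, tau, tau_is_lower_bound = lb,
                          confident = confident, thresholds = thresholds)
    res <- list(p = p, tau = tau, tau_is_lower_bound = lb,
                n_established = n_est, n_reached_xm = n_xm,
                n_reached_xf = n_xf, mode = mode, confident = confident)
  }
  fit <- tryCatch(fit_propagator_decay(Gcurve), error = function(e) NULL)
  res$lambda <- if (is.null(fit)) NA_real_ else fit$lam
  res$propagator <- Gcurve
  res$sojourn <- Tcurve
  res$host_id <- set$host_id
  res$span_generations <- span
  res$config <- list(x0 = x0, xm = xm, xf = xf,
                     min_generations_confident = min_generations_confident,
                     thresholds = thresholds, interpolation = interpolation,
                     method = method)
  class(res) <- "ptau"
  res
}

#' Classification thresholds for the selection-mode call
#'
#' Default decision rule applied to a (p, tau) pair: *diversifying* if
#' `p < p_div` and tau (or its lower bound) exceeds `tau_div`;
#' *periodic_sweeps* if `p >= p_sweep` and `|tau - 2| <= tau_sweep_halfwidth`;
#' *clonal_interference* if `p_ci_min <= p < p_sweep` and `tau <= tau_ci_max`;
#' otherwise *undetermined*. The literature gives overlapping descriptive
#' ranges; these fixed defaults are user-overridable and boundary ties
#' resolve toward `undetermined`.
#'
#' @param p_div,tau_div diversifying-selection bounds (defaults 0.5, 3).
#' @param p_sweep,tau_sweep_halfwidth periodic-sweep bounds (0.9, 0.5).
#' @param p_ci_min,tau_ci_max clonal-interference bounds (0.2, 2.5).
#' @return named list of thresholds.
#' @export
mode_thresholds <- function(p_div = 0.5, tau_div = 3,
                            p_sweep = 0.9, tau_sweep_halfwidth = 0.5,
                            p_ci_min = 0.2, tau_ci_max = 2.5) {
  list(p_div = p_div, tau_div = tau_div, p_sweep = p_sweep,
       tau_sweep_halfwidth = tau_sweep_halfwidth,
       p_ci_min = p_ci_min, tau_ci_max = tau_ci_max)
}

#' Classify the dominant selection mode from (p, tau)
#'
#' @param p fixation-probability statistic in `[0, 1]`.
#' @param tau sojourn-time ratio (or its lower bound).
#' @param tau_is_lower_bound whether `tau` is an end-of-experiment lower
#'   bound (no fixation observed).
#' @param confident whether the observation span supports a confident call;
#'   `FALSE` forces `"undetermined"`.
#' @param thresholds see [mode_thresholds()].
#' @return one of `"periodic_sweeps"`, `"clonal_interference"`,
#'   `"diversifying"`, `"undetermined"`.
#' @export
#' @examples
#' classify_mode(1, 2.25)                       # periodic_sweeps
#' classify_mode(0.3, 4, tau_is_lower_bound = TRUE)  # diversifying
#' classify_mode(0.5, 1.8)                      # clonal_interference
classify_mode <- function(p, tau, tau_is_lower_bound = FALSE,
                          confident = TRUE, thresholds = mode_thresholds()) {
  th <- thresholds
  if (!confident || is.na(p) || is.na(tau)) return("undetermined")
  if (p < th$p_div && tau > th$tau_div) return("diversifying")
  if (p >= th$p_sweep && abs(tau - 2) <= th$tau_sweep_halfwidth &&
      !tau_is_lower_bound)
    return("periodic_sweeps")
  if (p >= th$p_ci_min && p < th$p_sweep && tau <= th$tau_ci_max &&
      !tau_is_lower_bound)
    return("clonal_interference")
  "undetermined"
}

#' Sojourn-time ratio of a deterministic logistic trajectory
#'
#' For a mutation under constant selection `s`, the deterministic sojourn
#' time from `x0` to `x` is `log[x (1 - x0) / ((1 - x) x0)] / s`, so the
#' ratio `T(xf)/T(xm)` is independent of `s`. With the defaults
#' (`x0 = 0.01`, `xm = 0.3`, `xf = 0.95`) the ratio is 2.01, the
#' reference value (printed 2.0) expected under periodic selective sweeps.
#'
#' @param x0 establishment threshold.
#' @param xm intermediate frequency.
#' @param xf near-fixation frequency.
#' @return the ratio (dimensionless).
#' @export
#' @examples
#' logistic_sojourn_ratio()   # 2.01
logistic_sojourn_ratio <- function(x0 = 0.01, xm = 0.3, xf = 0.95) {
  if (!(0 < x0 && x0 < xm && xm <= xf && xf < 1))
    stop("need 0 < x0 < xm <= xf < 1")
  log(xf * (1 - x0) / ((1 - xf) * x0)) / log(xm * (1 - x0) / ((1 - xm) * x0))
}

#' Fit the exponential decay rate of a frequency propagator
#'
#' Under moderate clonal interference `G(x) ~ exp(-lambda x)`: `lambda`
#' is estimated as the least-squares slope of `-log G(x)` against `x`
#' over grid points with `G > 0`, clipped at 0.
#'
#' @param curve a `"propagator_curve"` from [frequency_propagator()].
#' @return An object of class `"propagator_fit"` with component `lam`.
#' @export
fit_propagator_decay <- function(curve) {
  stopifnot(inherits(curve, "propagator_curve"))
  keep <- curve$G > 0
  if (sum(keep) < 3L)
    stop("insufficient data: need >= 3 grid points with G > 0")
  x <- curve$x[keep]; y <- -log(curve$G[keep])
  lam <- stats::cov(x, y) / stats::var(x)
  structure(list(lam = max(0, lam)), class = "propagator_fit")
}

#' @export
print.propagator_fit <- function(x, ...) {
  cat(sprintf("Propagator decay fit: G(x) ~ exp(-lambda x), lambda = %.3f\n",
              x$lam))
  invisible(x)
}

#' @export
print.ptau <- function(x, ...) {
  cat(sprintf("p-tau selection test: host %s\n", x$host_id))
  cat(sprintf("  established trajectories: %d (reached xm: %d, xf: %d)\n",
              x$n_established, x$n_reached_xm, x$n_reached_xf))
  tl <- if (isTRUE(x$tau_is_lower_bound)) " (lower bound)" else ""
  cat(sprintf("  p = %s   tau = %s%s\n",
              formatC(x$p, digits = 3), formatC(x$tau, digits = 3), tl))
  cat(sprintf("  mode: %s%s\n", x$mode,
              if (!x$confident) " [short observation span]" else ""))
  invisible(x)
}

#' @export
summary.ptau <- function(object, ...) {
  print(object)
  cat(sprintf("  span: %.0f generations; G decay lambda = %s\n",
              object$span_generations, formatC(object$lambda, digits = 3)))
  cat("\n"); print(object$propagator)
  cat("\n"); print(object$sojourn)
  invisible(object)
}

#' @export
coef.ptau <- function(object, ...) {
  c(p = object$p, tau = object$tau, lambda = object$lambda)
}

#' Plot the G(x) and T(x) curves of a p-tau fit
#'
#' Two panels: the frequency propagator (with the fitted exponential
#' decay) and the sojourn-time spectrum, with `xm` and `xf` marked.
#'
#' @param x a `"ptau"` object.
#' @param ... passed to the panel plots.
#' @export
plot.ptau <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pc <- x$propagator
  graphics::plot(pc$x, pc$G, type = "b", pch = 16, ylim = c(0, 1),
                 xlab = "frequency x", ylab = "G(x)",
                 main = sprintf("propagator (p = %.2f)", x$p), ...)
  if (is.finite(x$lambda))
    graphics::curve(exp(-x$lambda * v), xname = "v", add = TRUE, lty = 2)
  graphics::abline(v = c(x$config$xm, x$config$xf), col = "grey60", lty = 3)
  sc <- x$sojourn
  graphics::plot(sc$x, sc$T, type = "b", pch = 16,
                 xlab = "frequency x", ylab = "T(x) [generations]",
                 main = sprintf("sojourn times (tau = %.2f%s)", x$tau,
                                if (x$tau_is_lower_bound) ", lb" else ""), ...)
  graphics::abline(v = c(x$config$xm, x$config$xf), col = "grey60", lty = 3)
  invisible(x)
}
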