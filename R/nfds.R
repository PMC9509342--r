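# Detection of negative frequency-dependent selection (NFDS) from
# trajectories, and estimation of the rare-type advantage.

#' Frequency / frequency-change correlation test for NFDS
#'
#' For one mutation, forms the pairs (x_t, dx_t) with dx_t = x_{t+1} - x_t
#' over consecutive *detected* samples (a 0 is a censored value, not a
#' measurement, so zeros inside the trajectory break pair formation), and
#' computes the Pearson correlation with its two-sided p value. A
#' significantly negative correlation — higher frequency followed by a
#' drop, lower frequency followed by a rise — is the signature of negative
#' frequency-dependent selection. Trajectories detected at fewer than
#' `min_points` time points do not qualify.
#'
#' @param freq sampled frequencies of one mutation.
#' @param days sampling days (same length as `freq`).
#' @param min_points minimum number of detected time points (default 4).
#' @param per_generation if `TRUE`, use per-generation rates
#'   `dx / d(generations)` instead of raw consecutive differences.
#' @param generations_per_day conversion used when `per_generation = TRUE`.
#' @return list of class `"nfds_result"` with `n_points`, `n_pairs`, `r`,
#'   `p_value`, `qualifies`.
#' @export
#' @examples
#' freq_change_correlation(c(0.1, 0.7, 0.1, 0.7), 1:4)  # r = -1
freq_change_correlation <- function(freq, days = seq_along(freq),
                                    min_points = 4L, per_generation = FALSE,
                                    generations_per_day = 15) {
  stopifnot(length(freq) == length(days))
  det <- which(freq > 0)
  n_points <- length(det)
  if (n_points < min_points) {
    return(structure(list(n_points = n_points, n_pairs = NA_integer_,
                          r = NA_real_, p_value = NA_real_,
                          qualifies = FALSE), class = "nfds_result"))
  }
  # consecutive detected samples only: runs of detection
  consec <- det[-length(det)] + 1L == det[-1L]
  i <- det[-length(det)][consec]
  x <- freq[i]
  dx <- freq[i + 1L] - freq[i]
  if (per_generation)
    dx <- dx / ((days[i + 1L] - days[i]) * generations_per_day)
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(dx) == 0) {
    r <- if (length(x) >= 2L && stats::sd(x) > 0 && stats::sd(dx) > 0)
      stats::cor(x, dx) else NA_real_
    return(structure(list(n_points = n_points, n_pairs = length(x), r = r,
                          p_value = NA_real_, qualifies = TRUE),
                     class = "nfds_result"))
  }
  ct <- stats::cor.test(x, dx)
  structure(list(n_points = n_points, n_pairs = length(x),
                 r = unname(ct$estimate), p_value = ct$p.value,
                 qualifies = TRUE),
            class = "nfds_result")
}

#' @export
print.nfds_result <- function(x, ...) {
  if (!x$qualifies) {
    cat(sprintf("NFDS test: does not qualify (%d detected time points)\n",
                x$n_points))
  } else {
    cat(sprintf("NFDS test: r = %.3f over %d pairs, two-sided p = %s\n",
                x$r, x$n_pairs,
                if (is.na(x$p_value)) "NA" else format.pval(x$p_value)))
  }
  invisible(x)
}

#' Run the NFDS correlation test on every trajectory of a set
#'
#' @param set a [trajectory_set()].
#' @param min_points minimum detected time points (default 4).
#' @param per_generation see [freq_change_correlation()].
#' @return data frame with one row per mutation: `mutation_id`,
#'   `n_points`, `n_pairs`, `r`, `p_value`, `qualifies`.
#' @export
nfds_scan <- function(set, min_points = 4L, per_generation = FALSE) {
  stopifnot(inherits(set, "trajectory_set"))
  rows <- lapply(seq_len(n_mutations(set)), function(i) {
    res <- freq_change_correlation(set$freq[i, ], set$days, min_points,
                                   per_generation, set$generations_per_day)
    data.frame(mutation_id = set$meta$mutation_id[i],
               n_points = res$n_points,
               n_pairs = if (is.na(res$n_pairs)) NA_integer_ else res$n_pairs,
               r = res$r, p_value = res$p_value, qualifies = res$qualifies,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the rare-type selective advantage of a mutation
#'
#' Under constant selection `s` the logit of a rare mutation's frequency
#' grows linearly at rate `s` per generation. Two estimators of that
#' slope over the rare range are provided:
#'
#' * `"ml"` (default when `depth` is supplied): maximum likelihood under
#'   the pool-seq observation model — binomial read counts at the given
#'   depth, with samples reported as 0 treated as left-censored at the
#'   detection threshold rather than discarded. At realistic depths
#'   (~300x) and a 5% floor this is essential: detected frequencies just
#'   above the floor are upward-selected noise, and the naive logit
#'   regression is biased low by tens of percent.
#' * `"ls"`: the simple least-squares slope of `logit(x)` against
#'   generations over detected samples in `(0, rare_max]`.
#'
#' @param freq sampled frequencies of one mutation.
#' @param days sampling days.
#' @param rare_max upper end of the rare range (default 0.1); samples
#'   after the first one exceeding it are not used.
#' @param generations_per_day conversion factor (default 15).
#' @param depth sequencing depth per locus (reads); enables the
#'   censored-binomial likelihood.
#' @param detection_threshold frequency below which observations are
#'   reported as 0 (default 0.05; only used by `"ml"`).
#' @param method `"ml"` or `"ls"`; defaults to `"ml"` when `depth` is
#'   given and `"ls"` otherwise.
#' @return selection-coefficient estimate per generation.
#' @export
rare_advantage <- function(freq, days, rare_max = 0.1,
                           generations_per_day = 15, depth = NULL,
                           detection_threshold = 0.05,
                           method = if (is.null(depth)) "ls" else "ml") {
  stopifnot(length(freq) == length(days))
  method <- match.arg(method, c("ml", "ls"))
  det <- which(freq > 0 & freq <= rare_max)
  if (length(det) < 2L)
    stop("insufficient data: need >= 2 detected samples in (0, ", rare_max, "]")
  g_det <- days[det] * generations_per_day
  y <- stats::qlogis(pmin(pmax(freq[det], 1e-6), 1 - 1e-6))
  slope_ls <- stats::cov(g_det, y) / stats::var(g_det)
  if (method == "ls") return(slope_ls)
  if (is.null(depth)) stop("method = 'ml' requires the sequencing depth")
  # window: everything up to the first sample beyond the rare range, so
  # leading (and interior) zeros contribute as censored observations
  over <- which(freq > rare_max)
  use <- seq_len(if (length(over)) over[1L] - 1L else length(freq))
  g <- days[use] * generations_per_day
  k <- round(freq[use] * depth)
  is_det <- freq[use] > 0
  kmax <- max(0L, ceiling(detection_threshold * depth) - 1L)
  nll <- function(par) {
    p <- stats::plogis(par[1L] + par[2L] * g)
    -sum(stats::dbinom(k[is_det], depth, p[is_det], log = TRUE)) -
      sum(stats::pbinom(kmax, depth, p[!is_det], log.p = TRUE))
  }
  a0 <- mean(y) - slope_ls * mean(g_det)
  fit <- stats::optim(c(a0, slope_ls), nll)
  fit$par[2L]
}
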