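# Sweep calling, mutation accumulation M(t), dN/dS counts, cross-host
# parallelism and the sweep-rate hypothesis tests.

#' Call selective sweeps in a trajectory set
#'
#' A selective sweep is a mutational trajectory that reached more than
#' `threshold` (default 95%) frequency and kept high frequency until the
#' end of observation. The call requires the interpolated maximum to
#' exceed `threshold` and every sampled frequency from the first crossing
#' day to the end to stay at or above `maintain_floor`. "Kept high
#' frequency" is qualitative in origin, so by default sampled points after
#' the crossing may dip to `maintain_floor = threshold`; `strict = TRUE`
#' requires every later point to exceed `threshold` itself.
#'
#' @param set a [trajectory_set()].
#' @param threshold sweep frequency threshold (default 0.95).
#' @param maintain_floor minimum frequency allowed after the crossing
#'   (default `threshold`).
#' @param strict if `TRUE`, require every sampled point after the crossing
#'   to exceed `threshold` (no dips to the floor).
#' @return A data frame of class `"sweep_calls"` with columns
#'   `mutation_id`, `first_day_above` (interpolated crossing day) and
#'   `maintained` (all `TRUE`: only maintained trajectories are called).
#' @export
detect_sweeps <- function(set, threshold = 0.95, maintain_floor = threshold,
                          strict = FALSE) {
  stopifnot(inherits(set, "trajectory_set"))
  floor_ <- if (strict) threshold else maintain_floor
  calls <- list()
  for (i in seq_len(n_mutations(set))) {
    f <- set$freq[i, ]
    if (max(f) <= threshold) next
    cross_day <- first_crossing(set$days, f, threshold,
                                interpolation = "linear")
    later <- set$days >= cross_day
    ok <- if (strict) all(f[later] > floor_) else all(f[later] >= floor_)
    # the crossing point itself sits at `threshold` by interpolation; the
    # sampled point at the crossing day (if any) is already > threshold
    if (ok)
      calls[[length(calls) + 1L]] <-
        data.frame(mutation_id = set$meta$mutation_id[i],
                   first_day_above = cross_day, maintained = TRUE,
                   stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(mutation_id = character(0), first_day_above = numeric(0),
               maintained = logical(0), stringsAsFactors = FALSE)
  class(out) <- c("sweep_calls", "data.frame")
  out
}

#' Mutation accumulation curve M(t) and its per-generation rate
#'
#' `M(t)` is the sum of allele frequencies over all detected mutations at
#' each sampling point; its least-squares slope against generations (free
#' intercept, since the first sample may postdate colonization) is the
#' per-genome per-generation rate of molecular evolution. Fixed mutations
#' keep contributing 1 at all later sampled days.
#'
#' @param set a [trajectory_set()].
#' @return An object of class `"accumulation_series"`: list with `days`,
#'   `M`, `rate` (per genome per generation), and `rate_se`. With fewer
#'   than 2 sampling days the rate is `NA`.
#' @export
mutation_accumulation <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  M <- if (n_mutations(set)) colSums(set$freq) else
    numeric(length(set$days))
  g <- generations(set)
  if (length(g) >= 2L) {
    gc <- g - mean(g)
    rate <- sum(gc * M) / sum(gc^2)
    resid <- M - mean(M) - rate * gc
    rate_se <- if (length(g) > 2L)
      sqrt(sum(resid^2) / (length(g) - 2L) / sum(gc^2)) else NA_real_
  } else {
    rate <- NA_real_; rate_se <- NA_real_
  }
  structure(list(days = set$days, M = M, rate = rate, rate_se = rate_se,
                 host_id = set$host_id),
            class = "accumulation_series")
}

#' @export
print.accumulation_series <- function(x, ...) {
  cat(sprintf("Mutation accumulation M(t), host %s\n", x$host_id))
  print(data.frame(day = x$days, M = round(x$M, 3)), row.names = FALSE)
  if (!is.na(x$rate))
    cat(sprintf("  rate: %.3g per genome per generation (SE %.2g)\n",
                x$rate, x$rate_se))
  invisible(x)
}

#' dN/dS counts for a trajectory set
#'
#' Raw counts of nonsynonymous and synonymous records and their ratio —
#' a count ratio, not site-normalised (site counts would require the
#' reference genome annotation). An elevated ratio indicates adaptive
#' evolution driven by positive selection.
#'
#' @param set a [trajectory_set()].
#' @return list of class `"dnds_summary"` with `dN`, `dS`, `ratio`
#'   (`NA` when `dS = 0`).
#' @export
dn_ds <- function(set) {
  stopifnot(inherits(set, "trajectory_set"))
  dN <- sum(set$meta$func_class == "nonsynonymous")
  dS <- sum(set$meta$func_class == "synonymous")
  structure(list(dN = dN, dS = dS,
                 ratio = if (dS > 0) dN / dS else NA_real_),
            class = "dnds_summary")
}

#' @export
print.dnds_summary <- function(x, ...) {
  cat(sprintf("dN = %d, dS = %d, dN/dS = %s\n", x$dN, x$dS,
              if (is.na(x$ratio)) "undefined (dS = 0)" else
                format(round(x$ratio, 2))))
  invisible(x)
}

#' Cross-host mutational parallelism
#'
#' For each genetic target, the set of hosts in which it was mutated
#' (each host counted once, regardless of how many records hit the
#' target), ordered by host count descending. The `loss_of_function`
#' flag marks targets hit by at least one indel or insertion-sequence
#' record — a heuristic for changes likely to disrupt the gene.
#'
#' @param sets list of [trajectory_set()] objects, one per host.
#' @return data frame of class `"parallelism_table"` with columns
#'   `target`, `n_hosts`, `hosts` (comma-separated), `loss_of_function`.
#' @export
parallelism <- function(sets) {
  if (inherits(sets, "trajectory_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "trajectory_set")))
  recs <- do.call(rbind, lapply(sets, function(s)
    data.frame(host = s$host_id, target = s$meta$target,
               func_class = s$meta$func_class, stringsAsFactors = FALSE)))
  recs <- recs[!is.na(recs$target), , drop = FALSE]
  if (nrow(recs) == 0L)
    return(structure(data.frame(target = character(0), n_hosts = integer(0),
                                hosts = character(0),
                                loss_of_function = logical(0)),
                     class = c("parallelism_table", "data.frame")))
  by_target <- split(recs, recs$target)
  out <- do.call(rbind, lapply(by_target, function(d) {
    hosts <- sort(unique(d$host))
    data.frame(target = d$target[1L], n_hosts = length(hosts),
               hosts = paste(hosts, collapse = ","),
               loss_of_function = any(d$func_class %in% c("indel", "IS")),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_hosts, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("parallelism_table", "data.frame")
  out
}

#' Fraction of mutations in intergenic regions
#'
#' @param sets list of [trajectory_set()] objects (or a single one).
#' @return list with `n_intergenic`, `n_total`, `fraction`.
#' @export
intergenic_fraction <- function(sets) {
  if (inherits(sets, "trajectory_set")) sets <- list(sets)
  cls <- unlist(lapply(sets, function(s) s$meta$func_class))
  n <- length(cls); k <- sum(cls == "intergenic")
  list(n_intergenic = k, n_total = n,
       fraction = if (n > 0) k / n else NA_real_)
}

#' Hypothesis tests on per-host sweep rates
#'
#' Two tests on per-host rates of selective sweeps: a one-sided Welch
#' unequal-variance t test that the rate is higher in hosts where the
#' invader co-exists with a resident strain (`group_with` greater), and a
#' Spearman rank correlation between sweep rate and mean population size.
#'
#' @param group_with per-host sweep rates, hosts with co-existence
#'   (length >= 2).
#' @param group_without per-host sweep rates, hosts without (length >= 2).
#' @param rates optional per-host sweep rates paired with `pop_sizes` for
#'   the Spearman test (defaults to the two groups concatenated).
#' @param pop_sizes optional per-host mean population sizes.
#' @return list of class `"sweep_rate_tests"` with elements `welch`
#'   (`t`, `df`, `p_value`, one-sided greater) and, when population sizes
#'   are given, `spearman` (`rho`, `p_value`).
#' @export
sweep_rate_tests <- function(group_with, group_without,
                             rates = c(group_with, group_without),
                             pop_sizes = NULL) {
  if (length(group_with) < 2L || length(group_without) < 2L)
    stop("insufficient data: each group needs at least 2 hosts")
  ht <- stats::t.test(group_with, group_without, alternative = "greater",
                      var.equal = FALSE)
  out <- list(welch = list(t = unname(ht$statistic),
                           df = unname(ht$parameter),
                           p_value = ht$p.value))
  if (!is.null(pop_sizes)) {
    ct <- suppressWarnings(stats::cor.test(rates, pop_sizes,
                                           method = "spearman"))
    out$spearman <- list(rho = unname(ct$estimate), p_value = ct$p.value)
  }
  class(out) <- "sweep_rate_tests"
  out
}

#' @export
print.sweep_rate_tests <- function(x, ...) {
  cat(sprintf("Welch one-sided t test: t = %.3f, df = %.2f, p = %.4g\n",
              x$welch$t, x$welch$df, x$welch$p_value))
  if (!is.null(x$spearman))
    cat(sprintf("Spearman rate vs population size: rho = %.3f, p = %.4g\n",
                x$spearman$rho, x$spearman$p_value))
  invisible(x)
}
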