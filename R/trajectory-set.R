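#' Functional annotation classes recognised for mutation records
#'
#' Coding changes are `"nonsynonymous"` / `"synonymous"`; `"intergenic"`
#' covers regulatory-region changes; `"indel"`, `"IS"` (insertion-sequence
#' movement) and `"HGT"` (phage- or plasmid-mediated horizontal transfer)
#' are structural events; anything else is `"other"`.
#'
#' @export
FUNC_CLASSES <- c("nonsynonymous", "synonymous", "intergenic",
                  "indel", "IS", "HGT", "other")

#' Construct a trajectory set
#'
#' A trajectory set holds all mutation-frequency trajectories observed in
#' one host population: a strictly increasing grid of sampling days, a
#' frequency matrix (one row per mutation, one column per day), and
#' per-mutation annotation. A day present in the grid but not reported for
#' a mutation means "sampled, below detection" and is stored as 0; truly
#' unsampled days are simply absent from the grid.
#'
#' @param host_id host identifier (scalar character).
#' @param days strictly increasing non-negative sampling days.
#' @param freq numeric matrix of frequencies in `[0, 1]`, `length(mutation_id)`
#'   rows by `length(days)` columns. A vector is accepted for one mutation.
#' @param mutation_id unique mutation identifiers (row order of `freq`).
#' @param target gene or intergenic label per mutation (e.g. `"dgoR"`,
#'   `"psuK/fruA"`); recycled if scalar.
#' @param func_class one of [FUNC_CLASSES] per mutation; recycled if scalar.
#' @param generations_per_day generation time conversion (default 15, the
#'   measured value for gut-colonizing *E. coli*).
#' @param detection_threshold pool-seq detection floor in `[0, 1)` (default
#'   0.05). Metadata used by downstream estimators, not a validation rule.
#'
#' @return An object of class `"trajectory_set"`.
#' @seealso [read_trajectories()], [ptau()], [detect_sweeps()]
#' @export
#' @examples
#' ts <- trajectory_set("m1", days = c(10, 20, 30),
#'                      freq = rbind(c(0.1, 0.5, 0.9)),
#'                      mutation_id = "snp1", target = "frlR",
#'                      func_class = "nonsynonymous")
#' ts
trajectory_set <- function(host_id, days, freq, mutation_id,
                           target = NA_character_, func_class = "other",
                           generations_per_day = 15,
                           detection_threshold = 0.05) {
  if (is.vector(freq)) freq <- matrix(freq, nrow = 1L)
  freq <- as.matrix(freq)
  storage.mode(freq) <- "double"
  days <- as.numeric(days)
  mutation_id <- as.character(mutation_id)
  n <- length(mutation_id)
  target <- rep_len(as.character(target), n)
  func_class <- rep_len(as.character(func_class), n)
  x <- structure(list(
    host_id = as.character(host_id)[1L],
    days = days,
    freq = freq,
    meta = data.frame(mutation_id = mutation_id, target = target,
                      func_class = func_class, stringsAsFactors = FALSE),
    generations_per_day = as.numeric(generations_per_day)[1L],
    detection_threshold = as.numeric(detection_threshold)[1L]
  ), class = "trajectory_set")
  validate_trajectory_set(x)
}

#' Validate a trajectory set
#'
#' Checks the container invariants: strictly increasing non-negative day
#' grid, frequencies in `[0, 1]`, unique mutation ids, recognised
#' functional classes, positive generations-per-day.
#'
#' @param x a `"trajectory_set"`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_trajectory_set <- function(x) {
  stopifnot(inherits(x, "trajectory_set"))
  d <- x$days
  if (length(d) < 1L || any(d < 0) || anyNA(d))
    stop("days must be non-negative and non-missing")
  if (length(d) > 1L && any(diff(d) <= 0))
    stop("days must be strictly increasing (duplicate or unordered days)")
  if (ncol(x$freq) != length(d))
    stop("freq must have one column per sampling day")
  if (nrow(x$freq) != nrow(x$meta))
    stop("freq must have one row per mutation record")
  if (nrow(x$freq) > 0L) {
    f <- x$freq
    if (anyNA(f) || any(f < 0) || any(f > 1))
      stop("frequencies must lie in [0, 1]")
  }
  if (anyDuplicated(x$meta$mutation_id))
    stop("mutation ids must be unique within a host")
  bad <- setdiff(unique(x$meta$func_class), FUNC_CLASSES)
  if (length(bad))
    stop("unknown func_class value(s): ", paste(bad, collapse = ", "))
  if (!is.finite(x$generations_per_day) || x$generations_per_day <= 0)
    stop("generations_per_day must be a positive number")
  if (!is.finite(x$detection_threshold) ||
      x$detection_threshold < 0 || x$detection_threshold >= 1)
    stop("detection_threshold must lie in [0, 1)")
  invisible(x)
}

#' Convert days post-colonization to generations
#'
#' Linear conversion `day * generations_per_day`. The default conversion
#' factor of 15 generations/day was measured for invading *E. coli* in the
#' mouse gut; 436 days correspond to ~6540 generations.
#'
#' @param day non-negative day(s).
#' @param generations_per_day positive conversion factor, or a
#'   `"trajectory_set"` whose factor is used.
#' @return generations, same length as `day`.
#' @export
#' @examples
#' to_generations(436)            # 6540
#' to_generations(1, 10)          # 10
to_generations <- function(day, generations_per_day = 15) {
  if (inherits(generations_per_day, "trajectory_set"))
    generations_per_day <- generations_per_day$generations_per_day
  day <- as.numeric(day)
  if (any(day < 0, na.rm = TRUE)) stop("day must be non-negative")
  if (!is.finite(generations_per_day) || generations_per_day <= 0)
    stop("generations_per_day must be positive")
  day * generations_per_day
}

#' Sampling-day grid of a trajectory set, in generations
#' @param x a `"trajectory_set"`.
#' @return numeric vector of generation times of the sampling days.
#' @export
generations <- function(x) {
  stopifnot(inherits(x, "trajectory_set"))
  x$days * x$generations_per_day
}

#' Number of mutation records in a trajectory set
#' @param x a `"trajectory_set"`.
#' @return integer count.
#' @export
n_mutations <- function(x) nrow(x$meta)

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: host %s\n", x$host_id))
  cat(sprintf("  %d mutation(s) x %d sampling day(s), days %s-%s (%.0f generations)\n",
              nrow(x$meta), length(x$days),
              format(min(x$days)), format(max(x$days)),
              max(generations(x))))
  cat(sprintf("  %g generations/day, detection threshold %g\n",
              x$generations_per_day, x$detection_threshold))
  if (nrow(x$meta) > 0L) {
    tab <- table(x$meta$func_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.trajectory_set <- function(x, row.names = NULL, optional = FALSE,
                                         sparse = FALSE, ...) {
  n <- nrow(x$meta)
  if (n == 0L)
    return(data.frame(host = character(), mutation_id = character(),
                      target = character(), func_class = character(),
                      day = numeric(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  d <- data.frame(
    host = x$host_id,
    mutation_id = rep(x$meta$mutation_id, each = length(x$days)),
    target = rep(x$meta$target, each = length(x$days)),
    func_class = rep(x$meta$func_class, each = length(x$days)),
    day = rep(x$days, times = n),
    frequency = as.vector(t(x$freq)),
    stringsAsFactors = FALSE
  )
  if (sparse) d <- d[d$frequency > 0, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Subset the mutation records of a trajectory set
#'
#' @param x a `"trajectory_set"`.
#' @param i row index (logical, integer or mutation-id character vector).
#' @return a `"trajectory_set"` with the selected records.
#' @export
subset_mutations <- function(x, i) {
  stopifnot(inherits(x, "trajectory_set"))
  if (is.character(i)) i <- match(i, x$meta$mutation_id)
  x$freq <- x$freq[i, , drop = FALSE]
  x$meta <- x$meta[i, , drop = FALSE]
  rownames(x$meta) <- NULL
  validate_trajectory_set(x)
  x
}

#' Pool several trajectory sets sharing one sampling grid
#'
#' Combines the records of several hosts (or simulation replicates) into a
#' single set, prefixing each mutation id with its host id. All sets must
#' share the same day grid and conversion factor. Used to pool replicate
#' simulations before a joint p-tau analysis.
#'
#' @param sets list of `"trajectory_set"` objects.
#' @param host_id id for the pooled set.
#' @return a `"trajectory_set"`.
#' @export
pool_trajectory_sets <- function(sets, host_id = "pooled") {
  stopifnot(length(sets) >= 1L, all(vapply(sets, inherits, TRUE, "trajectory_set")))
  ref <- sets[[1L]]
  for (s in sets) {
    if (!isTRUE(all.equal(s$days, ref$days)) ||
        s$generations_per_day != ref$generations_per_day)
      stop("all sets must share the same day grid and generations_per_day")
  }
  freq <- do.call(rbind, lapply(sets, `[[`, "freq"))
  meta <- do.call(rbind, lapply(sets, function(s) {
    m <- s$meta
    if (nrow(m)) m$mutation_id <- paste(s$host_id, m$mutation_id, sep = ":")
    m
  }))
  trajectory_set(host_id, ref$days, freq,
                 mutation_id = meta$mutation_id, target = meta$target,
                 func_class = meta$func_class,
                 generations_per_day = ref$generations_per_day,
                 detection_threshold = ref$detection_threshold)
}

#' Construct an OD600 time series
#'
#' @param times strictly increasing sampling times in hours (length >= 3).
#' @param od positive OD600 readings, same length as `times`.
#' @return An object of class `"od_series"`.
#' @export
od_series <- function(times, od) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop("times and od must have equal length")
  if (length(times) < 3L) stop("an OD series needs at least 3 points")
  if (anyNA(times) || anyNA(od)) stop("times and od must be non-missing")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("od must be positive (logarithms are taken)")
  structure(list(times = times, od = od), class = "od_series")
}

#' @export
print.od_series <- function(x, ...) {
  cat(sprintf("OD600 series: %d points, %.2f-%.2f h, OD %.3f-%.3f\n",
              length(x$times), min(x$times), max(x$times),
              min(x$od), max(x$od)))
  invisible(x)
}
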