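#' Read mutation-frequency trajectories from a long-format TSV
#'
#' The canonical dialect is tab-separated with header columns
#' `host  mutation_id  target  func_class  day  frequency` (UTF-8, `.`
#' decimal separator). Rows are grouped by host; each host's sampling grid
#' is the sorted set of distinct days appearing for that host. A
#' (mutation, day) pair not present in the file, for a day that was sampled
#' for the host, is interpreted as "sampled, below detection" and stored as
#' 0 — pool-seq calls under the detection floor are typically unreported —
#' so files written in the sparse dialect (zero rows omitted) read back
#' identically.
#'
#' @param path path to the TSV file.
#' @param detection_threshold detection floor recorded on each set
#'   (default 0.05).
#' @param generations_per_day conversion factor recorded on each set
#'   (default 15).
#' @return A named list of [trajectory_set()] objects, one per host, in
#'   order of first appearance.
#' @export
read_trajectories <- function(path, detection_threshold = 0.05,
                              generations_per_day = 15) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         colClasses = "character", comment.char = "",
                         encoding = "UTF-8")
  need <- c("host", "mutation_id", "target", "func_class", "day", "frequency")
  if (!all(need %in% names(d)))
    stop("missing column(s): ", paste(setdiff(need, names(d)), collapse = ", "))
  day <- suppressWarnings(as.numeric(d$day))
  freq <- suppressWarnings(as.numeric(d$frequency))
  bad <- which(is.na(day) | is.na(freq))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: day/frequency not numeric",
                 bad[1L] + 1L, path))
  oob <- which(freq < 0 | freq > 1)
  if (length(oob))
    stop(sprintf("frequency %g outside [0, 1] at line %d of %s",
                 freq[oob[1L]], oob[1L] + 1L, path))
  key <- paste(d$host, d$mutation_id, day, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("duplicate (host, mutation_id, day) row at line %d of %s",
                 i + 1L, path))
  }
  hosts <- unique(d$host)
  out <- lapply(hosts, function(h) {
    sel <- d$host == h
    days <- sort(unique(day[sel]))
    ids <- unique(d$mutation_id[sel])
    freqm <- matrix(0, nrow = length(ids), ncol = length(days),
                    dimnames = NULL)
    ri <- match(d$mutation_id[sel], ids)
    ci <- match(day[sel], days)
    freqm[cbind(ri, ci)] <- freq[sel]
    first <- sel & !duplicated(paste(d$host, d$mutation_id, sep = "\r"))
    ann <- d[first, c("mutation_id", "target", "func_class")]
    ann <- ann[match(ids, ann$mutation_id), ]
    trajectory_set(h, days, freqm, mutation_id = ids,
                   target = ann$target, func_class = ann$func_class,
                   generations_per_day = generations_per_day,
                   detection_threshold = detection_threshold)
  })
  names(out) <- hosts
  out
}

#' Write trajectory sets to the long-format TSV
#'
#' Inverse of [read_trajectories()]: `read(write(x))` reproduces `x` up to
#' row order, under either dialect.
#'
#' @param x a `"trajectory_set"` or a list of them.
#' @param path output file path.
#' @param sparse if `TRUE`, omit zero-frequency rows (they are recovered as
#'   sampled-at-0 on reading because the day remains in the host grid
#'   through other mutations); if `FALSE` (default) write explicit 0 rows.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(x, path, sparse = FALSE) {
  if (inherits(x, "trajectory_set")) x <- list(x)
  stopifnot(all(vapply(x, inherits, TRUE, "trajectory_set")))
  tabs <- lapply(x, as.data.frame, sparse = sparse)
  d <- do.call(rbind, tabs)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path))
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OD600 time series from a two-column TSV
#'
#' Expects header columns `time_h` and `od600`.
#'
#' @param path path to the TSV file.
#' @return An [od_series()].
#' @export
read_od_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("time_h", "od600") %in% names(d)))
    stop("OD series file must have columns time_h and od600")
  od_series(d$time_h, d$od600)
}

#' Write an OD600 series to a two-column TSV
#' @param x an `"od_series"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_od_series <- function(x, path) {
  stopifnot(inherits(x, "od_series"))
  utils::write.table(data.frame(time_h = x$times, od600 = x$od), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
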