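# Fixtures shared across test files: all built programmatically.

# deterministic logistic frequency trajectory: logit(x) = logit(x0) + s*g
logistic_freq <- function(gens, s, x0 = 0.01) plogis(qlogis(x0) + s * gens)

# single-host set whose trajectories have prescribed maxima (two days:
# start below detection, peak at the maximum)
maxima_set <- function(maxima, x0_start = 0) {
  trajectory_set("hmax", days = c(0, 1),
                 freq = cbind(rep(x0_start, length(maxima)), maxima),
                 mutation_id = sprintf("mx%02d", seq_along(maxima)),
                 generations_per_day = 1)
}

# the worked five-trajectory family: three reach 0.3 (first-passage times
# 100, 200, 300 generations), two of those reach 0.95 (at 400 and 600);
# all start exactly at x0 = 0.01 so origination is 0 for every rule
worked_five_set <- function() {
  g <- c(0, 100, 200, 300, 400, 600)
  f <- rbind(
    A = c(0.01, 0.30, 0.40, 0.50, 0.95, 0.95),
    B = c(0.01, 0.02, 0.30, 0.40, 0.50, 0.95),
    C = c(0.01, 0.02, 0.03, 0.30, 0.30, 0.30),
    D = c(0.01, 0.05, 0.10, 0.10, 0.05, 0.02),
    E = c(0.01, 0.25, 0.20, 0.10, 0.05, 0.02)
  )
  trajectory_set("hand", days = g, freq = f,
                 mutation_id = rownames(f), generations_per_day = 1)
}

# long-format TSV written to a temp file; returns the path
write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("host\tmutation_id\ttarget\tfunc_class\tday\tfrequency",
               lines), path)
  path
}

# random valid trajectory sets for property-style loops
random_set <- function(n_mut = 5, n_day = 8, seed = 1) {
  set.seed(seed)
  days <- sort(sample(1:200, n_day))
  f <- t(replicate(n_mut, {
    x <- cumsum(rnorm(n_day, 0.05, 0.2))
    pmin(pmax(x, 0), 1)
  }))
  trajectory_set(paste0("r", seed), days, f,
                 mutation_id = sprintf("m%02d", 1:n_mut),
                 generations_per_day = 1)
}
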