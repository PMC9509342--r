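test_that("no mutational input yields an empty trajectory set", {
  sch <- sampling_scheme(c(0, 50, 100), generations_per_day = 1)
  sim <- simulate_directional(wf_params(N = 1000, U = 0, T_gen = 100,
                                        seed = 1), sch)
  expect_equal(n_mutations(sim), 0L)
  expect_s3_class(sim, "trajectory_set")
})

test_that("simulations are reproducible from the seed and scope the RNG", {
  sch <- sampling_scheme(seq(0, 500, 100), generations_per_day = 1)
  p <- wf_params(N = 2000, U = 1e-4, s_mean = 0.05, T_gen = 500, seed = 9)
  set.seed(123); before <- runif(1)
  a <- simulate_directional(p, sch)
  set.seed(123)
  b <- simulate_directional(p, sch)
  expect_identical(a$freq, b$freq)
  expect_identical(a$meta, b$meta)
  # caller RNG stream is restored around the simulation
  set.seed(123); invisible(simulate_directional(p, sch))
  expect_equal(runif(1), before)
  r <- resource_params(N = 2000, mu = 1e-4, T_gen = 200, seed = 4)
  sch2 <- sampling_scheme(seq(0, 200, 50), generations_per_day = 1)
  expect_identical(simulate_resource_competition(r, sch2)$freq,
                   simulate_resource_competition(r, sch2)$freq)
})

test_that("sampling horizon beyond T_gen is a domain error", {
  sch <- sampling_scheme(c(0, 200), generations_per_day = 1)
  expect_error(simulate_directional(wf_params(N = 100, T_gen = 100, seed = 1),
                                    sch), "horizon")
  expect_error(
    simulate_resource_competition(resource_params(N = 100, T_gen = 100,
                                                  seed = 1), sch),
    "horizon")
})

test_that("single-copy fixation fraction matches the diffusion approximation", {
  # Kimura: P(fix) for one copy with advantage s in a haploid WF population
  # is (1 - exp(-2s)) / (1 - exp(-2Ns)); the denominator is ~1 here
  N <- 1e4; s <- 0.05; nrep <- 2000
  sch <- sampling_scheme(c(0, 2000), generations_per_day = 1)
  fixed <- vapply(seq_len(nrep), function(r) {
    sim <- simulate_directional(
      wf_params(N = N, U = 0, T_gen = 2000, seed = 5000 + r), sch,
      init_mutants = data.frame(count = 1, s = s), raw = TRUE)
    tr <- attr(sim, "truth")
    nrow(tr) == 1L && tr$final_freq == 1
  }, TRUE)
  p_exp <- (1 - exp(-2 * s)) / (1 - exp(-2 * N * s))
  se <- sqrt(p_exp * (1 - p_exp) / nrep)
  expect_lt(abs(mean(fixed) - p_exp), 3 * se)
})

test_that("neutral allele-frequency increments have Wright-Fisher moments", {
  N <- 100; nrep <- 2000
  sch <- sampling_scheme(c(0, 1), generations_per_day = 1)
  dx <- vapply(seq_len(nrep), function(r) {
    sim <- simulate_directional(
      wf_params(N = N, U = 0, T_gen = 1, seed = 9000 + r), sch,
      init_mutants = data.frame(count = N / 2, s = 0), raw = TRUE)
    diff(sim$freq[1, ])
  }, 0)
  expect_lt(abs(mean(dx)), 3 * sqrt(0.25 / N / nrep))
  expect_equal(var(dx), 0.25 / N, tolerance = 0.15)
})

test_that("subsampling converges to truth at high depth and censors below it", {
  gens <- seq(0, 100, 10)
  truth <- trajectory_set("h", gens,
                          rbind(logistic_freq(gens, 0.05, 0.2),
                                rep(0.03, length(gens))),
                          c("hi", "lo"), generations_per_day = 1)
  deep <- subsample(truth, sampling_scheme(gens, depth = 1e6,
                                           generations_per_day = 1), seed = 2)
  expect_lt(max(abs(deep$freq[1, ] - truth$freq[1, ])), 0.01)
  # a 3% trajectory at depth 300 with a 5% floor is mostly reported 0
  shallow <- subsample(truth, sampling_scheme(gens, depth = 300,
                                              generations_per_day = 1),
                       seed = 3)
  expect_gt(mean(shallow$freq[2, ] == 0), 0.5)
  # determinism and day-matching errors
  expect_identical(subsample(truth, sampling_scheme(gens, depth = 300,
                                                    generations_per_day = 1),
                             seed = 3)$freq, shallow$freq)
  expect_error(subsample(truth, sampling_scheme(c(0, 7),
                                                generations_per_day = 1)),
               "absent")
})

test_that("simulator output is a valid set that round-trips through the TSV", {
  sch <- sampling_scheme(seq(0, 1000, 100), generations_per_day = 1)
  sim <- simulate_directional(wf_params(N = 5000, U = 1e-5, s_mean = 0.05,
                                        T_gen = 1000, seed = 3), sch)
  expect_silent(validate_trajectory_set(sim))
  if (n_mutations(sim) > 0) {
    path <- tempfile(fileext = ".tsv")
    write_trajectories(sim, path)
    back <- read_trajectories(path)[[sim$host_id]]
    o <- match(sim$meta$mutation_id, back$meta$mutation_id)
    expect_equal(back$freq[o, , drop = FALSE], sim$freq, ignore_attr = TRUE)
  }
})

test_that("consumer-resource fitness confers a rare-type advantage", {
  alloc <- cbind(c(1, 0), c(0, 1))
  w <- resource_fitness(alloc, c(0.9, 0.1), c(0.5, 0.5))
  expect_gt(w[2], 1)   # minority specialist on the underused resource
  expect_lt(w[1], 1)
  # deterministic replicator iteration converges to supply proportions
  x <- c(0.9, 0.1)
  for (i in 1:200) {
    w <- resource_fitness(alloc, x, c(0.7, 0.3))
    x <- x * w / sum(x * w)
  }
  expect_equal(x, c(0.7, 0.3), tolerance = 1e-6)
  # unused resources contribute nothing rather than dividing by zero
  expect_equal(resource_fitness(cbind(c(1, 0)), 1, c(0.5, 0.5)), 0.5)
})

test_that("a single resource reduces to neutral dynamics", {
  # with R = 1 and no within-ecotype benefit every genotype has the same
  # fitness regardless of its allocation
  expect_equal(resource_fitness(matrix(c(1, 1, 1), 1), c(0.2, 0.3, 0.5), 1),
               rep(1, 3))
  # frequency increments of segregating trajectories at intermediate
  # frequencies (where extinction censoring is negligible) centre on zero
  dx <- unlist(lapply(1:20, function(r) {
    sim <- simulate_resource_competition(
      resource_params(R = 1, supply = 1, N = 300, mu = 5e-4, s_mean = 0,
                      T_gen = 600, seed = 700 + r),
      sampling_scheme(seq(0, 600, 20), generations_per_day = 1), raw = TRUE)
    if (n_mutations(sim) == 0) return(NULL)
    f <- sim$freq
    x <- f[, -ncol(f), drop = FALSE]
    d <- f[, -1, drop = FALSE] - x
    mid <- x >= 0.2 & x <= 0.8 & (x + d) > 0
    d[mid]
  }))
  expect_gt(length(dx), 30)
  expect_lt(abs(mean(dx)), 3 * sd(dx) / sqrt(length(dx)))
})

test_that("sweep calls on periodic-regime output match simulated fixations", {
  sch <- sampling_scheme(seq(0, 6000, 100), generations_per_day = 1)
  sim <- simulate_directional(wf_params(N = 1e5, U = 1e-7, s_mean = 0.05,
                                        T_gen = 6000, seed = 21), sch,
                              raw = TRUE)
  tr <- attr(sim, "truth")
  n_fixed <- sum(tr$final_freq == 1)
  expect_gt(n_fixed, 0)
  expect_equal(nrow(detect_sweeps(sim)), n_fixed)
})
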