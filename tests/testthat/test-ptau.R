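test_that("origination is the x0-crossing of the first observed segment", {
  # one detected point: both rules interpolate the chord from the last
  # zero sample: 100 * 0.01 / 0.20 = 5
  expect_equal(origination_time(c(0, 0.2), c(0, 100)), 5)
  expect_equal(origination_time(c(0, 0.2), c(0, 100), method = "interior"), 5)
  # first sample already high: backward extrapolation clipped at 0
  expect_equal(origination_time(c(0.3, 0.5), c(0, 100)), 0)
  expect_equal(origination_time(c(0.3, 0.5), c(0, 100), method = "interior"), 0)
  # never established
  expect_true(is.na(origination_time(c(0.005, 0.005), c(0, 100))))
  # backcast reconstructs the censored pre-detection segment:
  # line through (100, 0.2) and (200, 0.5) crosses 0.01 at
  # 100 - (0.2 - 0.01)/0.003 = 36.667
  expect_equal(origination_time(c(0, 0.2, 0.5), c(0, 100, 200)),
               100 - (0.2 - 0.01) / ((0.5 - 0.2) / 100))
  # interior rule instead takes the zero sample at face value
  expect_equal(origination_time(c(0, 0.2, 0.5), c(0, 100, 200),
                                method = "interior"), 5)
})

test_that("first-passage times match hand interpolation (linear/interior)", {
  f <- c(0, 0.2, 0.5, 0.96); g <- c(0, 100, 200, 300)
  # hand-derived under frequency-linear interpolation, chord origination:
  # origination 5; 0.3-crossing 100 + 100*(0.1/0.3); 0.95-crossing
  # 200 + 100*(0.45/0.46)
  expect_equal(first_passage_time(f, g, 0.3, interpolation = "linear",
                                  method = "interior"),
               100 + 100 * 0.1 / 0.3 - 5, tolerance = 1e-8)
  expect_equal(first_passage_time(f, g, 0.95, interpolation = "linear",
                                  method = "interior"),
               200 + 100 * 0.45 / 0.46 - 5, tolerance = 1e-8)
  expect_true(is.na(first_passage_time(f, g, 0.99)))
  expect_error(first_passage_time(f, g, 0.005), "exceed x0")
})

test_that("first-passage times match hand interpolation (logit/backcast)", {
  f <- c(0, 0.2, 0.5, 0.96); g <- c(0, 100, 200, 300)
  q <- qlogis
  orig <- 100 - (0.2 - 0.01) / ((0.5 - 0.2) / 100)
  cross3 <- 100 + 100 * (q(0.3) - q(0.2)) / (q(0.5) - q(0.2))
  cross95 <- 200 + 100 * (q(0.95) - q(0.5)) / (q(0.96) - q(0.5))
  expect_equal(first_passage_time(f, g, 0.3), cross3 - orig, tolerance = 1e-8)
  expect_equal(first_passage_time(f, g, 0.95), cross95 - orig,
               tolerance = 1e-8)
  # exact sample-point hits use the sample time
  expect_equal(first_crossing(g, c(0.01, 0.3, 0.5, 0.9), 0.3), 100)
})

test_that("propagator equals exhaustive enumeration over trajectory maxima", {
  pc <- frequency_propagator(maxima_set(c(0.05, 0.25, 0.40, 0.97, 0.99)))
  expect_equal(pc$n_established, 5L)
  expect_equal(pc$G[pc$x == 0.3], 0.6)
  expect_equal(pc$G[pc$x == 0.95], 0.4)
  expect_true(all(diff(pc$G) <= 0))
  # all trajectories fix
  expect_true(all(frequency_propagator(maxima_set(rep(1, 3)))$G == 1))
  # single trajectory: step function at its maximum
  pc1 <- frequency_propagator(maxima_set(0.5))
  expect_equal(pc1$G, as.numeric(pc1$x <= 0.5))
  expect_error(frequency_propagator(maxima_set(0.001)), "established")
})

test_that("sojourn curve averages first-passage times of reachers", {
  g <- c(0, 100, 300)
  f <- rbind(c(0.01, 0.3, 0.3), c(0.01, 0.02, 0.3))
  ts <- trajectory_set("h", g, f, c("a", "b"), generations_per_day = 1)
  sc <- sojourn_time_curve(ts)
  expect_equal(sc$T[sc$x == 0.3], 200)   # mean of 100 and 300
  expect_equal(sc$n_reaching[sc$x == 0.3], 2L)
  expect_true(is.na(sc$T[sc$x == 0.95]))
  expect_equal(sc$n_reaching[sc$x == 0.95], 0L)
})

test_that("dense logistic trajectories reproduce the closed-form sojourn", {
  s <- 0.05; x0 <- 0.01
  gens <- 0:300
  f <- logistic_freq(gens, s, x0)
  ts <- trajectory_set("h", gens, rbind(f), "m1", generations_per_day = 1)
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.95)
  closed <- log(grid * (1 - x0) / ((1 - grid) * x0)) / s
  for (interp in c("logit", "linear")) {
    sc <- sojourn_time_curve(ts, grid = grid, interpolation = interp)
    expect_equal(sc$T, closed, tolerance = 0.02)
  }
  # tau converges to the analytic ratio as sampling becomes dense
  fit <- ptau(ts, min_generations_confident = 0)
  expect_equal(fit$tau, logistic_sojourn_ratio(), tolerance = 0.01)
  expect_equal(fit$p, 1)
})

test_that("p and tau equal hand enumeration on the worked five-trajectory set", {
  ts <- worked_five_set()
  fit <- ptau(ts, min_generations_confident = 0)
  expect_equal(fit$n_established, 5L)
  expect_equal(fit$n_reached_xm, 3L)
  expect_equal(fit$n_reached_xf, 2L)
  expect_equal(fit$p, 2 / 3)
  expect_equal(fit$tau, 500 / 200)       # T(0.95) = 500, T(0.3) = 200
  expect_false(fit$tau_is_lower_bound)
  expect_equal(fit$propagator$G[fit$propagator$x == 0.3], 0.6)
  expect_equal(fit$sojourn$T[fit$sojourn$x == 0.3], 200)
  expect_equal(coef(fit)[["p"]], 2 / 3)
  # identical result under the spec's alternative rules (exact-hit design)
  fit2 <- ptau(ts, min_generations_confident = 0,
               interpolation = "linear", method = "interior")
  expect_equal(fit2$p, fit$p)
  expect_equal(fit2$tau, fit$tau)
})

test_that("tau falls back to the end-of-experiment lower bound without fixation", {
  g <- c(0, 100, 500, 1000)
  f <- rbind(c(0.01, 0.3, 0.5, 0.5), c(0.01, 0.02, 0.05, 0.1))
  ts <- trajectory_set("h", g, f, c("a", "b"), generations_per_day = 1)
  fit <- ptau(ts, min_generations_confident = 0)
  expect_equal(fit$p, 0)
  expect_true(fit$tau_is_lower_bound)
  # origination of the xm-reacher is 0, T(0.3) = 100, end = 1000
  expect_equal(fit$tau, (1000 - 0) / 100)
  # no trajectory reaching xm: undetermined with a warning
  low <- trajectory_set("h", g, rbind(c(0.01, 0.05, 0.1, 0.1)), "a",
                        generations_per_day = 1)
  expect_warning(res <- ptau(low, min_generations_confident = 0),
                 "undetermined")
  expect_equal(res$mode, "undetermined")
})

test_that("mode classification follows the documented decision rule", {
  expect_equal(classify_mode(1, 2.25), "periodic_sweeps")
  expect_equal(classify_mode(0.3, 4, tau_is_lower_bound = TRUE),
               "diversifying")
  expect_equal(classify_mode(0.5, 1.8), "clonal_interference")
  expect_equal(classify_mode(0.3, 4), "diversifying")
  # boundary and low-confidence calls resolve toward undetermined
  expect_equal(classify_mode(0.95, 2.6), "undetermined")
  expect_equal(classify_mode(0.1, 2), "undetermined")
  expect_equal(classify_mode(1, 2, confident = FALSE), "undetermined")
  # a lower bound cannot support a periodic or interference call
  expect_equal(classify_mode(1, 2.2, tau_is_lower_bound = TRUE),
               "undetermined")
  # thresholds are overridable
  th <- mode_thresholds(p_sweep = 0.8)
  expect_equal(classify_mode(0.85, 2.1, thresholds = th), "periodic_sweeps")
})

test_that("the analytic logistic sojourn ratio is selection-free", {
  r <- logistic_sojourn_ratio(0.01, 0.3, 0.95)
  expect_equal(r,
               log(0.95 * 0.99 / (0.05 * 0.01)) /
                 log(0.3 * 0.99 / (0.7 * 0.01)))
  expect_equal(round(r, 1), 2.0)
  expect_equal(logistic_sojourn_ratio(0.01, 0.5, 0.5), 1)
  expect_error(logistic_sojourn_ratio(0.3, 0.01, 0.95), "need")
  # s cancels: sojourn ratios of logistic trajectories at any s agree
  for (s in c(0.01, 0.05, 0.2)) {
    gens <- seq(0, 1500, by = 0.5)
    ts <- trajectory_set("h", gens, rbind(logistic_freq(gens, s)), "m",
                         generations_per_day = 1)
    fit <- ptau(ts, min_generations_confident = 0)
    expect_equal(fit$tau, r, tolerance = 0.01)
  }
})

test_that("propagator decay fit recovers exponential rates", {
  grid <- seq(0.05, 0.95, by = 0.05)
  mk <- function(G) structure(list(x = grid, G = G, n_established = 100L,
                                   x0 = 0.01), class = "propagator_curve")
  expect_equal(fit_propagator_decay(mk(exp(-3 * grid)))$lam, 3)
  expect_equal(fit_propagator_decay(mk(rep(1, length(grid))))$lam, 0)
  set.seed(42)
  noisy <- exp(-3 * grid) * exp(rnorm(length(grid), 0, 0.05))
  expect_equal(fit_propagator_decay(mk(noisy))$lam, 3, tolerance = 0.1)
  expect_error(fit_propagator_decay(mk(c(1, 0.5, rep(0, length(grid) - 2)))),
               "insufficient")
})

test_that("structural invariants hold on randomly generated sets", {
  for (seed in 1:10) {
    rs <- random_set(n_mut = 6, n_day = 10, seed = seed)
    if (max(rs$freq) < 0.01) next
    pc <- frequency_propagator(rs)
    expect_true(all(diff(pc$G) <= 0))
    expect_true(pc$G[1] <= 1 && all(pc$G >= 0))
    # per-trajectory first-passage times are non-decreasing in x
    pm <- evotraj:::passage_matrix(rs, pc$x, 0.01)
    for (k in seq_len(nrow(pm))) {
      v <- pm[k, !is.na(pm[k, ])]
      if (length(v) > 1) expect_true(all(diff(v) >= -1e-9))
    }
    fit <- tryCatch(ptau(rs, min_generations_confident = 0),
                    warning = function(w) NULL)
    if (!is.null(fit) && !is.na(fit$p))
      expect_true(fit$p >= 0 && fit$p <= 1)
  }
})

test_that("print, summary and plot methods run quietly", {
  ts <- worked_five_set()
  fit <- ptau(ts, min_generations_confident = 0)
  expect_output(print(fit), "p-tau selection test")
  expect_output(summary(fit), "Frequency propagator")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
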