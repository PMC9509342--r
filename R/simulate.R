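# Wright-Fisher simulators generating trajectory sets under the three
# selection modes: directional selection (periodic sweeps at low mutation
# supply, clonal interference at high supply) and consumer-resource
# competition generating negative frequency-dependent selection between
# ecotypes. Both track an explicit genotype genealogy (full asexual
# linkage) so each mutation's frequency is the summed frequency of the
# genotypes carrying it and hitchhiking arises naturally.

#' Parameters for the directional-selection Wright-Fisher simulator
#'
#' @param N population size (>= 10). The desk-scale default of 1e5 stands
#'   in for in-vivo populations of 1e7-1e8: the selection-drift balance is
#'   governed by N s and N U, so larger populations are emulated by
#'   scaling s and U.
#' @param U beneficial mutation rate per genome per generation; the
#'   product N U sets the clonal-interference regime.
#' @param s_mean selection coefficient (fixed value, or mean of the
#'   exponential distribution when `s_dist = "exponential"`).
#' @param s_dist `"fixed"` or `"exponential"`.
#' @param T_gen total number of generations to simulate.
#' @param seed integer seed; simulations are fully reproducible from it.
#' @return a `"wf_params"` list.
#' @export
wf_params <- function(N = 1e5, U = 1e-7, s_mean = 0.05,
                      s_dist = c("fixed", "exponential"),
                      T_gen = 8000, seed = 1) {
  s_dist <- match.arg(s_dist)
  N <- as.integer(N)
  stopifnot(N >= 10, U >= 0, s_mean > -1, T_gen >= 1)
  structure(list(N = N, U = U, s_mean = s_mean, s_dist = s_dist,
                 T_gen = as.integer(T_gen), seed = as.integer(seed)),
            class = "wf_params")
}

#' Parameters for the consumer-resource competition simulator
#'
#' Each genotype carries an allocation vector over `R` substitutable
#' resources; its resource fitness is the supply-weighted payoff of its
#' allocation given the population's aggregate consumption (see
#' [resource_fitness()]), which confers a rare-type advantage on underused
#' resources and stabilises ecotype coexistence at supply-proportional
#' frequencies. Mutations perturb the allocation vector and additionally
#' carry a within-ecotype directional benefit (exponential with mean
#' `s_mean`): conditionally beneficial mutations sweep within their
#' ecotype, reaching intermediate population frequencies quickly, while
#' cross-ecotype negative frequency-dependent selection suppresses their
#' fixation.
#'
#' @param R number of resources.
#' @param supply positive resource supply rates (length `R`); normalised
#'   to sum to 1.
#' @param alloc_mut_sd standard deviation of the truncated-Gaussian
#'   perturbation a mutation applies to the allocation vector.
#' @param mu mutation rate per genome per generation.
#' @param s_mean mean within-ecotype selection coefficient of new
#'   mutations (exponential; 0 disables the directional component, making
#'   allocation mutations the only fitness-relevant changes).
#' @param N population size.
#' @param T_gen total generations.
#' @param seed integer seed.
#' @param init `"specialists"` seeds `R` pure-specialist ecotypes at
#'   supply-proportional frequencies (the stable-ecotype regime);
#'   `"generalist"` seeds a single generalist genotype with
#'   supply-proportional allocation (ecotype formation de novo).
#' @return a `"resource_params"` list.
#' @export
resource_params <- function(R = 2, supply = rep(1 / R, R),
                            alloc_mut_sd = 0.05, mu = 5e-7, s_mean = 0.03,
                            N = 1e5, T_gen = 8000, seed = 1,
                            init = c("specialists", "generalist")) {
  init <- match.arg(init)
  R <- as.integer(R)
  N <- as.integer(N)
  stopifnot(R >= 1, length(supply) == R, all(supply > 0), alloc_mut_sd > 0,
            mu >= 0, s_mean >= 0, N >= 10, T_gen >= 1)
  structure(list(R = R, supply = supply / sum(supply),
                 alloc_mut_sd = alloc_mut_sd, mu = mu, s_mean = s_mean,
                 N = N, T_gen = as.integer(T_gen), seed = as.integer(seed),
                 init = init),
            class = "resource_params")
}

#' Pool-seq observation scheme
#'
#' @param sample_days strictly increasing sampling days (non-empty).
#' @param depth sequencing depth per locus (reads; default 300, the mean
#'   alignment depth typical of the pool-seq design emulated here).
#' @param detection_threshold frequencies observed below this are reported
#'   as 0 (default 0.05).
#' @param generations_per_day conversion factor (default 15; use 1 to
#'   specify sampling times directly in generations).
#' @return a `"sampling_scheme"` list.
#' @export
sampling_scheme <- function(sample_days, depth = 300,
                            detection_threshold = 0.05,
                            generations_per_day = 15) {
  sample_days <- as.numeric(sample_days)
  stopifnot(length(sample_days) >= 1, all(sample_days >= 0),
            !is.unsorted(sample_days, strictly = TRUE), depth >= 1,
            detection_threshold >= 0, detection_threshold < 1,
            generations_per_day > 0)
  structure(list(sample_days = sample_days, depth = as.integer(depth),
                 detection_threshold = detection_threshold,
                 generations_per_day = generations_per_day),
            class = "sampling_scheme")
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# binomial depth noise + detection-floor zeroing, using the current RNG
apply_observation <- function(freq, depth, threshold) {
  obs <- matrix(stats::rbinom(length(freq), depth, freq) / depth,
                nrow = nrow(freq))
  obs[obs < threshold] <- 0
  obs
}

# genotype registry used by both simulators; closures keep the loops tidy
new_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$parent <- integer(1024L); env$mut <- integer(1024L); env$n <- 0L
  env
}

reg_add <- function(reg, parent, mut) {
  n <- reg$n + 1L
  if (n > length(reg$parent)) {
    length(reg$parent) <- 2L * length(reg$parent)
    length(reg$mut) <- 2L * length(reg$mut)
  }
  reg$parent[n] <- parent; reg$mut[n] <- mut; reg$n <- n
  n
}

# mutation-id sets per genotype, memoized over the shared genealogy
make_muts_of <- function(reg) {
  cache <- vector("list", reg$n)
  function(gid) {
    v <- cache[[gid]]
    if (!is.null(v)) return(v)
    path <- integer(0); g <- gid
    while (g != 0L && is.null(cache[[g]])) {
      path <- c(path, g)
      g <- reg$parent[g]
    }
    base <- if (g == 0L) integer(0) else cache[[g]]
    for (k in rev(path)) {
      m <- reg$mut[k]
      if (m > 0L) base <- c(base, m)
      cache[[k]] <<- base
    }
    cache[[gid]]
  }
}

# turn genotype snapshots into a per-mutation truth frequency matrix
resolve_truth <- function(reg, snapshots, N) {
  muts_of <- make_muts_of(reg)
  per_sample <- lapply(snapshots, function(sn) {
    if (length(sn$gid) == 0L) return(NULL)
    ml <- lapply(sn$gid, muts_of)
    len <- lengths(ml)
    if (sum(len) == 0L) return(NULL)
    w <- rep(sn$cnt, len)
    rowsum(w, unlist(ml)) / N
  })
  ids <- sort(unique(as.integer(unlist(lapply(per_sample, rownames)))))
  truth <- matrix(0, nrow = length(ids), ncol = length(snapshots))
  for (j in seq_along(per_sample)) {
    f <- per_sample[[j]]
    if (!is.null(f)) truth[match(as.integer(rownames(f)), ids), j] <- f
  }
  list(ids = ids, truth = truth, muts_of = muts_of)
}

# package truth + observation into a trajectory_set with a "truth" attribute
finish_simulation <- function(reg, snapshots, ids, truth, muts_of,
                              m_s, m_origin, m_gid, scheme, host_id, raw,
                              generations_per_day) {
  label <- sprintf("m%05d", ids)
  if (raw) {
    obs <- truth
    keep <- rep(TRUE, length(ids))
  } else {
    obs <- apply_observation(truth, scheme$depth, scheme$detection_threshold)
    keep <- apply(obs, 1L, max) > 0
  }
  parent_mut <- vapply(ids, function(m) {
    pg <- reg$parent[m_gid[m]]
    if (pg == 0L) return(NA_character_)
    anc <- muts_of(pg)
    if (length(anc) == 0L) NA_character_ else sprintf("m%05d", anc[length(anc)])
  }, "")
  truth_df <- data.frame(
    mutation_id = label,
    s = m_s[ids],
    origin_gen = m_origin[ids],
    parent_mut = parent_mut,
    final_freq = truth[, ncol(truth)],
    stringsAsFactors = FALSE
  )
  set <- trajectory_set(
    host_id, scheme$sample_days,
    obs[keep, , drop = FALSE],
    mutation_id = label[keep], target = label[keep],
    func_class = "nonsynonymous",
    generations_per_day = generations_per_day,
    detection_threshold = scheme$detection_threshold
  )
  attr(set, "truth") <- truth_df
  set
}

#' Simulate trajectories under uniform directional selection
#'
#' Wright-Fisher dynamics with beneficial mutations: each generation the
#' genotype counts are multinomially resampled with weights proportional
#' to count times `(1 + s)`, where a genotype's `s` is the sum of its
#' mutations' coefficients; `Poisson(N U)` new mutations arise per
#' generation, each founding a child genotype. With `N U` small,
#' established mutations sweep one at a time (periodic sweeps, p near 1,
#' tau near 2); with `N U` of order 1, concurrent beneficial mutations
#' interfere (clonal interference, p < 1, tau <= 2). Output is sampled at
#' the scheme's days with binomial depth noise and the detection floor
#' applied; mutations never observed above the floor are dropped.
#'
#' @param params a [wf_params()] object.
#' @param scheme a [sampling_scheme()]; the sampling horizon (last day
#'   times `generations_per_day`) must not exceed `params$T_gen`.
#' @param init_mutants optional data frame with columns `count` and `s`:
#'   mutant genotypes seeded at generation 0 (used e.g. to measure
#'   fixation probabilities of a single copy).
#' @param host_id host id for the output set.
#' @param raw if `TRUE`, return the noiseless truth (all mutations, exact
#'   frequencies) instead of the pool-seq observation.
#' @return A [trajectory_set()] with attribute `"truth"`: a data frame of
#'   per-mutation ground truth (`s`, `origin_gen`, `parent_mut`,
#'   `final_freq`, with `final_freq = 1` marking fixation).
#' @export
#' @examples
#' sim <- simulate_directional(
#'   wf_params(N = 1e4, U = 1e-6, s_mean = 0.05, T_gen = 2000, seed = 7),
#'   sampling_scheme(seq(0, 2000, 100), generations_per_day = 1))
simulate_directional <- function(params, scheme, init_mutants = NULL,
                                 host_id = "sim", raw = FALSE) {
  stopifnot(inherits(params, "wf_params"), inherits(scheme, "sampling_scheme"))
  sample_gens <- as.integer(round(scheme$sample_days *
                                    scheme$generations_per_day))
  if (max(sample_gens) > params$T_gen)
    stop("sampling horizon exceeds T_gen")
  N <- params$N; U <- params$U
  draw_s <- if (params$s_dist == "fixed") {
    function() params$s_mean
  } else {
    function() stats::rexp(1L, 1 / params$s_mean)
  }

  with_sim_seed(params$seed, {
    reg <- new_registry()
    anc <- reg_add(reg, 0L, 0L)
    live_gid <- anc; live_cnt <- N; live_s <- 0
    m_s <- numeric(0); m_origin <- integer(0); m_gid <- integer(0)

    add_mutation <- function(parent_row, s_new, gen) {
      mid <- length(m_s) + 1L
      gid <- reg_add(reg, live_gid[parent_row], mid)
      m_s[mid] <<- s_new; m_origin[mid] <<- gen; m_gid[mid] <<- gid
      live_gid <<- c(live_gid, gid)
      live_cnt <<- c(live_cnt, 1L)
      live_s <<- c(live_s, live_s[parent_row] + s_new)
      live_cnt[parent_row] <<- live_cnt[parent_row] - 1L
    }

    if (!is.null(init_mutants)) {
      for (k in seq_len(nrow(init_mutants))) {
        cnt <- as.integer(init_mutants$count[k])
        mid <- length(m_s) + 1L
        gid <- reg_add(reg, anc, mid)
        m_s[mid] <- init_mutants$s[k]; m_origin[mid] <- 0L; m_gid[mid] <- gid
        live_gid <- c(live_gid, gid)
        live_cnt <- c(live_cnt, cnt)
        live_s <- c(live_s, init_mutants$s[k])
        live_cnt[1L] <- live_cnt[1L] - cnt
      }
      if (any(live_cnt < 0)) stop("init_mutants counts exceed N")
    }

    is_sample <- logical(params$T_gen + 1L)
    is_sample[sample_gens + 1L] <- TRUE
    snapshots <- vector("list", length(sample_gens)); si <- 0L
    take <- function() {
      si <<- si + 1L
      stopifnot(sum(live_cnt) == N)
      snapshots[[si]] <<- list(gid = live_gid, cnt = live_cnt)
    }
    if (is_sample[1L]) take()

    for (gen in seq_len(params$T_gen)) {
      live_cnt <- as.vector(stats::rmultinom(1L, N, live_cnt * (1 + live_s)))
      if (any(live_cnt == 0L)) {
        keep <- live_cnt > 0L
        live_gid <- live_gid[keep]; live_cnt <- live_cnt[keep]
        live_s <- live_s[keep]
      }
      if (U > 0) {
        nmut <- stats::rpois(1L, N * U)
        if (nmut > 0L) {
          rows <- sample.int(length(live_cnt), nmut, replace = TRUE,
                             prob = live_cnt)
          for (r in rows)
            if (live_cnt[r] > 0L) add_mutation(r, draw_s(), gen)
          keep <- live_cnt > 0L
          live_gid <- live_gid[keep]; live_cnt <- live_cnt[keep]
          live_s <- live_s[keep]
        }
      }
      if (is_sample[gen + 1L]) take()
      # dynamics frozen: no mutational input and a single surviving genotype
      if (U == 0 && length(live_cnt) == 1L && gen < params$T_gen) {
        while (si < length(sample_gens)) take()
        break
      }
    }

    if (length(m_s) == 0L) {
      set <- trajectory_set(host_id, scheme$sample_days,
                            matrix(0, 0L, length(sample_gens)),
                            mutation_id = character(0),
                            generations_per_day = scheme$generations_per_day,
                            detection_threshold = scheme$detection_threshold)
      attr(set, "truth") <- data.frame(mutation_id = character(0),
                                       s = numeric(0), origin_gen = integer(0),
                                       parent_mut = character(0),
                                       final_freq = numeric(0))
      return(set)
    }
    r <- resolve_truth(reg, snapshots, N)
    finish_simulation(reg, snapshots, r$ids, r$truth, r$muts_of,
                      m_s, m_origin, m_gid, scheme, host_id, raw,
                      scheme$generations_per_day)
  })
}

#' Consumer-resource fitness map
#'
#' Resource-competition payoff of each genotype given the current
#' population composition: `w_g = sum_r supply_r * alloc_gr / xbar_r`,
#' with `xbar_r = sum_h x_h * alloc_hr` the aggregate allocation to
#' resource `r`. A genotype specialising on an underused resource has
#' `w > 1` (rare-type advantage); the deterministic replicator iteration
#' of this map converges to supply-proportional ecotype frequencies.
#' Resources nobody consumes contribute nothing.
#'
#' @param alloc allocation matrix, resources in rows, genotypes in
#'   columns; columns non-negative, summing to 1.
#' @param x genotype frequencies (non-negative, summing to 1).
#' @param supply resource supply fractions (positive, summing to 1).
#' @return per-genotype fitness vector.
#' @export
#' @examples
#' a <- cbind(c(1, 0), c(0, 1))           # two specialists
#' resource_fitness(a, c(0.9, 0.1), c(0.5, 0.5))  # minority type has w > 1
resource_fitness <- function(alloc, x, supply) {
  xbar <- as.vector(alloc %*% x)
  ratio <- ifelse(xbar > 0, supply / xbar, 0)
  as.vector(crossprod(alloc, ratio))
}

#' Simulate trajectories under resource-competition diversifying selection
#'
#' Wright-Fisher dynamics on the consumer-resource fitness map of
#' [resource_fitness()], multiplied by each genotype's accumulated
#' within-ecotype directional benefit `(1 + s)`. Mutations perturb the
#' parental allocation vector by a truncated Gaussian (resampled if the
#' perturbed vector is all zero, then renormalised) and draw a direct
#' benefit from an exponential with mean `s_mean`. In the stable-ecotype
#' regime, conditionally beneficial mutations sweep within their ecotype —
#' reaching intermediate population frequencies on the time scale of their
#' selection coefficients — while negative frequency-dependent selection
#' between ecotypes pins ecotype frequencies near supply proportions and
#' suppresses fixation: the diversifying-selection signature (p well below
#' 0.5, tau far above 3 as an end-of-observation lower bound).
#'
#' @param params a [resource_params()] object.
#' @param scheme a [sampling_scheme()].
#' @param host_id host id for the output set.
#' @param raw if `TRUE`, return the noiseless truth.
#' @return A [trajectory_set()] with a `"truth"` attribute as in
#'   [simulate_directional()].
#' @export
simulate_resource_competition <- function(params, scheme, host_id = "sim",
                                          raw = FALSE) {
  stopifnot(inherits(params, "resource_params"),
            inherits(scheme, "sampling_scheme"))
  sample_gens <- as.integer(round(scheme$sample_days *
                                    scheme$generations_per_day))
  if (max(sample_gens) > params$T_gen)
    stop("sampling horizon exceeds T_gen")
  N <- params$N; R <- params$R; supply <- params$supply

  with_sim_seed(params$seed, {
    reg <- new_registry()
    if (params$init == "specialists" && R > 1L) {
      live_gid <- vapply(seq_len(R), function(i) reg_add(reg, 0L, 0L), 0L)
      live_alloc <- diag(R)
      cnt <- floor(N * supply)
      cnt[1L] <- cnt[1L] + N - sum(cnt)
      live_cnt <- as.integer(cnt)
    } else {
      live_gid <- reg_add(reg, 0L, 0L)
      live_alloc <- matrix(supply, ncol = 1L)
      live_cnt <- N
    }
    live_s <- numeric(length(live_gid))
    m_s <- numeric(0); m_origin <- integer(0); m_gid <- integer(0)

    perturb <- function(a) {
      repeat {
        b <- pmax(0, a + stats::rnorm(R, 0, params$alloc_mut_sd))
        if (sum(b) > 0) return(b / sum(b))
      }
    }

    is_sample <- logical(params$T_gen + 1L)
    is_sample[sample_gens + 1L] <- TRUE
    snapshots <- vector("list", length(sample_gens)); si <- 0L
    take <- function() {
      si <<- si + 1L
      stopifnot(sum(live_cnt) == N)
      snapshots[[si]] <<- list(gid = live_gid, cnt = live_cnt)
    }
    if (is_sample[1L]) take()

    for (gen in seq_len(params$T_gen)) {
      w <- (1 + live_s) * resource_fitness(live_alloc, live_cnt / N, supply)
      live_cnt <- as.vector(stats::rmultinom(1L, N, live_cnt * w))
      if (any(live_cnt == 0L)) {
        keep <- live_cnt > 0L
        live_gid <- live_gid[keep]; live_cnt <- live_cnt[keep]
        live_s <- live_s[keep]
        live_alloc <- live_alloc[, keep, drop = FALSE]
      }
      if (params$mu > 0) {
        nmut <- stats::rpois(1L, N * params$mu)
        if (nmut > 0L) {
          rows <- sample.int(length(live_cnt), nmut, replace = TRUE,
                             prob = live_cnt)
          for (r in rows) {
            if (live_cnt[r] == 0L) next
            mid <- length(m_s) + 1L
            s_new <- if (params$s_mean > 0)
              stats::rexp(1L, 1 / params$s_mean) else 0
            gid <- reg_add(reg, live_gid[r], mid)
            m_s[mid] <- s_new; m_origin[mid] <- gen; m_gid[mid] <- gid
            live_gid <- c(live_gid, gid)
            live_cnt <- c(live_cnt, 1L)
            live_s <- c(live_s, live_s[r] + s_new)
            live_alloc <- cbind(live_alloc, perturb(live_alloc[, r]))
            live_cnt[r] <- live_cnt[r] - 1L
          }
          keep <- live_cnt > 0L
          live_gid <- live_gid[keep]; live_cnt <- live_cnt[keep]
          live_s <- live_s[keep]
          live_alloc <- live_alloc[, keep, drop = FALSE]
        }
      }
      if (is_sample[gen + 1L]) take()
    }

    if (length(m_s) == 0L) {
      set <- trajectory_set(host_id, scheme$sample_days,
                            matrix(0, 0L, length(sample_gens)),
                            mutation_id = character(0),
                            generations_per_day = scheme$generations_per_day,
                            detection_threshold = scheme$detection_threshold)
      attr(set, "truth") <- data.frame(mutation_id = character(0),
                                       s = numeric(0), origin_gen = integer(0),
                                       parent_mut = character(0),
                                       final_freq = numeric(0))
      return(set)
    }
    r <- resolve_truth(reg, snapshots, N)
    finish_simulation(reg, snapshots, r$ids, r$truth, r$muts_of,
                      m_s, m_origin, m_gid, scheme, host_id, raw,
                      scheme$generations_per_day)
  })
}

#' Apply pool-seq observation noise to a dense truth set
#'
#' Subsamples a (typically noiseless) trajectory set at the scheme's days,
#' adds binomial depth noise, and zeroes observations below the detection
#' threshold. Deterministic given `seed`.
#'
#' @param truth a [trajectory_set()] whose day grid contains all scheme
#'   days.
#' @param scheme a [sampling_scheme()].
#' @param seed integer seed.
#' @return a [trajectory_set()] on the scheme's days.
#' @export
subsample <- function(truth, scheme, seed = 1) {
  stopifnot(inherits(truth, "trajectory_set"),
            inherits(scheme, "sampling_scheme"))
  j <- match(scheme$sample_days, truth$days)
  if (anyNA(j))
    stop("scheme day(s) absent from truth grid: ",
         paste(scheme$sample_days[is.na(j)], collapse = ", "))
  f <- truth$freq[, j, drop = FALSE]
  obs <- with_sim_seed(seed,
                       apply_observation(f, scheme$depth,
                                         scheme$detection_threshold))
  set <- trajectory_set(truth$host_id, scheme$sample_days, obs,
                        mutation_id = truth$meta$mutation_id,
                        target = truth$meta$target,
                        func_class = truth$meta$func_class,
                        generations_per_day = truth$generations_per_day,
                        detection_threshold = scheme$detection_threshold)
  attr(set, "depth") <- scheme$depth
  set
}
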