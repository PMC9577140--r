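#' Configuration of the parameter-tracking genetic algorithm
#'
#' Defaults follow the estimation protocol the package implements: a
#' population of 400 individuals initialized by Latin hypercube sampling
#' within the search bounds, tournament selection, two-point crossover,
#' creep mutation, 1500 simulated RR intervals per fitness evaluation with
#' the ten fittest individuals re-evaluated at 5000, one to three
#' generations per data segment depending on the Poincare difference
#' (`dP < 800` gives 1, `800 <= dP < 2000` gives 2, `dP >= 2000` gives 3),
#' and immigrants injected at every new segment (10-70% of the population,
#' growing linearly in `dP`) drawn in equal proportion from an elite
#' archive, from eight fast 16-individual helper GAs run at
#' `n_sim = 750`, and from random sampling.
#'
#' @param pop_size population size.
#' @param n_sim simulated RR intervals per evaluation.
#' @param n_sim_reeval simulated RR intervals for the elite re-evaluation.
#' @param elite_reeval_count number of fittest individuals re-evaluated at
#'   `n_sim_reeval` before the segment estimate is saved.
#' @param dp_thresholds two increasing Poincare-difference thresholds.
#' @param generations_map generations to run below, between and above the
#'   thresholds.
#' @param immigrant_fraction_range immigrant share at `dP = 0` and at
#'   `dP >= dp_thresholds[2]` (linear in between).
#' @param tournament_size tournament size for selection.
#' @param crossover_prob probability that a selected pair is crossed over.
#' @param mutation_rate per-gene creep-mutation probability.
#' @param mutation_step_fraction creep step as a fraction of each
#'   parameter's range (uniform in `+/-` this fraction).
#' @param n_elite individuals copied unchanged into the next generation.
#' @param init_generations generations run on the first segment of a
#'   recording (regardless of its Poincare difference): the population
#'   starts from random Latin hypercube samples and needs a burn-in before
#'   per-segment tracking effort is enough; later segments inherit a
#'   converged population.
#' @param fast_ga list with `count`, `pop`, `n_sim`, `generations` for the
#'   helper GAs feeding the immigrant pool.
#' @param archive_size elite-archive size carried between segments.
#' @param bounds search box, see [avn_bounds()].
#' @param n_per_pathway nodes per pathway chain in the simulator.
#' @param seed master seed; every stochastic step of
#'   [estimate_recording()] derives from it.
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 400, n_sim = 1500, n_sim_reeval = 5000,
                      elite_reeval_count = 10,
                      dp_thresholds = c(800, 2000),
                      generations_map = c(1L, 2L, 3L),
                      immigrant_fraction_range = c(0.10, 0.70),
                      tournament_size = 4, crossover_prob = 0.9,
                      mutation_rate = 0.3, mutation_step_fraction = 0.05,
                      n_elite = 1, init_generations = 10,
                      fast_ga = list(count = 8, pop = 16, n_sim = 750,
                                     generations = 3),
                      archive_size = 10,
                      bounds = avn_bounds(), n_per_pathway = 10L,
                      seed = 1L) {
  stopifnot(length(dp_thresholds) == 2, diff(dp_thresholds) > 0,
            length(generations_map) == 3,
            all(immigrant_fraction_range >= 0),
            all(immigrant_fraction_range <= 1))
  structure(as.list(environment()), class = "ga_config")
}

#' Latin hypercube initialization of a GA population
#'
#' Each of the 12 parameter dimensions is stratified into `pop_size`
#' equal-width slices with exactly one sample per slice, scaled to the
#' search bounds.  Uses the session RNG.
#'
#' @param pop_size number of individuals.
#' @param bounds see [avn_bounds()].
#' @return numeric `pop_size x 12` matrix, columns named by parameter.
#' @export
init_population <- function(pop_size, bounds = avn_bounds()) {
  u <- lhs::randomLHS(pop_size, 12L)
  pop <- sweep(u, 2L, bounds$range, `*`)
  pop <- sweep(pop, 2L, bounds$lower, `+`)
  colnames(pop) <- avn_param_names()
  pop
}

# evaluate one parameter vector on a segment; returns list(eps, rr)
eval_theta_internal <- function(theta_vec, seg, n_sim, seed,
                                n_per_pathway = 10L) {
  rr <- cpp_simulate_poisson(as.numeric(theta_vec), seg$lambda_hz,
                             seg$rr_min, as.integer(n_per_pathway),
                             as.numeric(seed), as.integer(n_sim), -1)
  rr <- diff(rr)
  if (length(rr) < 2)
    return(list(eps = Inf, rr = rr))
  list(eps = poincare_error(seg$hist, poincare_histogram(rr)), rr = rr)
}

#' Fitness evaluation of a parameter vector on a data segment
#'
#' Simulates `n_sim` RR intervals at the segment's arrival rate with the
#' segment's `rr_min` as coupling-node refractory period and returns the
#' Poincare-histogram error against the segment data.  Parameter sets whose
#' simulation emits fewer than two RR intervals get `Inf`.
#'
#' @param theta an [avn_theta()] or plain 12-vector.
#' @param seg an `rr_segment` from [segment_recording()].
#' @param n_sim number of RR intervals to simulate.
#' @param seed impulse-train seed.
#' @param n_per_pathway nodes per pathway chain.
#' @return scalar error `eps`.
#' @export
evaluate_theta <- function(theta, seg, n_sim = 1500, seed = 1,
                           n_per_pathway = 10L) {
  eval_theta_internal(as.numeric(theta), seg, n_sim, seed, n_per_pathway)$eps
}

#' Tournament selection
#'
#' Draws a tournament of `k` distinct individuals uniformly and returns the
#' index of the one with the lowest error.
#'
#' @param eps vector of fitness errors of the current population.
#' @param k tournament size (capped at the population size).
#' @return index of the winner.
#' @export
tournament_select <- function(eps, k = 4) {
  cand <- sample.int(length(eps), min(k, length(eps)))
  cand[which.min(eps[cand])]
}

#' Two-point crossover of two parameter vectors
#'
#' Two cut points are drawn among the 11 positions between genes; the block
#' between them is swapped.  Children are automatically within bounds.
#'
#' @param a,b numeric 12-vectors.
#' @return list with `child1`, `child2`.
#' @export
two_point_crossover <- function(a, b) {
  cuts <- sort(sample.int(11L, 2L))
  mid <- (cuts[1] + 1L):cuts[2]
  c1 <- a; c2 <- b
  c1[mid] <- b[mid]
  c2[mid] <- a[mid]
  list(child1 = c1, child2 = c2)
}

#' Creep mutation
#'
#' Each gene is independently mutated with probability `rate` by a uniform
#' step within `+/- step_fraction * r(p)` and clipped to the bounds.
#'
#' @param x numeric 12-vector.
#' @param rate per-gene mutation probability.
#' @param step_fraction maximal step as a fraction of each parameter range.
#' @param bounds see [avn_bounds()].
#' @return mutated 12-vector.
#' @export
creep_mutate <- function(x, rate = 0.3, step_fraction = 0.05,
                         bounds = avn_bounds()) {
  hit <- stats::runif(length(x)) < rate
  if (any(hit)) {
    step <- stats::runif(length(x), -1, 1) * step_fraction * bounds$range
    x[hit] <- x[hit] + step[hit]
    x <- pmin(pmax(x, bounds$lower), bounds$upper)
  }
  x
}

#' Number of GA generations for a given Poincare difference
#'
#' Piecewise-constant map: more generations are spent on segments where the
#' RR-series characteristics are changing fast.
#'
#' @param dp Poincare difference `dP(i) >= 0` (vectorized).
#' @param thresholds,map see [ga_config()].
#' @return integer vector of generation counts.
#' @export
generations_for <- function(dp, thresholds = c(800, 2000),
                            map = c(1L, 2L, 3L)) {
  stopifnot(all(dp >= 0))
  map[1L + (dp >= thresholds[1]) + (dp >= thresholds[2])]
}

#' Immigrant share for a given Poincare difference
#'
#' Linear ramp from `range[1]` at `dP = 0` to `range[2]` at
#' `dP >= dp_max`, mirroring the exploration/exploitation trade-off.
#'
#' @param dp Poincare difference (vectorized).
#' @param range immigrant fractions at the two ends.
#' @param dp_max saturation point (default: upper generations threshold).
#' @return fraction(s) in `[range[1], range[2]]`.
#' @export
immigrant_fraction <- function(dp, range = c(0.10, 0.70), dp_max = 2000) {
  range[1] + (range[2] - range[1]) * pmin(dp, dp_max) / dp_max
}

new_seed <- function() sample.int(2147483646L, 1L)

# one fast helper GA on the current segment; returns list(pop, eps, rr)
run_fast_ga <- function(seg, config) {
  fg <- config$fast_ga
  pop <- init_population(fg$pop, config$bounds)
  ev <- lapply(seq_len(fg$pop), function(j)
    eval_theta_internal(pop[j, ], seg, fg$n_sim, new_seed(),
                        config$n_per_pathway))
  eps <- vapply(ev, `[[`, numeric(1), "eps")
  rrs <- lapply(ev, `[[`, "rr")
  for (g in seq_len(fg$generations)) {
    st <- ga_generation(pop, eps, seg, config, n_sim = fg$n_sim)
    pop <- st$pop; eps <- st$eps; rrs <- st$rr
  }
  list(pop = pop, eps = eps, rr = rrs)
}

# one generation: elitism + tournament/crossover/mutation, full re-evaluation
ga_generation <- function(pop, eps, seg, config, n_sim = config$n_sim) {
  n <- nrow(pop)
  new_pop <- matrix(NA_real_, n, ncol(pop), dimnames = dimnames(pop))
  n_elite <- min(config$n_elite, n)
  if (n_elite > 0) {
    elite <- order(eps)[seq_len(n_elite)]
    new_pop[seq_len(n_elite), ] <- pop[elite, , drop = FALSE]
  }
  j <- n_elite
  while (j < n) {
    p1 <- pop[tournament_select(eps, config$tournament_size), ]
    p2 <- pop[tournament_select(eps, config$tournament_size), ]
    if (stats::runif(1) < config$crossover_prob) {
      cr <- two_point_crossover(p1, p2)
      p1 <- cr$child1; p2 <- cr$child2
    }
    for (child in list(p1, p2)) {
      if (j >= n) break
      j <- j + 1
      new_pop[j, ] <- creep_mutate(child, config$mutation_rate,
                                   config$mutation_step_fraction,
                                   config$bounds)
    }
  }
  ev <- lapply(seq_len(n), function(q)
    eval_theta_internal(new_pop[q, ], seg, n_sim, new_seed(),
                        config$n_per_pathway))
  list(pop = new_pop,
       eps = vapply(ev, `[[`, numeric(1), "eps"),
       rr = lapply(ev, `[[`, "rr"))
}

#' Build the immigrant pool for a new data segment
#'
#' `n` individuals are drawn in (as) equal (as possible) proportion from
#' three sources: (1) the elite archive of the previous segment, whose
#' stored simulated output is re-scored against the new segment's histogram
#' without re-simulation; (2) the best individuals of `fast_ga$count` fast
#' helper GAs run on the new segment; (3) random Latin hypercube samples.
#' Shortfalls in sources 1 and 2 (e.g. an empty archive on the first
#' segment) are topped up with random samples.
#'
#' @param n number of immigrants.
#' @param archive list with `pop` (matrix) and `rr` (list of simulated RR
#'   vectors), or `NULL`.
#' @param seg the new `rr_segment`.
#' @param config a [ga_config()].
#' @return list with `pop` (`n x 12` matrix) and `eps` (numeric; `NA` for
#'   random immigrants, which are scored during the next generation).
#' @export
make_immigrants <- function(n, archive, seg, config) {
  if (n <= 0) return(list(pop = NULL, eps = numeric(0)))
  share <- rep(n %/% 3L, 3L)
  extra <- n - sum(share)
  if (extra > 0) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
  pops <- list(); epss <- list()

  # source 1: elite archive, re-scored on the new segment from stored output
  n1 <- 0L
  if (!is.null(archive) && nrow(archive$pop) > 0 && share[1] > 0) {
    n1 <- min(share[1], nrow(archive$pop))
    eps1 <- vapply(seq_len(n1), function(q) {
      rr <- archive$rr[[q]]
      if (length(rr) < 2) return(Inf)
      poincare_error(seg$hist, poincare_histogram(rr))
    }, numeric(1))
    pops <- c(pops, list(archive$pop[seq_len(n1), , drop = FALSE]))
    epss <- c(epss, list(eps1))
  }

  # source 2: fast helper GAs on the new segment
  n2 <- share[2]
  if (n2 > 0) {
    fast <- list(pop = NULL, eps = numeric(0))
    for (f in seq_len(config$fast_ga$count)) {
      res <- run_fast_ga(seg, config)
      fast$pop <- rbind(fast$pop, res$pop)
      fast$eps <- c(fast$eps, res$eps)
    }
    take <- order(fast$eps)[seq_len(min(n2, length(fast$eps)))]
    pops <- c(pops, list(fast$pop[take, , drop = FALSE]))
    epss <- c(epss, list(fast$eps[take]))
    n2 <- length(take)
  }

  # source 3 (+ shortfall top-up): random samples
  n3 <- n - n1 - n2
  if (n3 > 0) {
    pops <- c(pops, list(init_population(n3, config$bounds)))
    epss <- c(epss, list(rep(NA_real_, n3)))
  }
  list(pop = do.call(rbind, pops), eps = unlist(epss))
}

#' Track model parameters across the sliding segments of a recording
#'
#' For each segment in order: the Poincare difference `dP(i)` of the
#' surrounding RR stream sets the optimization effort; immigrants replace
#' the lowest-fitness members; `generations_for(dP)` generations of
#' tournament selection, two-point crossover and creep mutation are run with
#' every individual evaluated at `n_sim` simulated RR intervals; the ten
#' fittest are re-evaluated at `n_sim_reeval` and the best one is saved as
#' the segment estimate.  The population persists across segments, so slow
#' parameter drift is tracked cheaply while regime switches (large `dP`)
#' trigger extra generations and more immigrants.
#'
#' @param segments list of `rr_segment`s from [segment_recording()].
#' @param rr_stream the recording's full retained RR sequence (ms), used to
#'   compute `dP(i)`; when too short for a `dP` window, `dP = 0` is used.
#' @param config a [ga_config()].
#' @param adaptive set `FALSE` to force a fixed single-generation,
#'   fixed-immigrant-share GA that ignores `dP` (reference mode for
#'   comparing against the adaptive schedule).
#' @param verbose print per-segment progress.
#' @return object of class `avn_trend`: data frame with columns `i`,
#'   `t_clock_h`, the 12 parameter estimates, `epsilon`, `dp`,
#'   `generations`, `n_immigrants`.  Attribute `config` stores the
#'   configuration used.
#' @export
estimate_recording <- function(segments, rr_stream = NULL,
                               config = ga_config(), adaptive = TRUE,
                               verbose = FALSE) {
  stopifnot(length(segments) >= 1)
  with_preserved_seed(config$seed, function() {
    bounds <- config$bounds
    pop <- init_population(config$pop_size, bounds)
    eps <- rep(NA_real_, config$pop_size)
    rrs <- vector("list", config$pop_size)
    archive <- NULL
    n_dp_need <- 3000L
    rows <- vector("list", length(segments))

    for (s in seq_along(segments)) {
      seg <- segments[[s]]
      dp <- 0
      if (!is.null(rr_stream) && length(rr_stream) >= n_dp_need)
        dp <- poincare_difference(rr_stream, seg$i)

      if (adaptive) {
        n_gen <- generations_for(dp, config$dp_thresholds,
                                 config$generations_map)
        frac <- immigrant_fraction(dp, config$immigrant_fraction_range,
                                   config$dp_thresholds[2])
      } else {
        n_gen <- 1L
        frac <- config$immigrant_fraction_range[1]
      }
      if (s == 1L) n_gen <- max(n_gen, config$init_generations)
      n_imm <- round(frac * config$pop_size)

      imm <- make_immigrants(n_imm, archive, seg, config)
      if (n_imm > 0) {
        worst <- order(eps, decreasing = TRUE, na.last = FALSE)[seq_len(n_imm)]
        pop[worst, ] <- imm$pop
        eps[worst] <- imm$eps
        rrs[worst] <- rep(list(numeric(0)), n_imm)
      }
      # unevaluated members (first segment, random immigrants) rank worst
      eps_sel <- ifelse(is.na(eps), Inf, eps)

      for (g in seq_len(n_gen)) {
        st <- ga_generation(pop, eps_sel, seg, config)
        pop <- st$pop; eps_sel <- st$eps; rrs <- st$rr
      }
      eps <- eps_sel

      # elite re-evaluation at higher n_sim before saving the estimate
      top <- order(eps)[seq_len(min(config$elite_reeval_count,
                                    length(eps)))]
      re_eps <- vapply(top, function(q)
        eval_theta_internal(pop[q, ], seg, config$n_sim_reeval, new_seed(),
                            config$n_per_pathway)$eps, numeric(1))
      best <- top[which.min(re_eps)]
      theta_hat <- pop[best, ]

      archive <- list(pop = pop[top, , drop = FALSE], rr = rrs[top])

      rows[[s]] <- c(i = seg$i, t_clock_h = seg$t_clock_h, theta_hat,
                     epsilon = min(re_eps), dp = dp,
                     generations = n_gen, n_immigrants = n_imm)
      if (verbose)
        message(sprintf(
          "segment %d/%d: dP=%.0f gen=%d imm=%d best eps=%.2f",
          s, length(segments), dp, n_gen, n_imm, min(re_eps)))
    }
    out <- as.data.frame(do.call(rbind, rows))
    class(out) <- c("avn_trend", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Read or write a parameter-trend table as CSV
#'
#' Columns: `i`, `t_clock_h`, the 12 parameters in fixed order, `epsilon`,
#' plus diagnostics when present.
#'
#' @param trend an `avn_trend` data frame from [estimate_recording()].
#' @param path file path.
#' @export
write_trend_csv <- function(trend, path) {
  utils::write.csv(as.data.frame(trend), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trend_csv
#' @export
read_trend_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("avn_trend", "data.frame")
  out
}
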