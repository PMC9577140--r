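test_that("Latin hypercube initialization stratifies every dimension", {
  b <- avn_bounds()
  set.seed(7)
  pop <- init_population(50, b)
  expect_equal(dim(pop), c(50, 12))
  expect_true(all(sweep(pop, 2, b$lower, `>=`)))
  expect_true(all(sweep(pop, 2, b$upper, `<=`)))
  # exactly one sample per equal-width stratum in each dimension
  for (j in 1:12) {
    u <- (pop[, j] - b$lower[j]) / b$range[j]
    expect_equal(sort(floor(u * 50)), 0:49)
  }
})

test_that("LHS marginals are uniform within Kolmogorov-Smirnov tolerance", {
  b <- avn_bounds()
  set.seed(11)
  pop <- init_population(400, b)
  for (j in c(1, 5, 12)) {
    u <- (pop[, j] - b$lower[j]) / b$range[j]
    expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
  }
})

test_that("tournament selection picks the fittest of the drawn candidates", {
  eps <- c(5, 1, 3, 7, 2)
  set.seed(3)
  # k = pop size: the global best must always win
  for (r in 1:20) expect_equal(tournament_select(eps, k = 5), 2)
  # selection pressure: mean error of winners below population mean
  set.seed(4)
  eps2 <- runif(50, 1, 100)
  winners <- replicate(1000, tournament_select(eps2, 4))
  expect_lt(mean(eps2[winners]), mean(eps2))
})

test_that("two-point crossover swaps the middle block and conserves genes", {
  a <- 1:12; b <- 101:112
  set.seed(2)
  for (r in 1:50) {
    ch <- two_point_crossover(a, b)
    expect_equal(sort(c(ch$child1, ch$child2)), sort(c(a, b)))
    # children are a/b outside one contiguous block
    expect_true(all(ch$child1 %in% c(a, b)))
    swapped <- which(ch$child1 != a)
    if (length(swapped))
      expect_equal(swapped, seq(min(swapped), max(swapped)))
  }
  same <- two_point_crossover(a, a)
  expect_equal(same$child1, a)
  expect_equal(same$child2, a)
})

test_that("creep mutation respects rate, step size and bounds", {
  b <- avn_bounds()
  x <- (b$lower + b$upper) / 2
  expect_equal(creep_mutate(x, rate = 0, bounds = b), x)

  # genes at the upper bound stay clipped
  set.seed(9)
  up <- b$upper
  for (r in 1:20) {
    m <- creep_mutate(up, rate = 1, step_fraction = 0.05, bounds = b)
    expect_true(all(m <= b$upper & m >= b$lower))
    expect_true(all(abs(m - up) <= 0.05 * b$range + 1e-9))
  }

  # empirical per-gene mutation frequency within a binomial CI
  set.seed(10)
  hits <- replicate(2000, sum(creep_mutate(x, rate = 0.3, bounds = b) != x))
  p_hat <- mean(hits) / 12
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / (2000 * 12)))
})

test_that("generation count and immigrant share follow the Poincare difference", {
  expect_equal(generations_for(500), 1L)
  expect_equal(generations_for(800), 2L)
  expect_equal(generations_for(1999), 2L)
  expect_equal(generations_for(2000), 3L)
  expect_equal(generations_for(c(0, 799.9, 800, 5000)), c(1L, 1L, 2L, 3L))
  expect_error(generations_for(-1))

  expect_equal(immigrant_fraction(0), 0.10)
  expect_equal(immigrant_fraction(1000), 0.40)
  expect_equal(immigrant_fraction(2000), 0.70)
  expect_equal(immigrant_fraction(99999), 0.70)
})

test_that("fitness evaluation is deterministic under seed and flags degenerate thetas", {
  theta <- avn_theta_baseline()
  rr <- simulate_rr(theta, 5, 1000, 350, seed = 50)$rr_ms
  seg <- make_segment(rr, lambda_hz = 5)
  e1 <- evaluate_theta(theta, seg, n_sim = 500, seed = 8)
  e2 <- evaluate_theta(theta, seg, n_sim = 500, seed = 8)
  expect_identical(e1, e2)
  expect_true(is.finite(e1) && e1 > 0)

  # maximal refractoriness at a high atrial rate: the error stays defined
  # (refractoriness is anchored to the last conducted impulse, so nodes
  # always conduct the first impulse after recovery)
  slow <- avn_theta(c(650, 700, 300, 650, 700, 300, 30, 75, 300, 30, 75, 300))
  seg_fast <- make_segment(rr, lambda_hz = 25)
  e_slow <- evaluate_theta(slow, seg_fast, n_sim = 200, seed = 1)
  expect_true(is.finite(e_slow) || is.infinite(e_slow))
  expect_gt(e_slow, 0)
  # the sentinel path: a simulation with fewer than two RR intervals
  seg_tiny <- make_segment(rr, lambda_hz = 5)
  sim <- simulate_rr(slow, 5, 1, seg_tiny$rr_min, seed = 1)
  expect_lt(length(sim$rr_ms), 2)
})

test_that("self-consistency: the generating theta scores far better than a distant one", {
  theta <- avn_theta_baseline()
  rr <- simulate_rr(theta, 5, 1000, 350, seed = 60)$rr_ms
  seg <- make_segment(rr, lambda_hz = 5)
  e_true <- evaluate_theta(theta, seg, n_sim = 3000, seed = 61)
  far <- avn_theta(c(650, 700, 60, 650, 700, 60, 30, 75, 40, 30, 75, 40))
  e_far <- evaluate_theta(far, seg, n_sim = 3000, seed = 61)
  expect_lt(e_true, e_far / 5)
})

test_that("immigrants are drawn from the three sources in equal proportion", {
  theta <- avn_theta_baseline()
  rr <- simulate_rr(theta, 5, 1000, 350, seed = 70)$rr_ms
  seg <- make_segment(rr, lambda_hz = 5)
  cfg <- ga_config(pop_size = 12, n_sim = 100,
                   fast_ga = list(count = 1, pop = 4, n_sim = 100,
                                  generations = 1))
  archive <- list(pop = init_population(10, cfg$bounds),
                  rr = replicate(10, simulate_rr(theta, 5, 100, 350,
                                                 seed = 1)$rr_ms,
                                 simplify = FALSE))
  set.seed(5)
  imm <- make_immigrants(9, archive, seg, cfg)
  expect_equal(nrow(imm$pop), 9)
  # archive share re-scored (finite), random share unscored (NA)
  expect_equal(sum(is.finite(imm$eps[1:3])), 3)
  expect_equal(sum(is.na(imm$eps)), 3)
  b <- cfg$bounds
  expect_true(all(sweep(imm$pop, 2, b$lower, `>=`)) &&
              all(sweep(imm$pop, 2, b$upper, `<=`)))

  # empty archive: its share falls back to random sampling
  set.seed(6)
  imm2 <- make_immigrants(9, NULL, seg, cfg)
  expect_equal(nrow(imm2$pop), 9)
  expect_equal(sum(is.na(imm2$eps)), 6)
})

test_that("recording estimation tracks a stationary truth and is reproducible", {
  theta <- avn_theta_baseline()
  rec <- generate_recording(function(t) as.numeric(theta), function(t) 5,
                            duration_h = 0.5, rr_min_coupling = 350,
                            seed = 4)
  afr <- condition_lambda(rec$afr, filter_width = 15)
  segs <- segment_recording(rec$rr, afr, n = 1000, stride_s = 300)
  expect_gte(length(segs), 4)
  cfg <- ga_config(pop_size = 30, n_sim = 400, n_sim_reeval = 1000,
                   elite_reeval_count = 5,
                   fast_ga = list(count = 1, pop = 8, n_sim = 300,
                                  generations = 1),
                   seed = 11)
  tr <- estimate_recording(segs, rec$rr$intervals$rr_ms, cfg)
  expect_s3_class(tr, "avn_trend")
  expect_equal(nrow(tr), length(segs))
  b <- cfg$bounds
  th_cols <- as.matrix(as.data.frame(tr)[, avn_param_names()])
  expect_true(all(sweep(th_cols, 2, b$lower, `>=`)) &&
              all(sweep(th_cols, 2, b$upper, `<=`)))
  expect_true(all(is.finite(tr$epsilon)))
  # the tracked error approaches the generating process error
  e_true <- median(vapply(segs, function(s)
    evaluate_theta(theta, s, n_sim = 1000, seed = 90), numeric(1)))
  expect_lt(median(tr$epsilon), 3 * e_true)

  tr2 <- estimate_recording(segs, rec$rr$intervals$rr_ms, cfg)
  expect_equal(as.data.frame(tr), as.data.frame(tr2))

  # trend CSV round-trip
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend_csv(tr, path)
  back <- read_trend_csv(path)
  expect_equal(back$R_min_FP, tr$R_min_FP, tolerance = 1e-9)
})
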