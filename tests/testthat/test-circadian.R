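test_that("phase estimation recovers a planted common phase", {
  b <- avn_bounds()
  t_h <- seq(0, 23.75, by = 0.25)
  means <- as.numeric(avn_theta_baseline())
  tr <- make_trend(t_h, means, amps = 0.05 * b$range, phi = 1.0,
                   noise_sd = 0.01 * b$range, seed = 101)
  ph <- estimate_phase(tr)
  expect_false(ph$degenerate)
  expect_lt(abs(ph$phi - 1.0), 0.1)
  expect_true(all(ph$pc_fits$a >= 0))

  # invariant to adding a constant to every parameter trend
  tr2 <- tr
  for (p in avn_param_names()) tr2[[p]] <- tr2[[p]] + 11
  expect_equal(estimate_phase(tr2)$phi, ph$phi, tolerance = 1e-6)
})

test_that("negative planted amplitude is reported as positive with a pi shift", {
  b <- avn_bounds()
  t_h <- seq(0, 23.5, by = 0.5)
  tr <- make_trend(t_h, as.numeric(avn_theta_baseline()),
                   amps = -0.05 * b$range, phi = 0.4,
                   noise_sd = 0.005 * b$range, seed = 102)
  ph <- estimate_phase(tr)
  # -a cos(wt + 0.4) = a cos(wt + 0.4 - pi)
  expect_lt(abs(ph$phi - (0.4 - pi)), 0.1)
})

test_that("the dominant of two planted rhythms sets the phase", {
  b <- avn_bounds()
  t_h <- seq(0, 23.75, by = 0.25)
  means <- as.numeric(avn_theta_baseline())
  set.seed(103)
  X <- sapply(1:12, function(j) {
    if (j <= 6)
      means[j] + 0.09 * b$range[j] * cos(2 * pi / 24 * t_h + 0.8)
    else
      means[j] + 0.03 * b$range[j] * cos(2 * pi / 24 * t_h - 2.0)
  })
  X <- X + matrix(rnorm(length(t_h) * 12, 0, 0.005), length(t_h), 12) *
    rep(b$range, each = length(t_h))
  colnames(X) <- avn_param_names()
  tr <- data.frame(i = seq_along(t_h), t_clock_h = t_h, X, epsilon = 1)
  ph <- estimate_phase(tr)
  expect_lt(abs(ph$phi - 0.8), 0.1)
})

test_that("constant trends are flagged degenerate", {
  t_h <- seq(0, 23, by = 1)
  tr <- make_trend(t_h, as.numeric(avn_theta_baseline()), amps = rep(0, 12),
                   phi = 0)
  ph <- estimate_phase(tr)
  expect_true(ph$degenerate)
  expect_true(is.na(ph$phi))
})

test_that("noiseless zero-variance cohort is recovered exactly by the OLS limit", {
  b <- avn_bounds()
  t_h <- seq(0, 23, by = 1)
  alpha <- 400; beta <- 30
  alpha_m <- c(Verapamil = 50, Metoprolol = 35)
  beta_m <- c(Verapamil = -5, Metoprolol = -12)
  phi <- 1.03
  rows <- list(); phs <- list()
  for (pat in 1:4) for (m in c("Baseline", "Verapamil", "Metoprolol")) {
    am <- if (m == "Baseline") 0 else alpha_m[[m]]
    bm <- if (m == "Baseline") 0 else beta_m[[m]]
    y <- (alpha + am) + (beta + bm) * cos(2 * pi / 24 * t_h + phi)
    X <- matrix(rep(y, 12), ncol = 12,
                dimnames = list(NULL, avn_param_names()))
    rows[[length(rows) + 1]] <- data.frame(patient = pat, treatment = m,
                                           t_h = t_h, X)
    phs[[length(phs) + 1]] <- data.frame(patient = pat, treatment = m,
                                         phi = phi)
  }
  fit <- suppressWarnings(  # lm warns on an essentially perfect fit
    fit_mixed_cosinor(do.call(rbind, rows), do.call(rbind, phs),
                      random_effects = FALSE,
                      parameters = "R_min_FP"))
  fx <- fit$fixed
  get <- function(effect, trt)
    fx$estimate[fx$effect == effect & fx$treatment == trt]
  expect_equal(get("alpha", "Baseline"), alpha, tolerance = 1e-8)
  expect_equal(get("beta", "Baseline"), beta, tolerance = 1e-8)
  expect_equal(get("alpha_m", "Verapamil"), 50, tolerance = 1e-8)
  expect_equal(get("beta_m", "Metoprolol"), -12, tolerance = 1e-8)
  # baseline rows carry no drug terms
  expect_false(any(fx$treatment == "Baseline" &
                   fx$effect %in% c("alpha_m", "beta_m")))
})

test_that("the OLS mode agrees with lm and the mixed fit recovers planted effects", {
  set.seed(104)
  t_h <- seq(0, 23, by = 1)
  rows <- list(); phs <- list()
  for (pat in 1:8) {
    eta <- rnorm(1, 0, 15); xi <- rnorm(1, 0, 4)
    for (m in c("Baseline", "Verapamil")) {
      am <- if (m == "Baseline") 0 else 45
      y <- (420 + am + eta) + (28 + xi) * cos(2 * pi / 24 * t_h + 0.9) +
        rnorm(length(t_h), 0, 5)
      X <- matrix(rep(y, 12), ncol = 12,
                  dimnames = list(NULL, avn_param_names()))
      rows[[length(rows) + 1]] <- data.frame(patient = pat, treatment = m,
                                             t_h = t_h, X)
      phs[[length(phs) + 1]] <- data.frame(patient = pat, treatment = m,
                                           phi = 0.9)
    }
  }
  trends <- do.call(rbind, rows); phases <- do.call(rbind, phs)

  ols <- fit_mixed_cosinor(trends, phases, random_effects = FALSE,
                           parameters = "R_min_FP")
  d <- merge(trends, phases, by = c("patient", "treatment"))
  d$cvar <- cos(2 * pi / 24 * d$t_h + d$phi)
  d$treatment <- relevel(factor(d$treatment), "Baseline")
  ref <- lm(R_min_FP ~ treatment * cvar, data = d)
  expect_equal(sort(ols$fixed$estimate), sort(unname(coef(ref))),
               tolerance = 1e-8)

  mixed <- fit_mixed_cosinor(trends, phases, parameters = "R_min_FP")
  fx <- mixed$fixed
  am_hat <- fx[fx$effect == "alpha_m", ]
  expect_lt(abs(am_hat$estimate - 45), 10)
  expect_true(am_hat$ci_lower < 45 + 15 && am_hat$ci_upper > 45 - 15)
  expect_true(!is.null(mixed$ranef_sd))

  # single-treatment input: drug effects flagged inestimable
  base_only <- trends[trends$treatment == "Baseline", ]
  ph_only <- phases[phases$treatment == "Baseline", ]
  single <- fit_mixed_cosinor(base_only, ph_only, parameters = "R_min_FP")
  expect_false(single$drug_effects)
  expect_false(any(single$fixed$effect %in% c("alpha_m", "beta_m")))
})

test_that("range-weighted RMSE behaves as a weighted residual norm", {
  b <- avn_bounds()
  t_h <- seq(0, 23, by = 1)
  means <- as.numeric(avn_theta_baseline())
  amps <- 0.04 * b$range
  tr <- make_trend(t_h, means, amps, phi = 1.2)
  cosine <- data.frame(parameter = avn_param_names(), m = means, a = amps,
                       phi = 1.2)
  expect_equal(weighted_rmse(tr, cosine), 0, tolerance = 1e-9)

  # constant offset delta on one parameter contributes delta / (12 r(p))
  delta <- 37
  tr2 <- tr
  tr2$R_min_FP <- tr2$R_min_FP + delta
  expect_equal(weighted_rmse(tr2, cosine),
               delta / (12 * b$range[["R_min_FP"]]), tolerance = 1e-9)

  # scaling a parameter and its range together leaves it unchanged
  tr3 <- tr; cosine3 <- cosine; b3 <- b
  tr3$tau_D_SP <- 2 * tr3$tau_D_SP
  cosine3[cosine3$parameter == "tau_D_SP", c("m", "a")] <-
    2 * cosine3[cosine3$parameter == "tau_D_SP", c("m", "a")]
  b3$range["tau_D_SP"] <- 2 * b3$range["tau_D_SP"]
  expect_equal(weighted_rmse(tr3, cosine3, b3), 0, tolerance = 1e-9)
})

test_that("paired Wilcoxon/BH comparisons find planted shifts and respect the null", {
  set.seed(105)
  pats <- 1:30
  base <- data.frame(patient = pats, treatment = "Baseline",
                     R_min_FP = rnorm(30, 435, 40),
                     HR = rnorm(30, 95, 8))
  drug <- base
  drug$treatment <- "Verapamil"
  drug$R_min_FP <- drug$R_min_FP + 50 + rnorm(30, 0, 10)
  drug$HR <- drug$HR + rnorm(30, 0, 2)  # null metric
  res <- compare_recording_averages(rbind(base, drug))
  expect_true(res$significant[res$metric == "R_min_FP"])
  expect_false(res$significant[res$metric == "HR"])
  expect_equal(res$n_pairs, c(30, 30))

  # identical averages: no significance, p = 1
  res2 <- compare_recording_averages(rbind(base, transform(base,
                                           treatment = "Diltiazem")))
  expect_true(all(!res2$significant))
  expect_true(all(res2$p_value == 1))

  # fewer than 6 complete pairs: flagged underpowered
  res3 <- compare_recording_averages(rbind(base[1:4, ], drug[1:4, ]))
  expect_true(all(res3$underpowered))
  expect_true(all(!res3$significant))

  # patients missing one member of a pair are dropped
  res4 <- compare_recording_averages(rbind(base, drug[1:20, ]))
  expect_equal(unique(res4$n_pairs), 20)
})
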