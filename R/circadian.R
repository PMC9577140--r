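#' Circadian phase of a recording via PCA and cosinor fitting
#'
#' The phase of the 24-hour rhythm is assumed common to all 12 model
#' parameters of a recording.  The 12 parameter trends are standardized
#' (divided by their search ranges `r(p)` by default, so millisecond-scale
#' parameters do not dominate), decomposed by principal component analysis,
#' and each principal-component projection is fitted to
#' `m_c + a_c * cos(2*pi*t/24 + phi_c)` by Nelder-Mead simplex search.  The
#' recording phase is the `phi_c` of the component with the largest fitted
#' amplitude; negative amplitudes are made positive by a phase shift of pi.
#'
#' @param trend an `avn_trend` data frame (columns `t_clock_h` and the 12
#'   parameters), or any data frame with those columns.
#' @param bounds see [avn_bounds()]; supplies the standardization ranges.
#' @param standardize `"range"` (divide by `r(p)`) or `"zscore"`.
#' @return object of class `cosinor_phase`: list with `phi` (rad, in
#'   `(-pi, pi]`), `pc_fits` (data frame `component`, `m`, `a`, `phi`,
#'   `sd_score`) and `degenerate` (`TRUE` when the trend is constant).
#' @export
estimate_phase <- function(trend, bounds = avn_bounds(),
                           standardize = c("range", "zscore")) {
  standardize <- match.arg(standardize)
  X <- as.matrix(as.data.frame(trend)[, avn_param_names()])
  t_h <- as.data.frame(trend)$t_clock_h
  if (standardize == "range") {
    Xs <- sweep(X, 2L, bounds$range, `/`)
  } else {
    sds <- apply(X, 2L, stats::sd)
    sds[sds == 0] <- 1
    Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, sds, `/`)
  }
  if (all(apply(Xs, 2L, stats::sd) < 1e-12)) {
    return(structure(list(phi = NA_real_, pc_fits = NULL,
                          degenerate = TRUE), class = "cosinor_phase"))
  }
  pc <- stats::prcomp(Xs, center = TRUE, scale. = FALSE)
  scores <- pc$x
  fits <- lapply(seq_len(ncol(scores)), function(cc) {
    f <- fit_cosinor(t_h, scores[, cc])
    data.frame(component = cc, m = f["m"], a = f["a"], phi = f["phi"],
               sd_score = stats::sd(scores[, cc]))
  })
  fits <- do.call(rbind, fits)
  rownames(fits) <- NULL
  best <- which.max(fits$a)
  phi <- fits$phi[best]
  # a principal component's sign is arbitrary, so phi carries a pi
  # ambiguity; anchor it so the aggregate (range-weighted) cosine amplitude
  # of the raw parameter trends is positive, making phases comparable
  # across recordings
  cvar <- cos(2 * pi / 24 * t_h + phi)
  a_w <- vapply(seq_len(ncol(Xs)), function(j)
    unname(stats::lm.fit(cbind(1, cvar), Xs[, j])$coefficients[2]),
    numeric(1))
  if (sum(a_w) < 0) phi <- wrap_phase(phi + pi)
  structure(list(phi = phi, pc_fits = fits, degenerate = FALSE),
            class = "cosinor_phase")
}

#' @export
print.cosinor_phase <- function(x, ...) {
  if (x$degenerate) cat("Cosinor phase: degenerate (constant trend)\n")
  else cat(sprintf("Cosinor phase: %.3f rad (dominant PC %d, amplitude %.3f)\n",
                   x$phi, which.max(x$pc_fits$a), max(x$pc_fits$a)))
  invisible(x)
}

# fit y ~ m + a cos(2 pi t / 24 + phi) by Nelder-Mead, seeded by the
# closed-form linear fit on (cos, sin) regressors; returns positive a
fit_cosinor <- function(t_h, y) {
  w <- 2 * pi / 24
  co <- cos(w * t_h); si <- sin(w * t_h)
  lf <- unname(stats::lm.fit(cbind(1, co, si), y)$coefficients)
  a0 <- sqrt(lf[2]^2 + lf[3]^2)
  phi0 <- atan2(-lf[3], lf[2])
  sse <- function(p) sum((y - p[1] - p[2] * cos(w * t_h + p[3]))^2)
  if (stats::sd(y) < 1e-12 || !is.finite(a0) || a0 < 1e-12) {
    est <- c(lf[1], 0, 0)
  } else {
    est <- stats::optim(c(lf[1], a0, phi0), sse,
                        method = "Nelder-Mead")$par
  }
  m <- unname(est[1]); a <- unname(est[2]); phi <- unname(est[3])
  if (a < 0) { a <- -a; phi <- phi + pi }
  phi <- wrap_phase(phi)
  c(m = m, a = a, phi = phi)
}

wrap_phase <- function(phi) {
  phi <- (phi + pi) %% (2 * pi) - pi
  ifelse(phi == -pi, pi, phi)
}

#' Population-level cosinor linear mixed-effects model
#'
#' Fits, separately for each of the 12 model parameters, the mixed-effects
#' cosinor `y = m + a * cos(2*pi*t/24 + phi)` with recording-specific phase
#' `phi` held fixed (estimated beforehand by [estimate_phase()]), so the
#' model is linear in the cosine regressor.  Mean and amplitude decompose
#' into fixed and random effects:
#' `m = alpha + alpha_m + eta_pat + eta_pat_m` and
#' `a = beta + beta_m + xi_pat + xi_pat_m`, where `alpha`, `beta` are
#' baseline population values, `alpha_m`, `beta_m` the average drug-induced
#' deviations (zero at baseline by construction), and the `eta`/`xi` terms
#' zero-mean Gaussian per-patient and per-recording deviations (the
#' recording-level deviations are likewise zero at baseline).  Estimation is
#' maximum likelihood via `lme4::lmer` with a full covariance structure
#' within each random term; 95% confidence intervals are Wald intervals.
#'
#' @param trends data frame with columns `patient`, `treatment`, `t_h` and
#'   the 12 parameter columns ([cohort_trends()] builds it from a list of
#'   per-recording trends).
#' @param phases data frame `patient`, `treatment`, `phi` with one row per
#'   recording.
#' @param baseline treatment label acting as reference (default
#'   `"Baseline"`).
#' @param random_effects set `FALSE` to drop all random effects, reducing
#'   the fit to ordinary least squares (diagnostic mode).
#' @param parameters which parameter columns to fit (default all 12).
#' @return object of class `mixed_cosinor`: list with `fixed` (data frame:
#'   `parameter`, `effect` in `alpha`/`alpha_m`/`beta`/`beta_m`,
#'   `treatment`, `estimate`, `se`, `ci_lower`, `ci_upper`), `ranef_sd`
#'   (data frame of random-effect standard deviations), `models` (the
#'   fitted objects) and `drug_effects` (`FALSE` when only one treatment was
#'   supplied, in which case drug terms are inestimable and omitted).
#' @export
fit_mixed_cosinor <- function(trends, phases, baseline = "Baseline",
                              random_effects = TRUE,
                              parameters = avn_param_names()) {
  d <- merge(as.data.frame(trends), as.data.frame(phases),
             by = c("patient", "treatment"))
  if (!nrow(d)) stop("no rows after merging trends with phases",
                     call. = FALSE)
  if (length(unique(d$patient)) < 2 && random_effects)
    stop("need at least 2 patients for a mixed model", call. = FALSE)
  treatments <- unique(d$treatment)
  drug_effects <- length(treatments) > 1
  if (drug_effects && !(baseline %in% treatments))
    stop("baseline treatment not present", call. = FALSE)
  d$treatment <- stats::relevel(factor(d$treatment),
                                ref = if (drug_effects) baseline
                                      else as.character(treatments[1]))
  d$cvar <- cos(2 * pi / 24 * d$t_h + d$phi)
  d$dnb <- as.numeric(d$treatment != baseline)
  d$dnb_c <- d$dnb * d$cvar
  d$rec <- interaction(d$patient, d$treatment, drop = TRUE)

  fixed_rows <- list()
  ranef_rows <- list()
  models <- list()
  for (p in parameters) {
    d$y <- d[[p]]
    if (!random_effects) {
      fm <- if (drug_effects) stats::lm(y ~ treatment * cvar, data = d)
            else stats::lm(y ~ cvar, data = d)
      co <- summary(fm)$coefficients
      est <- co[, 1]; se <- co[, 2]
    } else {
      form <- if (drug_effects)
        y ~ treatment * cvar + (1 + cvar | patient) + (0 + dnb + dnb_c | rec)
      else
        y ~ cvar + (1 + cvar | patient)
      fm <- suppressMessages(suppressWarnings(
        lme4::lmer(form, data = d, REML = FALSE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nRE = "ignore"))))
      co <- summary(fm)$coefficients
      est <- co[, 1]; se <- co[, 2]
      vc <- as.data.frame(lme4::VarCorr(fm))
      ranef_rows[[p]] <- data.frame(parameter = p, group = vc$grp,
                                    term1 = vc$var1,
                                    term2 = ifelse(is.na(vc$var2), "",
                                                   vc$var2),
                                    sd_or_cor = vc$sdcor)
    }
    models[[p]] <- fm
    z <- stats::qnorm(0.975)
    nm <- names(est)
    effect <- ifelse(nm == "(Intercept)", "alpha",
              ifelse(nm == "cvar", "beta",
              ifelse(grepl("^treatment.*:cvar$", nm), "beta_m", "alpha_m")))
    trt <- ifelse(effect %in% c("alpha", "beta"), baseline,
                  sub(":cvar$", "", sub("^treatment", "", nm)))
    fixed_rows[[p]] <- data.frame(
      parameter = p, effect = effect, treatment = trt, estimate = est,
      se = se, ci_lower = est - z * se, ci_upper = est + z * se,
      row.names = NULL)
  }
  structure(list(fixed = do.call(rbind, c(fixed_rows,
                                          make.row.names = FALSE)),
                 ranef_sd = if (length(ranef_rows))
                   do.call(rbind, c(ranef_rows, make.row.names = FALSE))
                 else NULL,
                 models = models, drug_effects = drug_effects,
                 baseline = baseline),
            class = "mixed_cosinor")
}

#' @export
print.mixed_cosinor <- function(x, ...) {
  cat("Mixed-effects cosinor fit over",
      length(unique(x$fixed$parameter)), "parameters\n")
  if (!x$drug_effects)
    cat("  (single treatment: drug effects inestimable)\n")
  print(utils::head(x$fixed, 12))
  invisible(x)
}

#' Stack per-recording parameter trends into one cohort table
#'
#' @param trend_list named list of `avn_trend` data frames.
#' @param patients,treatments vectors aligned with `trend_list` giving the
#'   patient id and treatment label of each recording.
#' @return data frame with `patient`, `treatment`, `t_h` and the 12
#'   parameter columns, ready for [fit_mixed_cosinor()].
#' @export
cohort_trends <- function(trend_list, patients, treatments) {
  stopifnot(length(trend_list) == length(patients),
            length(patients) == length(treatments))
  do.call(rbind, lapply(seq_along(trend_list), function(k) {
    tr <- as.data.frame(trend_list[[k]])
    data.frame(patient = patients[k], treatment = treatments[k],
               t_h = tr$t_clock_h, tr[, avn_param_names()],
               row.names = NULL)
  }))
}

#' Range-weighted RMSE between a trend and its fitted cosine
#'
#' Goodness of fit of the cosinor description of one recording: for each
#' parameter the RMSE between the estimated trend and
#' `m + a * cos(2*pi*t/24 + phi)` is divided by the parameter range `r(p)`,
#' and the 12 weighted RMSEs are averaged.
#'
#' @param trend an `avn_trend` data frame.
#' @param cosine data frame with columns `parameter`, `m`, `a`, `phi` (one
#'   row per parameter; `phi` typically shared).
#' @param bounds see [avn_bounds()].
#' @return scalar weighted RMSE (dimensionless).
#' @export
weighted_rmse <- function(trend, cosine, bounds = avn_bounds()) {
  tr <- as.data.frame(trend)
  r <- bounds$range
  vals <- vapply(avn_param_names(), function(p) {
    row <- cosine[cosine$parameter == p, , drop = FALSE]
    if (nrow(row) != 1)
      stop("cosine table must have one row per parameter", call. = FALSE)
    fit <- row$m + row$a * cos(2 * pi / 24 * tr$t_clock_h + row$phi)
    sqrt(mean((tr[[p]] - fit)^2)) / r[p]
  }, numeric(1))
  mean(vals)
}

#' Paired drug-vs-baseline comparison of recording averages
#'
#' For each metric and each drug, recording averages are compared against
#' baseline with a paired two-sided Wilcoxon signed rank test over patients
#' having both recordings; p-values are Benjamini-Hochberg adjusted across
#' all tests in the table and judged at the given false discovery rate.
#'
#' @param averages data frame with columns `patient`, `treatment` and one
#'   column per metric (recording averages).
#' @param metrics metric column names (default: everything except
#'   `patient`, `treatment`).
#' @param baseline reference treatment label.
#' @param fdr false discovery rate (default 0.05).
#' @param min_pairs minimum complete pairs below which a comparison is
#'   flagged underpowered (default 6).
#' @return data frame: `metric`, `treatment`, `n_pairs`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`, `underpowered`.
#' @export
compare_recording_averages <- function(averages, metrics = NULL,
                                       baseline = "Baseline", fdr = 0.05,
                                       min_pairs = 6) {
  averages <- as.data.frame(averages)
  if (is.null(metrics))
    metrics <- setdiff(names(averages), c("patient", "treatment"))
  drugs <- setdiff(unique(averages$treatment), baseline)
  base <- averages[averages$treatment == baseline, , drop = FALSE]
  rows <- list()
  for (drug in drugs) {
    trt <- averages[averages$treatment == drug, , drop = FALSE]
    common <- intersect(base$patient, trt$patient)
    for (metric in metrics) {
      x <- base[[metric]][match(common, base$patient)]
      y <- trt[[metric]][match(common, trt$patient)]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      n <- length(x)
      res <- tryCatch(
        suppressWarnings(stats::wilcox.test(y, x, paired = TRUE)),
        error = function(e) NULL)
      stat <- if (is.null(res)) NA_real_ else unname(res$statistic)
      pv <- if (is.null(res) || all(y == x)) 1 else res$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, treatment = drug, n_pairs = n,
        statistic = stat, p_value = pv,
        underpowered = n < min_pairs)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- !out$underpowered & out$p_adjusted < fdr
  out[, c("metric", "treatment", "n_pairs", "statistic", "p_value",
          "p_adjusted", "significant", "underpowered")]
}
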