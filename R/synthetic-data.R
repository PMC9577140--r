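#' Specification of a synthetic AF cohort with known ground truth
#'
#' Describes a cohort of patients in permanent atrial fibrillation, each
#' recorded for `duration_h` hours at baseline and under rate-control
#' drugs, with 24-hour cosinor structure planted in every model parameter:
#' for patient `pat` under treatment `m`, parameter `p` follows
#' `theta_p(t) = m_pat_m(p) + a_pat_m(p) * cos(2*pi*t/24 + phi)` with
#' `m_pat_m = alpha + alpha_m + eta_pat + eta_pat_m` and
#' `a_pat_m = beta + beta_m + xi_pat + xi_pat_m`, clipped to the search
#' bounds.  Defaults plant the treatment effect pattern seen clinically:
#' refractory-period parameters shift upward under all four drugs (mean
#' effects taken from published recording-average differences), and the
#' beta-blockers additionally damp the circadian amplitude of the
#' conduction-delay parameters.  The atrial rate trend is a 24-hour cosine
#' around a treatment-specific mean.
#'
#' @param n_patients number of patients (default 20; desk-scale stand-in for
#'   a 60-patient cohort).
#' @param treatments treatment labels; the first is baseline.
#' @param duration_h recording duration in hours (default 24).
#' @param alpha baseline population means (12-vector; default
#'   [avn_theta_baseline()]).
#' @param alpha_m matrix (treatments-minus-baseline x 12) of planted mean
#'   drug effects.
#' @param beta baseline population cosinor amplitudes (12-vector; default
#'   5% of each range).
#' @param beta_m matrix of planted amplitude drug effects (default:
#'   -40% of `beta` on the conduction-delay parameters for the two
#'   beta-blockers, 0 elsewhere).
#' @param phi planted circadian phase in rad (default 1.03, an acrophase
#'   near 04:00).
#' @param eta_sd,eta_m_sd per-patient and per-recording random-effect SDs on
#'   the mean (fractions of `r(p)`; defaults 0.04 and 0.02).
#' @param xi_sd,xi_m_sd the same for the amplitude (defaults 0.015, 0.01).
#' @param lambda_mean named vector of mean atrial rates (Hz) per treatment.
#' @param lambda_amp amplitude of the 24-h atrial-rate cosine (Hz).
#' @param rr_min_coupling coupling-node refractory period used when
#'   generating (ms).
#' @param gap_spec list with `n` and `duration_min`: that many gaps of that
#'   length are cut at random positions per recording (default 3 x 10 min);
#'   use `list(n = 0)` for gap-free recordings.
#' @param grid_min width of the piecewise-stationary simulation grid in
#'   minutes (default 1).
#' @param start_clock_h clock time at recording start (default 0).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 20,
                        treatments = c("Baseline", "Verapamil", "Diltiazem",
                                       "Metoprolol", "Carvedilol"),
                        duration_h = 24,
                        alpha = avn_theta_baseline(),
                        alpha_m = default_alpha_m(treatments),
                        beta = 0.05 * avn_bounds()$range,
                        beta_m = default_beta_m(treatments, beta),
                        phi = 1.03,
                        eta_sd = 0.04, eta_m_sd = 0.02,
                        xi_sd = 0.015, xi_m_sd = 0.01,
                        lambda_mean = default_lambda_mean(treatments),
                        lambda_amp = 0.2,
                        rr_min_coupling = 250,
                        gap_spec = list(n = 3, duration_min = 10),
                        grid_min = 1,
                        start_clock_h = 0) {
  spec <- as.list(environment())
  b <- avn_bounds()
  if (any(as.numeric(alpha) < b$lower) || any(as.numeric(alpha) > b$upper))
    stop("planted baseline means violate the parameter bounds",
         call. = FALSE)
  structure(spec, class = "cohort_spec")
}

# planted drug effects on the cosinor mean: recording-average differences
# from baseline reported for the four rate-control drugs
default_alpha_m <- function(treatments) {
  tab <- rbind(
    Verapamil  = c(53, 75, -10, 39, 43,  3, 0.1, 2.8, 3, 0.6, -2.5, -1),
    Diltiazem  = c(83, 85, -12, 46, 70, -9, 0.1, 3.2, 4, 1.5, -6.7, -2),
    Metoprolol = c(54, 92, -13, 19, 81, -4, 0.6, 2.9, 8, 0.7, -3.7,  1),
    Carvedilol = c(41, 80,  -8, 28, 43, -4, 0.0, 2.5, 1, 0.0, -4.8, -5))
  colnames(tab) <- avn_param_names()
  drugs <- setdiff(treatments, treatments[1])
  out <- matrix(0, length(drugs), 12,
                dimnames = list(drugs, avn_param_names()))
  known <- intersect(drugs, rownames(tab))
  out[known, ] <- tab[known, ]
  out
}

# planted drug effects on the cosinor amplitude: beta-blockers damp the
# circadian swing of the conduction-delay parameters
default_beta_m <- function(treatments, beta) {
  drugs <- setdiff(treatments, treatments[1])
  out <- matrix(0, length(drugs), 12,
                dimnames = list(drugs, avn_param_names()))
  delay <- c("D_min_FP", "delta_D_FP", "tau_D_FP",
             "D_min_SP", "delta_D_SP", "tau_D_SP")
  bb <- intersect(drugs, c("Metoprolol", "Carvedilol"))
  for (d in bb) out[d, delay] <- -0.4 * beta[delay]
  out
}

default_lambda_mean <- function(treatments) {
  ref <- c(Baseline = 4.96, Verapamil = 4.56, Diltiazem = 4.71,
           Metoprolol = 4.86, Carvedilol = 4.81)
  out <- ref[treatments]
  out[is.na(out)] <- 4.96
  names(out) <- treatments
  out
}

#' Generate one recording from time-varying parameters
#'
#' Piecewise-stationary simulation on a minute grid: within each grid cell
#' the parameters and the atrial rate are frozen at their cell-start values
#' and the AV-node network is simulated for the cell duration; activation
#' times are concatenated.  Gaps are cut afterwards.
#'
#' @param theta_fun function of clock time (h) returning a 12-vector.
#' @param lambda_fun function of clock time (h) returning the atrial rate
#'   (Hz).
#' @param duration_h recording length in hours.
#' @param rr_min_coupling coupling-node refractory period (ms).
#' @param seed integer seed.
#' @param grid_min grid width in minutes.
#' @param gap_spec see [cohort_spec()].
#' @param id,treatment,start_clock_h recording metadata.
#' @param afr_noise_sd per-minute measurement noise on the emitted AFR
#'   trend (Hz).
#' @return list with `rr` (an [rr_recording()]), `afr` (an [afr_trend()])
#'   and `truth` (per-minute data frame of the planted parameters and rate).
#' @export
generate_recording <- function(theta_fun, lambda_fun, duration_h = 24,
                               rr_min_coupling = 250, seed = 1,
                               grid_min = 1,
                               gap_spec = list(n = 0),
                               id = "synthetic", treatment = "Baseline",
                               start_clock_h = 0, afr_noise_sd = 0.05) {
  with_preserved_seed(seed, function() {
    n_cells <- ceiling(duration_h * 60 / grid_min)
    beats <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    bounds <- avn_bounds()
    for (cell in seq_len(n_cells)) {
      t0_s <- (cell - 1) * grid_min * 60
      t_h <- start_clock_h + t0_s / 3600
      theta <- pmin(pmax(as.numeric(theta_fun(t_h)), bounds$lower),
                    bounds$upper)
      lam <- lambda_fun(t_h)
      sim <- cpp_simulate_poisson(theta, lam, rr_min_coupling, 10L,
                                  new_seed(), -1L, grid_min * 60000)
      # activations in flight at the cell boundary would overlap the next
      # cell's start; truncate to the cell
      sim <- sim[sim <= grid_min * 60000]
      beats[[cell]] <- t0_s + sim / 1000
      truth[[cell]] <- c(minute = (cell - 1) * grid_min, lambda_hz = lam,
                         stats::setNames(theta, avn_param_names()))
    }
    beat_s <- unlist(beats)
    beat_s <- beat_s[beat_s <= duration_h * 3600]
    # carry the coupling-node refractory constraint across cell boundaries:
    # a beat closer than rr_min to its predecessor could not have conducted
    if (length(beat_s) > 1) {
      keep <- rep(TRUE, length(beat_s))
      last <- beat_s[1]
      for (k in 2:length(beat_s)) {
        if (beat_s[k] - last < rr_min_coupling / 1000) keep[k] <- FALSE
        else last <- beat_s[k]
      }
      beat_s <- beat_s[keep]
    }
    truth <- as.data.frame(do.call(rbind, truth))

    rec <- rr_recording(beat_s, id = id, treatment = treatment,
                        start_clock_h = start_clock_h)
    if (!is.null(gap_spec$n) && gap_spec$n > 0) {
      iv <- rec$intervals
      for (g in seq_len(gap_spec$n)) {
        gs <- stats::runif(1, 0, duration_h * 3600 -
                                gap_spec$duration_min * 60)
        ge <- gs + gap_spec$duration_min * 60
        iv <- iv[iv$t_end_s <= gs | iv$t_start_s >= ge, , drop = FALSE]
      }
      rec <- replace_intervals(rec, iv)
    }

    minutes <- 0:(ceiling(duration_h * 60) - 1)
    lam_min <- vapply(minutes, function(m)
      lambda_fun(start_clock_h + m / 60), numeric(1))
    afr <- afr_trend(minutes,
                     pmax(lam_min + stats::rnorm(length(minutes), 0,
                                                 afr_noise_sd), 0.5))
    list(rr = rec, afr = afr, truth = truth)
  })
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws patient- and recording-level random effects, builds the planted
#' cosinor parameter trajectories for every patient x treatment, and
#' simulates each recording with [generate_recording()].  Everything needed
#' to score downstream recovery is returned in `truth`.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed.
#' @param verbose print one line per recording.
#' @return list of class `synthetic_cohort`: `recordings` (list of
#'   `generate_recording()` outputs with `patient`/`treatment` fields) and
#'   `truth` (list with `cosinor` data frame of planted per-recording
#'   `m`/`a`/`phi` per parameter, plus the spec).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1,
                            verbose = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_preserved_seed(seed, function() {
    b <- avn_bounds()
    r <- b$range
    treatments <- spec$treatments
    baseline <- treatments[1]
    recordings <- list()
    cos_rows <- list()
    for (pat in seq_len(spec$n_patients)) {
      eta_pat <- stats::rnorm(12, 0, spec$eta_sd * r)
      xi_pat <- stats::rnorm(12, 0, spec$xi_sd * r)
      for (m in treatments) {
        if (m == baseline) {
          eta_pm <- xi_pm <- rep(0, 12)
          am <- bm <- rep(0, 12)
        } else {
          eta_pm <- stats::rnorm(12, 0, spec$eta_m_sd * r)
          xi_pm <- stats::rnorm(12, 0, spec$xi_m_sd * r)
          am <- spec$alpha_m[m, ]
          bm <- spec$beta_m[m, ]
        }
        m_pm <- as.numeric(spec$alpha) + am + eta_pat + eta_pm
        a_pm <- as.numeric(spec$beta) + bm + xi_pat + xi_pm
        phi <- spec$phi
        lam_mean <- spec$lambda_mean[[m]]
        theta_fun <- local({
          m_pm <- m_pm; a_pm <- a_pm; phi <- phi
          function(t_h) m_pm + a_pm * cos(2 * pi / 24 * t_h + phi)
        })
        lambda_fun <- local({
          lam_mean <- lam_mean; amp <- spec$lambda_amp; phi <- phi
          function(t_h) lam_mean + amp * cos(2 * pi / 24 * t_h + phi)
        })
        rec <- generate_recording(
          theta_fun, lambda_fun, spec$duration_h,
          spec$rr_min_coupling, seed = new_seed(),
          grid_min = spec$grid_min, gap_spec = spec$gap_spec,
          id = sprintf("pat%02d_%s", pat, m), treatment = m,
          start_clock_h = spec$start_clock_h)
        rec$patient <- pat
        rec$treatment <- m
        recordings[[length(recordings) + 1L]] <- rec
        cos_rows[[length(cos_rows) + 1L]] <- data.frame(
          patient = pat, treatment = m, parameter = avn_param_names(),
          m = m_pm, a = a_pm, phi = phi, lambda_mean = lam_mean,
          row.names = NULL)
        if (verbose)
          message(sprintf("generated pat %d / %s", pat, m))
      }
    }
    structure(list(recordings = recordings,
                   truth = list(cosinor = do.call(rbind, cos_rows),
                                spec = spec)),
              class = "synthetic_cohort")
  })
}

#' Single recording with an abrupt regime switch
#'
#' A short recording whose parameters jump at the midpoint from typical
#' baseline values to a maximally refractory, rate-independent regime
#' (`R_min` at the top of its range with no diastolic modulation), which at
#' a high atrial rate produces a tight RR distribution several hundred
#' milliseconds away from the baseline one.  The Poincare difference
#' exceeds the upper effort threshold around the switch and stays far below
#' the lower one elsewhere, exercising the adaptive effort schedule of the
#' genetic algorithm.
#'
#' @param seed integer seed.
#' @param duration_h total duration (default 3 h; switch at the midpoint).
#' @param lambda_hz atrial rate (default 8).
#' @param rr_min_coupling coupling-node refractory period (default 350 ms).
#' @return list with `rr`, `afr`, `theta_pre`, `theta_post`,
#'   `switch_time_h`, `rr_min_coupling`.
#' @export
generate_switch_scenario <- function(seed = 1, duration_h = 3,
                                     lambda_hz = 8,
                                     rr_min_coupling = 350) {
  theta_pre <- avn_theta_baseline()
  theta_post <- avn_theta(c(650, 0, 60, 650, 0, 60,
                            5, 10, 141, 5, 10, 185))
  switch_h <- duration_h / 2
  out <- generate_recording(
    theta_fun = function(t_h)
      if (t_h < switch_h) as.numeric(theta_pre) else as.numeric(theta_post),
    lambda_fun = function(t_h) lambda_hz,
    duration_h = duration_h, rr_min_coupling = rr_min_coupling,
    seed = seed, gap_spec = list(n = 0), id = "switch",
    treatment = "Baseline")
  out$theta_pre <- theta_pre
  out$theta_post <- theta_post
  out$switch_time_h <- switch_h
  out$rr_min_coupling <- rr_min_coupling
  out
}
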