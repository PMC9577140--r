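#' Node refractory period as a function of the diastolic interval
#'
#' After conducting an impulse, a node enters a refractory state whose
#' duration depends on how recovered the node was when the impulse arrived:
#' `R(t_dia) = R_min + delta_R * (1 - exp(-t_dia / tau_R))`.  The refractory
#' period grows monotonically from `R_min` (at `t_dia = 0`) towards the
#' asymptote `R_min + delta_R`.
#'
#' @param t_dia diastolic interval(s) in ms, must be finite and `>= 0`
#'   (negative diastolic intervals mean the impulse is blocked and never
#'   reach this function).
#' @param p named vector or list with `R_min`, `delta_R`, `tau_R` (ms), e.g.
#'   from [avn_pathway()].
#' @return refractory period(s) in ms.
#' @export
refractory_period <- function(t_dia, p) {
  if (any(!is.finite(t_dia)))
    stop("t_dia must be finite", call. = FALSE)
  if (any(t_dia < 0))
    stop("t_dia must be non-negative", call. = FALSE)
  p <- as.list(p)
  p$R_min + p$delta_R * (1 - exp(-t_dia / p$tau_R))
}

#' Node conduction delay as a function of the diastolic interval
#'
#' `D(t_dia) = D_min + delta_D * exp(-t_dia / tau_D)`: a node forwards an
#' impulse after a delay that decays from `D_min + delta_D` (at `t_dia = 0`)
#' towards `D_min` for long diastolic intervals.
#'
#' @inheritParams refractory_period
#' @param p named vector or list with `D_min`, `delta_D`, `tau_D` (ms).
#' @return conduction delay(s) in ms.
#' @export
conduction_delay <- function(t_dia, p) {
  if (any(!is.finite(t_dia)))
    stop("t_dia must be finite", call. = FALSE)
  if (any(t_dia < 0))
    stop("t_dia must be non-negative", call. = FALSE)
  p <- as.list(p)
  p$D_min + p$delta_D * exp(-t_dia / p$tau_D)
}

#' Diastolic interval preceding an impulse
#'
#' The recovery time a node has had since the end of its last refractory
#' period: `t_arrival - t_last - R_last`.  A negative value signals that the
#' node is still refractory and the impulse is blocked.
#'
#' @param t_arrival arrival time of the impulse (ms).
#' @param t_last time of the node's most recent activation (ms).
#' @param r_last refractory period issued at that activation (ms).
#' @return diastolic interval in ms (may be negative, meaning block).
#' @export
diastolic_interval <- function(t_arrival, t_last, r_last) {
  if (any(t_arrival < t_last))
    stop("impulse arrives before the node's last activation", call. = FALSE)
  t_arrival - t_last - r_last
}

#' Generate a Poisson atrial impulse train
#'
#' During atrial fibrillation the impulses bombarding the AV node are
#' modelled as a homogeneous Poisson process with mean arrival rate
#' `lambda_hz`.
#'
#' @param lambda_hz mean arrival rate in impulses per second (> 0).
#' @param n number of impulses to generate, or `NULL`.
#' @param duration_s alternatively, generate all impulses in
#'   `[0, duration_s]`; exactly one of `n`, `duration_s` must be given.
#' @param seed optional integer seed; when given the global RNG state is
#'   left untouched.
#' @return object of class `impulse_train`: list with `times_ms` (strictly
#'   increasing arrival times in ms) and `lambda_hz`.
#' @export
generate_atrial_impulses <- function(lambda_hz, n = NULL, duration_s = NULL,
                                     seed = NULL) {
  if (!is.finite(lambda_hz) || lambda_hz <= 0)
    stop("lambda_hz must be positive", call. = FALSE)
  if (is.null(n) == is.null(duration_s))
    stop("supply exactly one of n, duration_s", call. = FALSE)
  gen <- function() {
    mean_ms <- 1000 / lambda_hz
    if (!is.null(n)) {
      cumsum(stats::rexp(n, rate = 1 / mean_ms))
    } else {
      horizon <- duration_s * 1000
      # draw in chunks until the horizon is passed
      times <- numeric(0)
      last <- 0
      chunk <- max(16L, ceiling(lambda_hz * duration_s * 1.2))
      while (last <= horizon) {
        gaps <- stats::rexp(chunk, rate = 1 / mean_ms)
        times <- c(times, last + cumsum(gaps))
        last <- times[length(times)]
      }
      times[times <= horizon]
    }
  }
  times <- if (is.null(seed)) gen() else with_preserved_seed(seed, gen)
  structure(list(times_ms = times, lambda_hz = lambda_hz),
            class = "impulse_train")
}

# run fn under set.seed(seed) and restore the caller's RNG state
with_preserved_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Network topology description
#'
#' @param n_per_pathway number of nodes per pathway chain (10 in the full
#'   model).
#' @return data frame with one row per node: `node`, `pathway`
#'   (`"FP"`, `"SP"` or `"coupling"`) and `position` in the chain.
#' @export
avn_topology <- function(n_per_pathway = 10L) {
  data.frame(
    node = seq_len(2L * n_per_pathway + 1L),
    pathway = c(rep("FP", n_per_pathway), rep("SP", n_per_pathway),
                "coupling"),
    position = c(seq_len(n_per_pathway), seq_len(n_per_pathway), 1L),
    stringsAsFactors = FALSE
  )
}

as_ventricular_series <- function(times) {
  structure(list(activation_times_ms = times,
                 rr_ms = diff(times)),
            class = "ventricular_series")
}

#' @export
print.ventricular_series <- function(x, ...) {
  cat("Ventricular activation series:", length(x$activation_times_ms),
      "activations,", length(x$rr_ms), "RR intervals\n")
  if (length(x$rr_ms))
    cat(sprintf("  mean RR %.0f ms (range %.0f-%.0f)\n", mean(x$rr_ms),
                min(x$rr_ms), max(x$rr_ms)))
  invisible(x)
}

#' Simulate the AV-node network for a given atrial impulse train
#'
#' Event-driven propagation of every atrial impulse through the fast and the
#' slow pathway chain into the coupling node.  Each impulse enters the first
#' node of both chains simultaneously; a refractory node blocks it, a
#' recovered node forwards it after the diastolic-interval-dependent
#' conduction delay.  The coupling node adds a fixed 60 ms delay and has a
#' fixed refractory period `rr_min` (in data fitting: the mean of the ten
#' shortest observed RR intervals), which lower-bounds every simulated RR
#' interval.  The simulation is a pure function of its arguments.
#'
#' @param theta an [avn_theta()] parameter vector.
#' @param train an `impulse_train` from [generate_atrial_impulses()], or a
#'   numeric vector of strictly increasing arrival times in ms.
#' @param rr_min coupling-node refractory period in ms (> 0).
#' @param n_per_pathway nodes per chain; 10 for the full 21-node network.
#' @return object of class `ventricular_series`: list with strictly
#'   increasing `activation_times_ms` and `rr_ms = diff(activation_times_ms)`.
#' @examples
#' train <- generate_atrial_impulses(5, duration_s = 30, seed = 1)
#' sim <- simulate_avnode(avn_theta_baseline(), train, rr_min = 350)
#' head(sim$rr_ms)
#' @export
simulate_avnode <- function(theta, train, rr_min, n_per_pathway = 10L) {
  stopifnot(inherits(theta, "avn_theta"))
  if (!is.finite(rr_min) || rr_min <= 0)
    stop("rr_min must be positive", call. = FALSE)
  times <- if (inherits(train, "impulse_train")) train$times_ms
           else as.numeric(train)
  if (length(times) == 0)
    return(as_ventricular_series(numeric(0)))
  if (any(diff(times) <= 0))
    stop("impulse arrival times must be strictly increasing", call. = FALSE)
  out <- cpp_simulate_train(as.numeric(theta), times, rr_min,
                            as.integer(n_per_pathway))
  as_ventricular_series(out)
}

#' Simulate a fixed number of RR intervals under Poisson atrial input
#'
#' Convenience wrapper used throughout model fitting: atrial impulses are
#' generated lazily from a Poisson process with rate `lambda_hz` and the
#' simulation runs until exactly `n_rr` RR intervals have been emitted.
#' Reproducible given `seed` (the global RNG is not touched).
#'
#' @inheritParams simulate_avnode
#' @param lambda_hz atrial arrival rate, impulses per second.
#' @param n_rr number of RR intervals to emit.
#' @param seed integer seed for the impulse train.
#' @return a `ventricular_series`; it may hold fewer than `n_rr` intervals
#'   for pathological parameter sets where conduction (almost) never
#'   succeeds.
#' @export
simulate_rr <- function(theta, lambda_hz, n_rr, rr_min, seed,
                        n_per_pathway = 10L) {
  stopifnot(inherits(theta, "avn_theta"))
  if (!is.finite(lambda_hz) || lambda_hz <= 0)
    stop("lambda_hz must be positive", call. = FALSE)
  if (!is.finite(rr_min) || rr_min <= 0)
    stop("rr_min must be positive", call. = FALSE)
  out <- cpp_simulate_poisson(as.numeric(theta), lambda_hz, rr_min,
                              as.integer(n_per_pathway), as.numeric(seed),
                              as.integer(n_rr), -1)
  as_ventricular_series(out)
}

#' Simulate ventricular activity over a fixed time horizon
#'
#' As [simulate_rr()] but stops generating atrial impulses after
#' `duration_s` seconds (impulses already in flight are drained).  Used by
#' the synthetic-data generator for piecewise-stationary minute grids.
#'
#' @inheritParams simulate_rr
#' @param duration_s horizon in seconds.
#' @return a `ventricular_series`.
#' @export
simulate_duration <- function(theta, lambda_hz, duration_s, rr_min, seed,
                              n_per_pathway = 10L) {
  stopifnot(inherits(theta, "avn_theta"))
  out <- cpp_simulate_poisson(as.numeric(theta), lambda_hz, rr_min,
                              as.integer(n_per_pathway), as.numeric(seed),
                              -1L, duration_s * 1000)
  as_ventricular_series(out)
}
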