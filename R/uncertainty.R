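#' Latin hypercube sample matrices around a parameter estimate
#'
#' Two `n x 12` matrices of quasi-Monte-Carlo (Latin hypercube) samples
#' drawn inside the hyper-rectangle `theta_hat +/- half_width * r`,
#' intersected with the global search bounds — a local neighbourhood
#' covering `2 * half_width` (15% by default) of each parameter's range.
#'
#' @param theta_hat estimated parameter vector (12 values, within bounds).
#' @param bounds see [avn_bounds()].
#' @param n rows per matrix (default 30).
#' @param half_width half-width of the sampling box as a fraction of each
#'   range (default 0.075).
#' @return list with matrices `A` and `B`, and the box `lower`/`upper`.
#' @export
uncertainty_matrices <- function(theta_hat, bounds = avn_bounds(), n = 30,
                                 half_width = 0.075) {
  theta_hat <- as.numeric(theta_hat)
  lo <- pmax(theta_hat - half_width * bounds$range, bounds$lower)
  hi <- pmin(theta_hat + half_width * bounds$range, bounds$upper)
  draw <- function() {
    u <- lhs::randomLHS(n, 12L)
    m <- sweep(u, 2L, hi - lo, `*`)
    m <- sweep(m, 2L, lo, `+`)
    colnames(m) <- avn_param_names()
    m
  }
  list(A = draw(), B = draw(), lower = lo, upper = hi)
}

#' Variance contribution of each parameter to the fitness error
#'
#' For every parameter `p` a matrix `AB_p` is built by replacing column `p`
#' of `A` with column `p` of `B`; the error is evaluated by simulation for
#' each row of `A` and `AB_p`, and the expected contribution of `p`
#' (including all its interactions) to the output variance is
#' `v_hat(p) = (1 / (2n)) * sum_q (eps(A_q) - eps(AB_p_q))^2`.
#' The same fresh impulse-train seed is reused for row `q` of `A` and of
#' every `AB_p` (paired evaluation), so the differences reflect the
#' parameter step rather than Monte-Carlo noise.
#'
#' @param A,B matrices from [uncertainty_matrices()].
#' @param seg the `rr_segment` the estimate belongs to.
#' @param n_sim simulated RR intervals per evaluation.
#' @param n_per_pathway nodes per pathway chain.
#' @return named 12-vector `v_hat`; entries are `NA` when a sentinel
#'   (infinite) error was encountered for that parameter.
#' @export
variance_contribution <- function(A, B, seg, n_sim = 1500,
                                  n_per_pathway = 10L) {
  n <- nrow(A)
  seeds <- vapply(seq_len(n), function(q) new_seed(), numeric(1))
  eps_a <- vapply(seq_len(n), function(q)
    eval_theta_internal(A[q, ], seg, n_sim, seeds[q], n_per_pathway)$eps,
    numeric(1))
  eps_ab <- vapply(seq_len(12L), function(p) {
    vapply(seq_len(n), function(q) {
      row <- A[q, ]
      row[p] <- B[q, p]
      eval_theta_internal(row, seg, n_sim, seeds[q], n_per_pathway)$eps
    }, numeric(1))
  }, numeric(n))
  variance_from_errors(eps_a, eps_ab)
}

#' Variance contributions from paired error evaluations
#'
#' The estimator behind [variance_contribution()], separated out so it can
#' be applied to stored error tables:
#' `v_hat(p) = (1 / (2n)) * sum_q (eps_a[q] - eps_ab[q, p])^2`.
#'
#' @param eps_a errors of the `n` rows of `A`.
#' @param eps_ab `n x 12` matrix of errors of the column-swapped rows.
#' @return named 12-vector; `NA` where a non-finite error occurred.
#' @export
variance_from_errors <- function(eps_a, eps_ab) {
  eps_ab <- as.matrix(eps_ab)
  n <- length(eps_a)
  stopifnot(nrow(eps_ab) == n)
  v_hat <- vapply(seq_len(ncol(eps_ab)), function(p) {
    d <- eps_a - eps_ab[, p]
    if (any(!is.finite(d))) return(NA_real_)
    sum(d^2) / (2 * n)
  }, numeric(1))
  names(v_hat) <- avn_param_names()[seq_len(ncol(eps_ab))]
  v_hat
}

#' Uncertainty step size from variance contributions
#'
#' `u(p) = 0.15 * r(p) / (v_hat(p) - sigma_eps) * 0.1 * eps_bar`: the
#' parameter step that would raise the error contribution at the estimate by
#' 10%, derived from the slope between the sampled neighbourhood
#' (half-width `0.075 r`, so full distance `0.15 r`) and the error
#' fluctuation at the estimate itself.  When `v_hat(p) <= sigma_eps` the
#' variance contribution is indistinguishable from realization noise and the
#' step is unbounded (`Inf`): the slope interpretation breaks down.  `u` is
#' a relative measure (between parameters, patients, times of day), not a
#' probabilistic interval.
#'
#' @param v_hat 12-vector from [variance_contribution()].
#' @param r parameter ranges `r(p)` (see [avn_bounds()]).
#' @param eps_bar mean error over realizations at the estimate.
#' @param sigma_eps standard deviation of those realizations.
#' @param half_width sampling-box half-width used (default 0.075).
#' @param target_increase relative error increase defining the step
#'   (default 0.1).
#' @return named 12-vector `u` in ms; `Inf` marks unbounded entries, `NA`
#'   propagates flagged variance contributions.
#' @export
uncertainty_step <- function(v_hat, r, eps_bar, sigma_eps,
                             half_width = 0.075, target_increase = 0.1) {
  stopifnot(eps_bar > 0)
  u <- (2 * half_width) * r / (v_hat - sigma_eps) * target_increase * eps_bar
  u[!is.na(v_hat) & v_hat <= sigma_eps] <- Inf
  names(u) <- avn_param_names()
  u
}

#' Local (Sobol-variant) uncertainty of a parameter estimate
#'
#' Full per-estimate uncertainty procedure: (1) the error at `theta_hat` is
#' evaluated for `n_real` fresh impulse-train realizations, giving `eps_bar`
#' and `sigma_eps`; (2) Latin hypercube matrices `A`, `B` are sampled in
#' `theta_hat +/- 0.075 r`; (3) paired evaluations of `A` and the
#' column-swapped `AB_p` give the variance contribution `v_hat(p)`; (4) the
#' step sizes `u(p)` follow from [uncertainty_step()].
#'
#' @param theta_hat estimated 12-vector.
#' @param seg the `rr_segment` it was estimated on.
#' @param bounds see [avn_bounds()].
#' @param n_sim simulated RR intervals per error evaluation (default 1500).
#' @param n_real realizations at `theta_hat` (default 30).
#' @param n_sample rows of `A` and `B` (default 30).
#' @param half_width sampling-box half-width (default 0.075).
#' @param seed seed for the whole procedure (session RNG preserved).
#' @param n_per_pathway nodes per pathway chain.
#' @return object of class `avn_uncertainty`: list with `u`, `v_hat`,
#'   `eps_bar`, `sigma_eps`, `A`, `B`.
#' @export
estimate_uncertainty <- function(theta_hat, seg, bounds = avn_bounds(),
                                 n_sim = 1500, n_real = 30, n_sample = 30,
                                 half_width = 0.075, seed = 1,
                                 n_per_pathway = 10L) {
  theta_hat <- as.numeric(theta_hat)
  with_preserved_seed(seed, function() {
    eps <- vapply(seq_len(n_real), function(q)
      eval_theta_internal(theta_hat, seg, n_sim, new_seed(),
                          n_per_pathway)$eps, numeric(1))
    eps <- eps[is.finite(eps)]
    if (length(eps) < 2)
      stop("estimate produced (almost) no conducted beats; cannot assess",
           call. = FALSE)
    mats <- uncertainty_matrices(theta_hat, bounds, n_sample, half_width)
    v_hat <- variance_contribution(mats$A, mats$B, seg, n_sim,
                                   n_per_pathway)
    u <- uncertainty_step(v_hat, bounds$range, mean(eps), stats::sd(eps),
                          half_width)
    structure(list(u = u, v_hat = v_hat, eps_bar = mean(eps),
                   sigma_eps = stats::sd(eps), A = mats$A, B = mats$B),
              class = "avn_uncertainty")
  })
}

#' @export
print.avn_uncertainty <- function(x, ...) {
  cat(sprintf("Parameter uncertainty: eps_bar=%.2f sigma_eps=%.2f\n",
              x$eps_bar, x$sigma_eps))
  print(round(rbind(v_hat = x$v_hat, u = x$u), 3))
  invisible(x)
}
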