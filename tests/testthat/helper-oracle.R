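# Independent brute-force trace of the dual-pathway network: processes a
# global agenda of (time, pathway, node) events, re-sorting at every step and
# applying the refractory/delay recursions directly.  Deliberately naive and
# structurally different from the package's event-driven engine.
oracle_simulate <- function(theta, arrivals, rr_min, n_chain = 2) {
  theta <- as.numeric(theta)
  pw <- list(
    list(r_min = theta[1], d_r = theta[2], t_r = theta[3],
         d_min = theta[7], d_d = theta[8], t_d = theta[9]),
    list(r_min = theta[4], d_r = theta[5], t_r = theta[6],
         d_min = theta[10], d_d = theta[11], t_d = theta[12]))
  state <- list()
  coup <- list(active = FALSE, t_last = NA_real_)
  out <- numeric(0)
  agenda <- data.frame(t = rep(arrivals, each = 2),
                       pathway = rep(c(0, 1), times = length(arrivals)),
                       node = 1)
  while (nrow(agenda)) {
    ord <- order(agenda$t, agenda$pathway, agenda$node)
    agenda <- agenda[ord, , drop = FALSE]
    ev <- agenda[1, ]
    agenda <- agenda[-1, , drop = FALSE]
    if (ev$pathway == 2) {
      if (!coup$active || (ev$t - coup$t_last - rr_min) >= 0) {
        coup$active <- TRUE
        coup$t_last <- ev$t
        out <- c(out, ev$t + 60)
      }
      next
    }
    p <- pw[[ev$pathway + 1]]
    key <- paste(ev$pathway, ev$node)
    st <- state[[key]]
    if (is.null(st)) {
      conducts <- TRUE
      delay <- p$d_min
      r_new <- p$r_min + p$d_r
    } else {
      tdia <- ev$t - st$t_last - st$r_last
      conducts <- tdia >= 0
      if (conducts) {
        delay <- p$d_min + p$d_d * exp(-tdia / p$t_d)
        r_new <- p$r_min + p$d_r * (1 - exp(-tdia / p$t_r))
      }
    }
    if (conducts) {
      state[[key]] <- list(t_last = ev$t, r_last = r_new)
      agenda <- rbind(agenda, data.frame(
        t = ev$t + delay,
        pathway = if (ev$node < n_chain) ev$pathway else 2,
        node = if (ev$node < n_chain) ev$node + 1 else 1))
    }
  }
  sort(out)
}

# wrap an RR vector as an rr_segment without going through a full recording
make_segment <- function(rr, lambda_hz = 5, rr_min = NULL, i = 1,
                         t_clock_h = 0) {
  if (is.null(rr_min)) rr_min <- mean(sort(rr)[seq_len(min(10, length(rr)))])
  structure(list(i = i, rr = rr, lambda_hz = lambda_hz, rr_min = rr_min,
                 t_start_s = 0, t_clock_h = t_clock_h,
                 hist = poincare_histogram(rr)),
            class = "rr_segment")
}

# cosinor-structured 12-parameter trend table
make_trend <- function(t_h, means, amps, phi, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- sapply(seq_len(12), function(j)
    means[j] + amps[j] * cos(2 * pi / 24 * t_h + phi) +
      stats::rnorm(length(t_h), 0, noise_sd[min(j, length(noise_sd))]))
  colnames(X) <- avn_param_names()
  out <- data.frame(i = seq_along(t_h), t_clock_h = t_h, X, epsilon = 1)
  class(out) <- c("avn_trend", "data.frame")
  out
}
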