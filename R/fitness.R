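#' Binned Poincare-plot histogram of an RR series
#'
#' The Poincare plot is the scatter of successive RR-interval pairs
#' `(RR_k, RR_{k+1})`.  For fitness evaluation the plot is binned on a fixed
#' two-dimensional grid: 50 ms wide square bins with centers at
#' 250, 300, ..., 1800 ms on both axes (32 x 32 = 1024 bins).  A bin with
#' center `c` covers `[c - 25, c + 25)`; pairs with either member outside
#' `[225, 1825)` ms are dropped, not clamped.
#'
#' @param rr numeric vector of RR intervals (ms), length >= 2.
#' @param bin_width bin width in ms.
#' @param centers bin centers (identical for both axes).
#' @return object of class `poincare_hist`: list with integer matrix
#'   `counts` (rows = RR_k bin, cols = RR_{k+1} bin), `centers`,
#'   `bin_width`, `n_pairs` (pairs inside the grid) and `n_intervals`
#'   (length of `rr`, used for count scaling in [poincare_error()]).
#' @export
poincare_histogram <- function(rr, bin_width = 50,
                               centers = seq(250, 1800, by = 50)) {
  rr <- as.numeric(rr)
  if (length(rr) < 2)
    stop("need at least 2 RR intervals to form a Poincare pair",
         call. = FALSE)
  nb <- length(centers)
  lo <- centers[1] - bin_width / 2
  hi <- centers[nb] + bin_width / 2
  x <- rr[-length(rr)]
  y <- rr[-1]
  ix <- floor((x - lo) / bin_width) + 1
  iy <- floor((y - lo) / bin_width) + 1
  keep <- x >= lo & x < hi & y >= lo & y < hi
  counts <- matrix(0L, nb, nb)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = seq_len(nb)),
                 factor(iy[keep], levels = seq_len(nb)))
    counts <- matrix(as.integer(tab), nb, nb)
  }
  structure(list(counts = counts, centers = centers, bin_width = bin_width,
                 n_pairs = sum(keep), n_intervals = length(rr)),
            class = "poincare_hist")
}

#' @export
print.poincare_hist <- function(x, ...) {
  cat(sprintf("Poincare histogram: %d x %d bins (%g ms), %d/%d pairs in range\n",
              nrow(x$counts), ncol(x$counts), x$bin_width, x$n_pairs,
              x$n_intervals - 1L))
  invisible(x)
}

same_binning <- function(a, b) {
  a$bin_width == b$bin_width && length(a$centers) == length(b$centers) &&
    all(a$centers == b$centers)
}

#' Poincare-histogram error (inverse fitness) between data and model output
#'
#' A chi-square-type discrepancy between the binned Poincare plot of an
#' observed RR segment (`N` intervals, counts `x_k`) and of a simulated RR
#' series (`N_sim` intervals, counts `x~_k`):
#' `eps = (1/K) * sum_k (x_k - s * x~_k)^2 / (s * x~_k)` with
#' `s = N / N_sim`.  The sum runs over the 2-D bins; bins empty in both
#' histograms contribute zero, and bins where the simulation is empty but
#' the data are not use a pseudo-count `x~_k = 0.5` (before scaling) so the
#' error surface stays finite.  The normalization constant `K` is the
#' per-axis bin count (32): on this scale a simulation drawn from the same
#' process as the data typically scores around 5-10, the scale on which the
#' Poincare-difference effort thresholds and the uncertainty estimate
#' operate.
#'
#' @param hist_data,hist_sim `poincare_hist` objects on identical grids.
#' @return scalar `eps >= 0`; zero iff data counts equal scaled simulated
#'   counts in every bin.
#' @export
poincare_error <- function(hist_data, hist_sim) {
  stopifnot(inherits(hist_data, "poincare_hist"),
            inherits(hist_sim, "poincare_hist"))
  if (!same_binning(hist_data, hist_sim))
    stop("histograms use different bin grids", call. = FALSE)
  s <- hist_data$n_intervals / hist_sim$n_intervals
  x <- as.numeric(hist_data$counts)
  xs <- as.numeric(hist_sim$counts)
  use <- x > 0 | xs > 0
  if (!any(use)) return(0)
  K <- length(hist_data$centers)
  xs_use <- xs[use]
  xs_use[xs_use == 0] <- 0.5
  sum((x[use] - s * xs_use)^2 / (s * xs_use)) / K
}

#' Poincare-plot difference: a non-stationarity heuristic
#'
#' Quantifies how fast the RR-series characteristics change around interval
#' `i` by comparing the binned Poincare plots of two overlapping windows of
#' `n_dp` intervals starting at `i` and at `i + offset`:
#' `dP(i) = (1/K) * sum_k (x_k(i) - x_k(i + offset))^2`,
#' normalized by the same per-axis bin count `K = 32` as
#' [poincare_error()].  Large values indicate a rapid regime change and
#' trigger more optimization effort in [estimate_recording()]: stationary
#' stretches score on the order of a hundred, abrupt regime switches
#' thousands.
#'
#' @param rr full RR-interval stream (ms).
#' @param i 1-based start index of the first window.
#' @param n_dp window length in intervals (default 2000).
#' @param offset shift of the second window (default 1000).
#' @inheritParams poincare_histogram
#' @return scalar `dP(i) >= 0`.  When the stream is too short for both
#'   windows the start index is pulled back so that the last computable
#'   value is reused (boundary rule).
#' @export
poincare_difference <- function(rr, i, n_dp = 2000, offset = 1000,
                                bin_width = 50,
                                centers = seq(250, 1800, by = 50)) {
  n <- length(rr)
  need <- n_dp + offset
  if (n < need)
    stop("RR stream shorter than one dP evaluation window", call. = FALSE)
  i <- max(1L, min(as.integer(i), n - need + 1L))
  h1 <- poincare_histogram(rr[i:(i + n_dp - 1L)], bin_width, centers)
  h2 <- poincare_histogram(rr[(i + offset):(i + offset + n_dp - 1L)],
                           bin_width, centers)
  a <- as.numeric(h1$counts)
  b <- as.numeric(h2$counts)
  sum((a - b)^2) / length(h1$centers)
}
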