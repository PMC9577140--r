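#' RR-interval recording
#'
#' Container for one 24-hour (or shorter) RR-interval recording.  Internally
#' the recording is a table of intervals with explicit start and end beat
#' times (seconds from recording start), so that gaps left by exclusions are
#' self-describing: interval `k` follows a gap whenever
#' `t_start_s[k] > t_end_s[k-1]`.
#'
#' @param beat_time_s strictly increasing beat times in seconds from
#'   recording start.
#' @param quality logical per-beat flags marking beats adjacent to
#'   morphologically deviant QRS complexes (default all `FALSE`).
#' @param id recording identifier.
#' @param treatment treatment label (e.g. `"Baseline"`, `"Verapamil"`).
#' @param start_clock_h clock time of day (hours, 0-24) at recording start;
#'   anchors the circadian covariate.
#' @return object of class `rr_recording`: list with `intervals`
#'   (data frame `t_start_s`, `t_end_s`, `rr_ms`), `quality` (per-beat, kept
#'   until [apply_quality_exclusions()] consumes it), `beat_time_s`, `id`,
#'   `treatment`, `start_clock_h`.
#' @export
rr_recording <- function(beat_time_s, quality = NULL, id = "rec",
                         treatment = "Baseline", start_clock_h = 0) {
  beat_time_s <- as.numeric(beat_time_s)
  if (length(beat_time_s) >= 2 && any(diff(beat_time_s) <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  if (is.null(quality)) quality <- rep(FALSE, length(beat_time_s))
  if (length(quality) != length(beat_time_s))
    stop("quality flags must align with beats", call. = FALSE)
  n <- length(beat_time_s)
  intervals <- data.frame(
    t_start_s = if (n >= 2) beat_time_s[-n] else numeric(0),
    t_end_s = if (n >= 2) beat_time_s[-1] else numeric(0)
  )
  intervals$rr_ms <- (intervals$t_end_s - intervals$t_start_s) * 1000
  structure(list(intervals = intervals, quality = as.logical(quality),
                 beat_time_s = beat_time_s, id = id, treatment = treatment,
                 start_clock_h = start_clock_h),
            class = "rr_recording")
}

replace_intervals <- function(rec, intervals) {
  rec$intervals <- intervals
  rec$beat_time_s <- sort(unique(c(intervals$t_start_s, intervals$t_end_s)))
  rec$quality <- rep(FALSE, length(rec$beat_time_s))
  rec
}

#' @export
print.rr_recording <- function(x, ...) {
  n <- nrow(x$intervals)
  cat(sprintf("RR recording '%s' (%s): %d intervals", x$id, x$treatment, n))
  if (n)
    cat(sprintf(", %.1f h retained over a %.1f h span",
                sum(x$intervals$rr_ms) / 3.6e6,
                (max(x$intervals$t_end_s) - min(x$intervals$t_start_s)) / 3600))
  cat("\n")
  invisible(x)
}

#' Drop RR intervals adjacent to morphologically deviant beats
#'
#' Both the interval ending at and the interval starting at a flagged beat
#' are removed, since either of them involves a beat whose detection is
#' unreliable.
#'
#' @param rec an [rr_recording()].
#' @return the recording with flagged-adjacent intervals removed and the
#'   quality flags cleared.
#' @export
apply_quality_exclusions <- function(rec) {
  stopifnot(inherits(rec, "rr_recording"))
  if (!any(rec$quality)) return(rec)
  bad_times <- rec$beat_time_s[rec$quality]
  iv <- rec$intervals
  keep <- !(iv$t_start_s %in% bad_times | iv$t_end_s %in% bad_times)
  replace_intervals(rec, iv[keep, , drop = FALSE])
}

#' Remove minutes with implausibly low heart rate
#'
#' Missed beat detections leave stretches with unrealistically low apparent
#' heart rate.  The recording is partitioned into non-overlapping one-minute
#' windows aligned to the recording start; every window containing fewer
#' than `min_bpm` beats is removed entirely, leaving a gap.
#'
#' @param rec an [rr_recording()].
#' @param min_bpm minimum number of beats per minute (default 20).
#' @return the recording with low-rate minutes excised.
#' @export
remove_low_rate_minutes <- function(rec, min_bpm = 20) {
  stopifnot(inherits(rec, "rr_recording"))
  iv <- rec$intervals
  if (!nrow(iv)) return(rec)
  beats <- sort(unique(c(iv$t_start_s, iv$t_end_s)))
  minute <- floor(beats / 60)
  counts <- table(minute)
  bad <- as.numeric(names(counts))[counts < min_bpm]
  if (!length(bad)) return(rec)
  bad_beats <- beats[minute %in% bad]
  keep <- !(iv$t_start_s %in% bad_beats | iv$t_end_s %in% bad_beats)
  replace_intervals(rec, iv[keep, , drop = FALSE])
}

#' Is a recording long enough for circadian analysis?
#'
#' A recording qualifies when at least `min_retained_h` hours of RR data
#' remain after exclusions and the span between the first and the last
#' retained beat is at least `min_span_h` hours (so that the 24-hour cosine
#' is identifiable).
#'
#' @param rec an [rr_recording()] with exclusions already applied.
#' @param min_retained_h minimum summed retained duration (default 12 h).
#' @param min_span_h minimum first-to-last span (default 20 h).
#' @return `TRUE` or `FALSE`.
#' @export
recording_eligible <- function(rec, min_retained_h = 12, min_span_h = 20) {
  stopifnot(inherits(rec, "rr_recording"))
  iv <- rec$intervals
  if (!nrow(iv)) return(FALSE)
  retained_h <- sum(iv$rr_ms) / 3.6e6
  span_h <- (max(iv$t_end_s) - min(iv$t_start_s)) / 3600
  retained_h >= min_retained_h && span_h >= min_span_h
}

#' Atrial fibrillatory rate trend
#'
#' One AFR sample per minute, as produced by upstream f-wave frequency
#' tracking.
#'
#' @param minute integer minute index from recording start (0-based).
#' @param afr_hz atrial fibrillatory rate in Hz.
#' @return object of class `afr_trend`: data frame with columns `minute`,
#'   `afr_hz` and (after [condition_lambda()]) `lambda_hz`.
#' @export
afr_trend <- function(minute, afr_hz) {
  stopifnot(length(minute) == length(afr_hz))
  structure(data.frame(minute = as.numeric(minute),
                       afr_hz = as.numeric(afr_hz)),
            class = c("afr_trend", "data.frame"))
}

#' Condition an AFR trend into an atrial arrival-rate trend
#'
#' Three steps: (1) the AFR is mapped to the atrial arrival rate `lambda`,
#' by default through `lambda = AFR / (1 - AFR * t_dep)` with atrial
#' depolarization time `t_dep` (seconds); the default `t_dep = 0` makes the
#' map the identity.  (2) Outlying minutes are removed automatically: a
#' minute is an outlier when its `lambda` deviates from a centered
#' `outlier_window`-minute rolling median by more than `outlier_mad` median
#' absolute deviations of the residual series.  (3) The surviving trend is
#' low-pass filtered with a sliding triangular window of total width
#' `filter_width` samples (one sample = one minute), normalized to unit sum
#' and renormalized over available samples at edges and gaps.
#'
#' @param afr an [afr_trend()].
#' @param t_dep atrial depolarization time in seconds (default 0).
#' @param outlier_window rolling-median window, minutes (odd; default 31).
#' @param outlier_mad MAD multiple beyond which a minute is dropped
#'   (default 5).
#' @param filter_width triangular window width in samples (default 70).
#' @return the trend with a `lambda_hz` column added; minutes removed as
#'   outliers carry `NA`.
#' @export
condition_lambda <- function(afr, t_dep = 0, outlier_window = 31,
                             outlier_mad = 5, filter_width = 70) {
  stopifnot(inherits(afr, "afr_trend"))
  if (nrow(afr) < filter_width)
    stop("AFR trend shorter than the filter width", call. = FALSE)
  lambda <- afr$afr_hz / (1 - afr$afr_hz * t_dep)
  if (any(!is.finite(lambda) | lambda <= 0))
    stop("lambda correction produced non-positive rates; check t_dep",
         call. = FALSE)
  # outlier removal against a rolling median
  k <- min(outlier_window, nrow(afr))
  if (k %% 2 == 0) k <- k - 1
  if (k >= 3 && nrow(afr) >= k) {
    med <- stats::runmed(lambda, k, endrule = "median")
    resid <- lambda - med
    s <- stats::mad(resid)
    if (s > 0) lambda[abs(resid) > outlier_mad * s] <- NA
  }
  afr$lambda_hz <- triangular_filter(lambda, filter_width)
  afr
}

# NA-aware triangular smoothing; weights renormalized over available samples
triangular_filter <- function(x, width) {
  half <- floor(width / 2)
  w <- 1 - abs(seq(-half, half)) / (half + 1)
  n <- length(x)
  num <- numeric(n)
  den <- numeric(n)
  ok <- !is.na(x)
  xz <- ifelse(ok, x, 0)
  for (j in seq(-half, half)) {
    src <- seq_len(n) + j
    valid <- src >= 1 & src <= n
    wj <- w[j + half + 1]
    num[valid] <- num[valid] + wj * xz[src[valid]]
    den[valid] <- den[valid] + wj * ok[src[valid]]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

#' Cut a recording into overlapping estimation segments
#'
#' The retained RR intervals are cut into windows of exactly `n` consecutive
#' intervals.  Window start indices advance by a nominal `stride_s` seconds:
#' the number of windows is `round(retained_duration / stride_s)` (800 for a
#' gap-free 24-hour recording at the 108 s default) and the starts are
#' spread evenly over the interval index range, so the stride adapts locally
#' at gaps and at the recording end and every retained interval is covered
#' by at least one window.  Each segment carries the mean conditioned
#' arrival rate over its time span, the mean of its ten shortest RR
#' intervals (the coupling-node refractory period used when fitting), and
#' the clock time of its first interval.
#'
#' @param rec an eligible [rr_recording()].
#' @param afr a conditioned [afr_trend()] (from [condition_lambda()]).
#' @param n segment length in RR intervals (default 1000).
#' @param stride_s nominal window stride in seconds (default 108).
#' @return list of `rr_segment` objects; empty list when fewer than `n`
#'   intervals are retained.  Each segment is a list with `i` (start index
#'   into the retained interval sequence), `rr` (the `n` intervals, ms),
#'   `lambda_hz`, `rr_min`, `t_start_s`, `t_clock_h` and `hist` (the
#'   precomputed data histogram for fitness evaluation).
#' @export
segment_recording <- function(rec, afr, n = 1000, stride_s = 108) {
  stopifnot(inherits(rec, "rr_recording"), inherits(afr, "afr_trend"))
  if (is.null(afr$lambda_hz))
    stop("AFR trend must be conditioned first (condition_lambda)",
         call. = FALSE)
  iv <- rec$intervals
  n_int <- nrow(iv)
  if (n_int < n) return(list())
  total_s <- sum(iv$rr_ms) / 1000
  n_seg <- max(1L, round(total_s / stride_s))
  starts <- unique(round(seq(1L, n_int - n + 1L, length.out = n_seg)))
  lapply(starts, function(i) {
    idx <- i:(i + n - 1L)
    rr <- iv$rr_ms[idx]
    t0 <- iv$t_start_s[idx[1]]
    t1 <- iv$t_end_s[idx[n]]
    mins <- floor(t0 / 60):floor(t1 / 60)
    lam <- afr$lambda_hz[afr$minute %in% mins]
    lam <- mean(lam, na.rm = TRUE)
    if (!is.finite(lam))
      lam <- mean(afr$lambda_hz, na.rm = TRUE)
    k10 <- min(10L, n)
    structure(list(
      i = i,
      rr = rr,
      lambda_hz = lam,
      rr_min = mean(sort(rr)[seq_len(k10)]),
      t_start_s = t0,
      t_clock_h = (rec$start_clock_h + t0 / 3600) %% 24,
      hist = poincare_histogram(rr)
    ), class = "rr_segment")
  })
}

#' @export
print.rr_segment <- function(x, ...) {
  cat(sprintf(
    "RR segment at i=%d (%.2f h): %d intervals, lambda %.2f Hz, RR_min %.0f ms\n",
    x$i, x$t_clock_h, length(x$rr), x$lambda_hz, x$rr_min))
  invisible(x)
}

#' Read and write the package's CSV dialects
#'
#' RR recordings are 3-column CSVs (`beat_time_s`, `rr_ms`, `quality_flag`):
#' one row per beat, where `rr_ms` is the interval ending at that beat and
#' is `NA` for the first beat and for any beat that follows a gap.  AFR
#' trends are 2-column CSVs (`minute`, `afr_hz`).
#'
#' @param path file path.
#' @param ... passed to the [rr_recording()] constructor (`id`, `treatment`,
#'   `start_clock_h`).
#' @return `read_rr_csv` an [rr_recording()]; `read_afr_csv` an
#'   [afr_trend()].
#' @export
read_rr_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  rec <- rr_recording(d$beat_time_s, quality = as.logical(d$quality_flag),
                      ...)
  # rows with rr_ms == NA (beyond the first) mark gaps: drop those intervals
  if (nrow(rec$intervals) && any(is.na(d$rr_ms[-1]))) {
    keep <- !is.na(d$rr_ms[-1])
    rec <- replace_intervals(rec, rec$intervals[keep, , drop = FALSE])
    q <- d$quality_flag[match(rec$beat_time_s, d$beat_time_s)]
    rec$quality <- !is.na(q) & q > 0
  }
  rec
}

#' @rdname read_rr_csv
#' @param rec an [rr_recording()] (written beat-wise from its retained
#'   intervals).
#' @export
write_rr_csv <- function(rec, path) {
  beats <- rec$beat_time_s
  iv <- rec$intervals
  rr <- rep(NA_real_, length(beats))
  m <- match(round(iv$t_end_s, 9), round(beats, 9))
  rr[m] <- round(iv$rr_ms, 3)
  utils::write.csv(
    data.frame(beat_time_s = beats, rr_ms = rr,
               quality_flag = as.integer(rec$quality)),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_rr_csv
#' @export
read_afr_csv <- function(path) {
  d <- utils::read.csv(path)
  afr_trend(d$minute, d$afr_hz)
}

#' @rdname read_rr_csv
#' @param afr an [afr_trend()].
#' @export
write_afr_csv <- function(afr, path) {
  utils::write.csv(data.frame(minute = afr$minute, afr_hz = afr$afr_hz),
                   path, row.names = FALSE)
  invisible(path)
}
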