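test_that("recordings track intervals, gaps and metadata", {
  beats <- c(0, 0.6, 1.2, 1.8)
  rec <- rr_recording(beats, id = "r1", treatment = "Verapamil",
                      start_clock_h = 8)
  expect_equal(nrow(rec$intervals), 3)
  expect_equal(rec$intervals$rr_ms, rep(600, 3))
  expect_error(rr_recording(c(0, 1, 1)), "increasing")
  expect_error(rr_recording(beats, quality = c(TRUE, FALSE)), "align")
})

test_that("quality exclusions remove both intervals touching a flagged beat", {
  beats <- seq(0, 6, by = 0.6)   # 11 beats, 10 intervals
  q <- rep(FALSE, 11)

  rec <- rr_recording(beats, quality = q)
  expect_equal(nrow(apply_quality_exclusions(rec)$intervals), 10)

  q5 <- replace(q, 5, TRUE)
  rec5 <- apply_quality_exclusions(rr_recording(beats, quality = q5))
  expect_equal(nrow(rec5$intervals), 8)
  # the removed ones are intervals 4 and 5 (ending and starting at beat 5)
  expect_false(any(abs(rec5$intervals$t_start_s - beats[4]) < 1e-9 &
                   abs(rec5$intervals$t_end_s - beats[5]) < 1e-9))

  rec_all <- apply_quality_exclusions(
    rr_recording(beats, quality = rep(TRUE, 11)))
  expect_equal(nrow(rec_all$intervals), 0)
})

test_that("minutes with fewer than 20 beats are excised", {
  # 70 bpm for 1 min, then 10 beats in the next minute, then 70 bpm again
  beats <- c(seq(0, 59.9, length.out = 70),
             seq(61, 118, length.out = 10),
             seq(120.2, 179.9, length.out = 70))
  rec <- remove_low_rate_minutes(rr_recording(beats))
  mins <- floor(rec$intervals$t_end_s / 60)
  expect_false(any(mins == 1 & floor(rec$intervals$t_start_s / 60) == 1))
  # a uniform 60 bpm recording (complete minutes) is untouched
  rec2 <- rr_recording(seq(0, 299, by = 1))
  expect_equal(remove_low_rate_minutes(rec2)$intervals, rec2$intervals)
})

test_that("eligibility needs 12 h retained and a 20 h span", {
  mk <- function(retained_h, span_h) {
    # retained_h hours of 1-s beats at the start, plus a tail block ending
    # at span_h
    head_beats <- seq(0, retained_h * 3600 - 1)
    structure(list(intervals = data.frame(
      t_start_s = c(head_beats[-length(head_beats)], span_h * 3600 - 1),
      t_end_s = c(head_beats[-1], span_h * 3600),
      rr_ms = 1000)), class = "rr_recording")
  }
  expect_false(recording_eligible(mk(11, 24)))
  expect_false(recording_eligible(mk(18, 19)))
  expect_true(recording_eligible(mk(21, 22)))
})

test_that("lambda conditioning preserves constants, removes outliers, smooths", {
  n <- 200
  afr <- afr_trend(0:(n - 1), rep(5, n))
  out <- condition_lambda(afr)
  expect_equal(out$lambda_hz, rep(5, n), tolerance = 1e-12)

  # a single 10x spike is removed before filtering
  set.seed(31)
  spiked <- afr_trend(0:(n - 1), replace(rep(5, n) + rnorm(n, 0, 0.01),
                                         100, 50))
  sm <- condition_lambda(spiked)
  expect_true(all(abs(sm$lambda_hz - 5) < 0.5, na.rm = TRUE))

  expect_error(condition_lambda(afr_trend(0:10, rep(5, 11))), "width")

  # non-identity AFR->lambda map
  out2 <- condition_lambda(afr, t_dep = 0.02)
  expect_equal(out2$lambda_hz, rep(5 / (1 - 5 * 0.02), n), tolerance = 1e-12)
})

test_that("triangular filter has a normalized triangular impulse response", {
  n <- 201
  x <- replace(rep(0, n), 101, 1)
  y <- avnodetrend:::triangular_filter(x, 70)
  expect_equal(sum(y), 1, tolerance = 1e-12)
  expect_equal(which.max(y), 101)
  # symmetric, linearly decaying flanks
  expect_equal(y[101 - 10], y[101 + 10])
  expect_equal(y[101 + 35] > 0, TRUE)
  expect_equal(y[101 + 36], 0)
})

test_that("segmentation yields 800 windows for a gap-free 24-hour recording", {
  rr_s <- 0.72  # 83 bpm
  beats <- seq(0, 24 * 3600, by = rr_s)
  rec <- rr_recording(beats)
  afr <- afr_trend(0:(24 * 60 - 1), rep(5, 24 * 60))
  segs <- segment_recording(rec, condition_lambda(afr))
  expect_equal(length(segs), 800)
  expect_true(all(vapply(segs, function(s) length(s$rr), numeric(1)) == 1000))
  # coverage: every retained interval belongs to at least one window
  covered <- rep(FALSE, nrow(rec$intervals))
  for (s in segs) covered[s$i:(s$i + 999)] <- TRUE
  expect_true(all(covered))
  # determinism / idempotence
  segs2 <- segment_recording(rec, condition_lambda(afr))
  expect_identical(lapply(segs, `[[`, "i"), lapply(segs2, `[[`, "i"))
  # lambda within the conditioned trend's range; rr_min for constant rr
  expect_equal(vapply(segs, `[[`, numeric(1), "lambda_hz"), rep(5, 800),
               tolerance = 1e-9)
  expect_equal(segs[[1]]$rr_min, 720)
})

test_that("short recordings give one or zero segments", {
  beats <- seq(0, by = 0.6, length.out = 1001)  # exactly 1000 intervals
  rec <- rr_recording(beats)
  afr <- condition_lambda(afr_trend(0:99, rep(5, 100)))
  segs <- segment_recording(rec, afr)
  expect_equal(length(segs), 1)
  expect_equal(segs[[1]]$rr_min, 600)
  rec2 <- rr_recording(beats[1:900])
  expect_equal(length(segment_recording(rec2, afr)), 0)
})

test_that("RR and AFR CSV round-trips preserve gaps and flags", {
  beats <- c(seq(0, 10, by = 0.5), seq(40, 50, by = 0.5))
  q <- rep(FALSE, length(beats)); q[3] <- TRUE
  rec <- rr_recording(beats, quality = q)
  # cut the cross-gap interval the way exclusions would
  iv <- rec$intervals[rec$intervals$rr_ms < 2000, ]
  rec_gap <- avnodetrend:::replace_intervals(rec, iv)
  rec_gap$quality[3] <- TRUE

  path <- withr::local_tempfile(fileext = ".csv")
  write_rr_csv(rec_gap, path)
  back <- read_rr_csv(path)
  expect_equal(back$intervals$rr_ms, rec_gap$intervals$rr_ms)
  expect_equal(back$intervals$t_start_s, rec_gap$intervals$t_start_s)
  expect_equal(which(back$quality), 3)

  afr <- afr_trend(0:9, 5 + 0.1 * sin(0:9))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_afr_csv(afr, path2)
  expect_equal(read_afr_csv(path2)$afr_hz, afr$afr_hz)
})
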