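H <- 3600 * 1000  # one clock hour in ms

test_that("nocturnal windowing clips to [00:00, 05:00) and severs the boundary IBI", {
  s <- constant_series(1000, t0 = -10 * 60000, t1 = 5 * H + 10 * 60000)
  w <- window_night(s)
  expect_true(all(w$t_ms >= 0 & w$t_ms < 5 * H))
  expect_true(is.na(w$ibi_ms[1]))        # predecessor beat lay before midnight
  expect_false(anyNA(w$ibi_ms[-1]))
  expect_equal(n_beats(w), 5 * H / 1000)
})

test_that("a recording entirely before midnight yields an empty flagged series", {
  s <- constant_series(800, t0 = -2 * H, t1 = -1)
  w <- window_night(s)
  expect_equal(n_beats(w), 0)
  expect_true("no nocturnal data" %in% w$flags)
})

test_that("a five-hour window tiles into sixty 5-minute segments", {
  s <- constant_series(800)
  segs <- segment_series(window_night(s))
  expect_length(segs, 60)
  expect_true(all(vapply(segs, function(g) g$end_ms - g$start_ms, 0) == 3e5))
  ## every beat lands in exactly one segment
  expect_equal(sum(vapply(segs, function(g) length(g$t_ms), 0L)), n_beats(s))
})

test_that("a beat exactly on a segment boundary joins the later segment", {
  s <- beat_series("p", "r", c(299000, 300000, 301000), c(NA, 1000, 1000))
  segs <- segment_series(s)
  expect_equal(segs[[1]]$t_ms, 299000)
  expect_equal(segs[[2]]$t_ms[1:2], c(300000, 301000))
  ## the straddling IBI is severed in the later segment
  expect_true(is.na(segs[[2]]$ibi_ms[1]))
})

test_that("an empty series still yields sixty segments of zero completeness", {
  s <- beat_series("p", "r", numeric(0), numeric(0))
  segs <- segment_series(s)
  expect_length(segs, 60)
  expect_true(all(vapply(segs, `[[`, 0, "completeness") == 0))
})

test_that("completeness is IBI coverage over segment length, inclusive at 70%", {
  seg <- manual_segment(rep(700, 300))            # 300 x 700 = 210,000 ms
  expect_equal(seg$completeness, 0.70)
  kept <- screen_completeness(list(seg), 0.70)[[1]]
  expect_equal(kept$status, "kept")               # threshold is inclusive
  just_below <- manual_segment(rep(700, 299))
  expect_equal(screen_completeness(list(just_below))[[1]]$status,
               "low_completeness")
})

test_that("full coverage caps completeness at one beat below 1", {
  seg <- manual_segment(rep(800, 375))            # 375 x 800 = 300,000 ms
  expect_gte(seg$completeness, 1 - 800 / 300000)
  expect_lte(seg$completeness, 1)
})

test_that("any step in an overlapping minute invalidates a segment", {
  s <- constant_series(800)
  segs <- segment_series(window_night(s))
  steps <- zero_steps()
  steps$steps[steps$minute_start_ms == 7 * 60000] <- 1L  # minute 7: segment 2
  out <- exclude_movement(segs, steps)
  st <- vapply(out, `[[`, "", "status")
  expect_equal(which(st == "movement"), 2L)
  expect_equal(sum(st == "kept"), 59L)
})

test_that("zero steps everywhere removes nothing and steps outside the window have no effect", {
  s <- constant_series(800)
  segs <- segment_series(window_night(s))
  out <- exclude_movement(segs, zero_steps())
  expect_true(all(vapply(out, `[[`, "", "status") == "kept"))
  steps <- zero_steps(t0 = -2 * H, t1 = 6 * H)
  steps$steps[steps$minute_start_ms < 0] <- 50L   # movement before midnight
  out2 <- exclude_movement(segs, steps)
  expect_true(all(vapply(out2, `[[`, "", "status") == "kept"))
})

test_that("range rule removes a non-physiological IBI", {
  ibis <- rep(800, 50); ibis[25] <- 3000
  seg <- manual_segment(ibis, len_ms = 60000)
  fl <- filter_spurious(seg)
  expect_equal(fl$log$rule, "range")
  expect_equal(fl$log$ibi_ms, 3000)
  expect_true(is.na(fl$x$ibi_ms[26]))  # beat 26 carries the 3000 ms interval
})

test_that("a clean constant series passes the filter untouched", {
  seg <- manual_segment(rep(800, 100), len_ms = 90000)
  fl <- filter_spurious(seg)
  expect_equal(nrow(fl$log), 0)
  expect_identical(fl$x$ibi_ms, seg$ibi_ms)
})

test_that("a split beat is caught by the relative-deviation rule", {
  ibis <- c(rep(800, 20), 400, 400, rep(800, 20))  # one beat split in two
  seg <- manual_segment(ibis, len_ms = 60000)
  fl <- filter_spurious(seg)
  expect_equal(sort(fl$log$ibi_ms), c(400, 400))
  expect_true(all(fl$log$rule == "relative_deviation"))
})

test_that("filtering is idempotent on its own output", {
  ibis <- c(rep(800, 30), 250, 400, 3000, rep(820, 30))
  seg <- manual_segment(ibis, len_ms = 90000)
  once <- filter_spurious(seg)
  twice <- filter_spurious(once$x)
  expect_equal(nrow(twice$log), 0)
  expect_identical(twice$x$ibi_ms, once$x$ibi_ms)
})

test_that("interpolation reproduces constants and hits the sample-count contract", {
  seg <- manual_segment(rep(800, 375))
  tach <- interp_tachogram(seg, rate = 4)
  expect_length(tach$ibi_ms, 1200)                 # 300 s x 4 Hz
  expect_true(all(abs(tach$ibi_ms - 800) < 1e-6))
})

test_that("interpolation recovers a sinusoidal modulation at sample times", {
  t_beat <- cumsum(c(0, rep(500, 599)))            # 2 Hz beats, 300 s
  f <- function(t) 500 + 40 * sin(2 * pi * 0.1 * t / 1000)
  seg <- list(start_ms = 0, end_ms = 300000, t_ms = t_beat,
              ibi_ms = c(NA, f(t_beat[-1])))
  tach <- interp_tachogram(seg, rate = 4)
  inner <- tach$t_ms > 1000 & tach$t_ms < 299000   # spline edges excluded
  expect_lt(max(abs(tach$ibi_ms[inner] - f(tach$t_ms[inner]))), 1)
})

test_that("interpolation refuses fewer than two valid beats", {
  seg <- manual_segment(numeric(0))
  expect_error(interp_tachogram(seg), "uninterpolatable")
})

test_that("beat count never increases through window and filter stages", {
  sim <- simulate_ibi(ibi_config(duration = 7200, gap_fraction = 0.05,
                                 spurious_rate = 3, seed = 31))
  w <- window_night(sim$series)
  expect_lte(n_beats(w), n_beats(sim$series))
  fl <- filter_spurious(w)
  expect_equal(n_beats(fl$x), n_beats(w))          # filtering blanks IBIs only
  expect_lte(sum(!is.na(fl$x$ibi_ms)), sum(!is.na(w$ibi_ms)))
})

test_that("segment statuses account for every segment", {
  sim <- simulate_ibi(ibi_config(duration = 18000, gap_fraction = 0.15,
                                 spurious_rate = 4,
                                 movement_minutes = c(10, 120, 200),
                                 seed = 32))
  night <- process_night(sim$series, sim$steps)
  tab <- table(factor(night$segments$status,
                      levels = c("kept", "low_completeness", "movement",
                                 "artifact_burst")))
  expect_equal(sum(tab), nrow(night$segments))
  expect_equal(nrow(night$segments), 60)
  expect_gt(tab[["kept"]], 0)
  expect_gt(tab[["movement"]], 0)
})
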