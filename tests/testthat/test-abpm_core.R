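# Ingest, quality control, window means and the time-weighted 24-h mean.

test_that("parse_readings handles empty, single-subject and bad rows", {
  f <- tempfile(fileext = ".csv")
  writeLines("subject_id,timestamp,sbp,dbp", f)
  expect_identical(parse_readings(f), list())

  # one subject, 60 rows
  cfg <- cohort_config(n_subjects = 1, seed = 1, p_dropout = 0,
                       p_device_removal = 0)
  sim <- simulate_cohort_data(cfg)
  utils::write.csv(sim$readings, f, row.names = FALSE)
  recs <- parse_readings(f)
  expect_length(recs, 1)
  expect_length(recs[[1]]$times, 60)

  # 5-row fixture: one dbp >= sbp row and one bad timestamp are excluded
  writeLines(c("subject_id,timestamp,sbp,dbp",
               "A,2020-01-01T10:00:00,120,80",
               "A,2020-01-01T10:20:00,80,120",
               "A,not-a-time,121,81",
               "A,2020-01-01T10:40:00,122,82",
               "A,2020-01-01T11:00:00,118,78"), f)
  expect_warning(recs <- parse_readings(f), "line\\(s\\) 3, 4")
  expect_length(recs[[1]]$times, 3)
  expect_equal(recs[[1]]$sbp, c(120, 122, 118))
})

test_that("plausibility filtering is off by default and works when on", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,timestamp,sbp,dbp",
               "A,2020-01-01T10:00:00,300,80",   # sbp out of bounds
               "A,2020-01-01T10:20:00,95,90",    # pulse pressure < 10
               "A,2020-01-01T10:40:00,120,80"), f)
  expect_length(parse_readings(f)[[1]]$times, 3)
  expect_warning(recs <- parse_readings(f, plausibility = TRUE))
  expect_length(recs[[1]]$times, 1)
})

test_that("quality_filter applies the 10-day / 5-night minimums", {
  # boundary case: exactly 10 daytime and 5 nighttime readings pass
  day_t <- sprintf("%02d:00", 10:19)
  night_t <- c("00:40", "01:20", "03:00", "04:40", "05:20")
  rec <- make_record(c(night_t, day_t), sbp = rep(120, 15),
                     dbp = rep(80, 15))
  qc <- quality_filter(rec)
  expect_equal(qc$n_day, 10)
  expect_equal(qc$n_night, 5)
  expect_true(qc$qc_pass)

  # 9 daytime + 20 nighttime fails the daytime minimum
  rec2 <- make_record(c(sprintf("00:%02d", seq(0, 57, 3)),
                        sprintf("%02d:30", 10:18)),
                      sbp = rep(120, 29), dbp = rep(80, 29))
  qc2 <- quality_filter(rec2)
  expect_equal(qc2$n_day, 9)
  expect_equal(qc2$n_night, 20)
  expect_false(qc2$qc_pass)

  # half-open window: a reading stamped exactly 20:00 is not daytime
  rec3 <- make_record(c("19:59", "20:00"), c(120, 130), c(80, 85))
  expect_equal(quality_filter(rec3)$n_day, 1)
})

test_that("quality_filter is monotone and windows never double-count", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    mins <- sort(sample(0:1439, n))
    hm1 <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
    rec <- make_record(hm1, sbp = rep(120, n), dbp = rep(80, n))
    qc <- quality_filter(rec)
    expect_lte(qc$n_day + qc$n_night, n)
    # adding one more reading never flips pass -> fail
    extra_min <- sample(setdiff(0:1439, mins), 1)
    hm2 <- sprintf("%02d:%02d", c(mins, extra_min) %/% 60,
                   c(mins, extra_min) %% 60)
    ord <- order(c(mins, extra_min))
    rec2 <- make_record(hm2[ord], sbp = rep(120, n + 1),
                        dbp = rep(80, n + 1))
    qc2 <- quality_filter(rec2)
    if (qc$qc_pass) expect_true(qc2$qc_pass)
  }
})

test_that("window_mean averages only in-window readings", {
  rec <- make_record("12:00", 120, 80)
  m <- window_mean(rec, c("10:00", "20:00"))
  expect_equal(c(m$sbp, m$dbp), c(120, 80))

  rec2 <- make_record(c("11:00", "13:00"), c(110, 130), c(70, 90))
  m2 <- window_mean(rec2, c("10:00", "20:00"))
  expect_equal(c(m2$sbp, m2$dbp), c(120, 80))

  # empty window is flagged missing, never zero
  m3 <- window_mean(rec2, c("00:00", "06:00"))
  expect_equal(m3$n, 0L)
  expect_true(is.na(m3$sbp))

  # 15-reading fixture spanning both windows: hand-computed daytime mean
  day_sbp <- c(118, 122, 125, 119, 121, 124, 120, 123, 117, 126)
  night_sbp <- c(105, 108, 102, 107, 104)
  rec4 <- make_record(c(sprintf("%02d:15", 10:19), sprintf("0%d:30", 1:5)),
                      sbp = c(day_sbp, night_sbp),
                      dbp = rep(75, 15))
  m4 <- window_mean(rec4, c("10:00", "20:00"))
  expect_equal(m4$n, 10)
  expect_equal(m4$sbp, mean(day_sbp))
  expect_equal(window_mean(rec4, c("00:00", "06:00"))$sbp, mean(night_sbp))
})

test_that("time-weighted 24-h mean: uniform, hand-worked and oracle", {
  # equally spaced readings centred in the span carry uniform weights and
  # collapse to the arithmetic mean (at the span edge the clipped first /
  # last intervals are asymmetric by construction)
  hm <- sprintf("%02d:30", 0:23)
  set.seed(7)
  sbp <- round(rnorm(24, 120, 10))
  rec <- make_record(hm, sbp, sbp - 40, fit_hm = "00:00")
  w <- weighted_24h_mean(rec)
  expect_equal(w$sbp, mean(sbp), tolerance = 1e-12)

  # two readings: 130 covering 18 h, 110 covering 6 h -> 125
  rec2 <- make_record(c("12:00", "00:00"), c(130, 110), c(80, 70),
                      fit_hm = "00:00")
  expect_equal(weighted_24h_mean(rec2)$sbp, (18 * 130 + 6 * 110) / 24)

  # fewer than 2 readings is flagged missing
  expect_true(is.na(weighted_24h_mean(make_record("12:00", 120, 80))$sbp))

  # brute-force interval-integration oracle on random <=10-reading records
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    mins <- sort(sample(0:1435, n))
    hm_i <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
    sbp_i <- round(runif(n, 90, 180))
    rec_i <- make_record(hm_i, sbp_i, sbp_i - 40, fit_hm = "00:00")
    got <- weighted_24h_mean(rec_i)$sbp
    want <- oracle_weighted_mean(rec_i$times, rec_i$sbp, rec_i$fit_time,
                                 rec_i$fit_time + 86400)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("records longer than 24 h are truncated before weighting", {
  # 26-h record: the reading at +25 h must not contribute
  rec <- make_record(c("00:00", "12:00", "00:00", "01:00"),
                     c(120, 140, 120, 999), c(80, 90, 80, 500),
                     fit_hm = "00:00")
  w <- weighted_24h_mean(rec)
  expect_lt(w$sbp, 150)
  oracle <- oracle_weighted_mean(rec$times[1:3], rec$sbp[1:3],
                                 rec$fit_time, rec$fit_time + 86400)
  expect_equal(w$sbp, oracle, tolerance = 1e-9)
})

test_that("hourly weighting mode is the mean of hourly means", {
  # two readings in one hour, one in another: hourly mode balances hours
  rec <- make_record(c("10:00", "10:30", "15:00"), c(120, 122, 100),
                     c(80, 82, 70), fit_hm = "00:00")
  w <- weighted_24h_mean(rec, mode = "hourly")
  expect_equal(w$sbp, mean(c(mean(c(120, 122)), 100)))
})

test_that("any mean lies in the closed hull of its inputs", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    mins <- sort(sample(0:1439, n))
    sbp <- round(runif(n, 80, 200))
    rec <- make_record(sprintf("%02d:%02d", mins %/% 60, mins %% 60),
                       sbp, sbp - 30, fit_hm = "00:00")
    w <- weighted_24h_mean(rec)
    expect_gte(w$sbp, min(sbp))
    expect_lte(w$sbp, max(sbp))
    for (win in list(c("10:00", "20:00"), c("00:00", "06:00"))) {
      m <- window_mean(rec, win)
      if (m$n > 0) {
        expect_gte(m$sbp, min(sbp))
        expect_lte(m$sbp, max(sbp))
      }
    }
  }
})

test_that("office_mean follows the triplicate-average protocol", {
  m <- office_mean(c(118, 120, 122), c(76, 80, 84))
  expect_equal(c(m$mean_sbp, m$mean_dbp), c(120, 80))
  expect_true(m$complete)

  # two readings: averaged but flagged incomplete
  m2 <- office_mean(c(118, NA, 122), c(76, NA, 84))
  expect_equal(m2$mean_sbp, 120)
  expect_false(m2$complete)
  expect_true(m2$usable)

  # identical triplicate gives that value exactly
  m3 <- office_mean(rep(135, 3), rep(85, 3))
  expect_equal(m3$mean_sbp, 135)

  # an invalid reading (sbp <= dbp) is dropped like a missing one
  m4 <- office_mean(c(118, 80, 122), c(76, 90, 84))
  expect_equal(m4$n_readings, 2)

  # fewer than 2 valid readings: excluded from the primary analysis
  m5 <- office_mean(c(118, NA, NA), c(76, NA, NA))
  expect_false(m5$usable)
  expect_true(is.na(m5$mean_sbp))
})

test_that("summarize_abpm assembles the per-subject analysis row", {
  day_t <- sprintf("%02d:00", 10:19)
  night_t <- sprintf("0%d:00", 1:5)
  rec <- make_record(c(night_t, day_t),
                     sbp = c(rep(108, 5), rep(120, 10)),
                     dbp = c(rep(66, 5), rep(78, 10)))
  s <- summarize_abpm(list(rec))
  expect_true(s$qc_pass)
  expect_equal(s$day_sbp, 120)
  expect_equal(s$night_sbp, 108)
  expect_gt(s$wt24_sbp, 108)
  expect_lt(s$wt24_sbp, 120)
  expect_equal(nrow(summarize_abpm(list())), 0)
})
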