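test_that("bout-to-day assignment groups by the start day, never splitting", {
  b <- data.frame(participant_id = "p1",
                  start = posix(c("2013-05-02 23:59:30", "2013-05-02 10:00:00",
                                  "2013-05-03 08:00:00", "2013-05-03 09:00:00",
                                  "2013-05-03 22:00:00")),
                  duration = c(90, 20, 15, 40, 10), n_steps = rep(20, 5),
                  cadence = rep(85, 5), speed = rep(0.7, 5),
                  stride_length = rep(95, 5), stride_duration = rep(1.4, 5))
  m <- assignBoutsToDays(b)
  expect_equal(sort(names(m)), c("2013-05-02", "2013-05-03"))
  expect_equal(sum(vapply(m, nrow, integer(1))), 5L)
  # the 23:59:30 bout with 90 s duration stays on its start day
  expect_true(90 %in% m[["2013-05-02"]]$duration)

  set.seed(7)
  for (rep in 1:10) {
    n <- sample(1:60, 1)
    b <- data.frame(participant_id = "p1",
                    start = posix("2013-05-01 00:00:00") + runif(n, 0, 6 * 86400),
                    duration = runif(n, 3, 120), n_steps = rep(10, n),
                    cadence = rep(85, n), speed = rep(0.7, n),
                    stride_length = rep(95, n), stride_duration = rep(1.4, n))
    m <- assignBoutsToDays(b)
    byday <- table(format(b$start, "%Y-%m-%d", tz = "UTC"))
    expect_equal(vapply(m, nrow, integer(1))[names(byday)], c(byday))
  }
})

test_that("valid-day flagging uses strict >12 h and splits midnight-crossing wear", {
  w1 <- data.frame(participant_id = "p1",
                   start = posix("2013-05-02 08:00:00"), end = posix("2013-05-02 21:00:00"))
  f1 <- flagValidDays(w1)
  expect_equal(f1$wear_hours, 13)
  expect_true(f1$valid)

  # exactly 12.0 h is invalid under the strict rule
  w2 <- data.frame(participant_id = "p1",
                   start = posix("2013-05-02 08:00:00"), end = posix("2013-05-02 20:00:00"))
  expect_false(flagValidDays(w2)$valid)

  # 20:00 day 1 to 02:00 day 2: 4 h to day 1, 2 h to day 2
  w3 <- data.frame(participant_id = "p1",
                   start = posix("2013-05-01 20:00:00"), end = posix("2013-05-02 02:00:00"))
  f3 <- flagValidDays(w3)
  expect_equal(f3$wear_hours, c(4, 2))
  expect_false(any(f3$valid))

  # minute-grid oracle on random interval sets within a 3-day window
  set.seed(13)
  day0 <- as.numeric(posix("2013-05-01 00:00:00"))
  for (rep in 1:10) {
    n <- sample(1:8, 1)
    sMin <- sample(0:(3 * 1440 - 30), n, replace = TRUE)
    eMin <- pmin(sMin + sample(30:900, n, replace = TRUE), 3 * 1440)
    w <- data.frame(participant_id = "p1",
                    start = as.POSIXct(day0 + sMin * 60, origin = "1970-01-01", tz = "UTC"),
                    end = as.POSIXct(day0 + eMin * 60, origin = "1970-01-01", tz = "UTC"))
    fl <- flagValidDays(w)
    for (i in seq_len(nrow(fl))) {
      dayIdx <- as.integer(fl$date[i] - as.Date("2013-05-01"))
      lo <- dayIdx * 1440; hi <- lo + 1440
      cs <- pmax(pmin(eMin, hi), lo); cc <- pmax(pmin(sMin, hi), lo)
      keep <- cs > cc
      exp_h <- if (any(keep)) oracleUnionHours(cc[keep], cs[keep]) else 0
      expect_equal(fl$wear_hours[i], exp_h, tolerance = 1e-9)
    }
    expect_true(all(fl$wear_hours <= 24 + 1e-12))
  }
})

test_that("duration strata use strict 'greater than' bounds and partition gt10", {
  b <- randomDayBouts(0)
  b <- rbind(b, within(randomDayBouts(4), duration <- c(5, 12, 35, 70)))
  st <- stratifyBouts(b)
  expect_equal(vapply(st, nrow, integer(1)),
               c(all = 4L, gt10 = 3L, gt30 = 2L, gt60 = 1L, shorter = 1L))

  b30 <- within(randomDayBouts(1), duration <- 30)
  st30 <- stratifyBouts(b30)
  expect_equal(nrow(st30$shorter), 1L)
  expect_equal(nrow(st30$gt30), 0L)

  b10 <- within(randomDayBouts(1), duration <- 10)
  st10 <- stratifyBouts(b10)
  expect_equal(nrow(st10$all), 1L)
  expect_equal(nrow(st10$gt10), 0L)
  expect_equal(nrow(st10$shorter), 0L)

  set.seed(3)
  for (rep in 1:20) {
    b <- randomDayBouts(sample(0:50, 1))
    st <- stratifyBouts(b)
    expect_true(nrow(st$all) >= nrow(st$gt10))
    expect_true(nrow(st$gt10) >= nrow(st$gt30))
    expect_true(nrow(st$gt30) >= nrow(st$gt60))
    expect_equal(nrow(st$shorter) + nrow(st$gt30), nrow(st$gt10))
    expect_equal(sort(c(st$shorter$duration, st$gt30$duration)), sort(st$gt10$duration))
  }
})

test_that("percentile and COV primitives match hand-computed values", {
  expect_equal(percentileP90(c(7, 7, 7)), 7)
  expect_equal(percentileP90(1:10), 9.1)
  expect_equal(percentileP90(4.2), 4.2)
  expect_true(is.na(percentileP90(numeric())))

  expect_equal(boutCoV(c(3, 3, 3)), 0)
  expect_equal(boutCoV(c(2, 4)), sqrt(2) / 3, tolerance = 1e-12)
  expect_true(is.na(boutCoV(5)))
  expect_true(is.na(boutCoV(c(-2, 1))))  # non-positive mean

  set.seed(5)
  for (rep in 1:20) {
    x <- runif(sample(2:40, 1), 1, 50)
    expect_equal(percentileP90(x), oracleQuantile(x, 0.9), tolerance = 1e-12)
    expect_equal(boutCoV(x), oracleCov(x), tolerance = 1e-12)
  }
})

test_that("daily DMO computation matches the brute-force oracle and the vectorized path", {
  set.seed(101)
  cfg <- dmoConfig()
  for (rep in 1:150) {
    n <- sample(c(0, 1, 2, sample(3:80, 1)), 1)
    b <- randomDayBouts(n)
    day <- makeDay(b)
    got <- computeDailyDMOs(day, cfg)
    exp <- oracleDaily(b)
    for (f in dmoNames()) {
      if (is.na(exp[[f]])) expect_true(is.na(got[[f]]), label = paste(f, "defined-ness"))
      else expect_equal(got[[f]], exp[[f]], tolerance = 1e-12, label = f)
    }
    # vectorized cohort path agrees with the scalar reference path
    if (n > 0) {
      b2 <- cbind(participant_id = "p1", start = posix("2013-05-06 10:00:00") + seq_len(n),
                  b)
      flags <- data.frame(participant_id = "p1", date = as.Date("2013-05-06"),
                          wear_hours = 13, valid = TRUE)
      vec <- dmobench:::.dailyDMOTable(b2, flags, cfg)
      for (f in dmoNames())
        expect_equal(vec[[f]], got[[f]], tolerance = 1e-12, label = paste("vec", f))
    }
  }
  expect_error(computeDailyDMOs(makeDay(randomDayBouts(3), valid = FALSE)), "invalid day")
})

test_that("a valid bout-free day has zero sums and counts but undefined statistics", {
  r <- computeDailyDMOs(makeDay(randomDayBouts(0)))
  expect_equal(r$walking_duration, 0)
  expect_equal(r$n_steps, 0)
  expect_equal(r$n_wb + r$n_wb_gt10 + r$n_wb_gt30 + r$n_wb_gt60, 0)
  statCols <- setdiff(dmoNames(), c("walking_duration", "n_steps", "n_wb",
                                    "n_wb_gt10", "n_wb_gt30", "n_wb_gt60"))
  expect_true(all(is.na(unlist(r[statCols]))))
})

test_that("speed statistics are scale-equivariant and COVs scale-invariant", {
  set.seed(21)
  b <- randomDayBouts(40)
  r1 <- computeDailyDMOs(makeDay(b))
  b2 <- b
  b2$speed <- b$speed * 3
  r2 <- computeDailyDMOs(makeDay(b2))
  for (f in c("speed_short", "speed_long", "speed_p90_gt10", "speed_p90_long"))
    expect_equal(r2[[f]], 3 * r1[[f]], tolerance = 1e-12, label = f)
  expect_equal(r2$speed_cov_long, r1$speed_cov_long, tolerance = 1e-12)
  # P90 never below the median of the same values
  expect_true(r1$wb_duration_p90 >= r1$wb_duration_median)
})

test_that("weekly aggregation averages defined daily values and applies the valid-week rule", {
  set.seed(31)
  d1 <- computeDailyDMOs(makeDay(randomDayBouts(25)))
  # 7 identical daily records collapse to the daily record
  daily7 <- do.call(rbind, replicate(7, d1, simplify = FALSE))
  daily7$date <- as.Date("2013-05-06") + 0:6
  wk <- aggregateWeekly(daily7)
  expect_equal(wk$n_valid_days, 7L)
  for (f in dmoNames()) {
    if (is.na(d1[[f]])) expect_true(is.na(wk[[f]]))
    else expect_equal(wk[[f]], d1[[f]], tolerance = 1e-12, label = f)
  }
  # below the valid-week threshold: exclusion marker
  expect_null(aggregateWeekly(daily7[1:2, ]))
  # partial definition: mean over defined values, contribution count recorded
  d <- daily7[1:3, ]
  d$speed_long <- c(0.8, NA, 0.9)
  wk3 <- aggregateWeekly(d)
  expect_equal(wk3$speed_long, 0.85)
  expect_equal(attr(wk3, "nDaysContributing")[["speed_long"]], 2L)
})

test_that("cohort table retains exactly the participants passing the valid-week scan", {
  cfg <- syntheticConfig(nParticipants = 12, nDays = 5)
  coh <- generateCohort(cfg, seed = 5)
  se <- suppressMessages(computeCohortTable(coh$participants, coh$bouts, coh$wear))
  expect_s4_class(se, "DMOExperiment")
  expect_equal(nrow(se), 24L)
  # brute-force re-scan of the validity rules
  fl <- flagValidDays(coh$wear)
  nv <- tapply(fl$valid, fl$participant_id, sum)
  expect_equal(sort(colnames(se)), sort(names(nv)[nv >= 3]))
  expect_equal(unname(nValidDays(se)[colnames(se)]), as.vector(nv[colnames(se)]))
  # daily counts are monotone across strata on every day
  dl <- dmoDaily(se)
  expect_true(all(dl$n_wb >= dl$n_wb_gt10 & dl$n_wb_gt10 >= dl$n_wb_gt30 &
                    dl$n_wb_gt30 >= dl$n_wb_gt60))
})
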