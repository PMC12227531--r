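test_that("participant reader computes BMI, rejects bad rows and round-trips", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,age,sex,height_cm,weight_kg",
               "p1,70,F,155,65",
               "p2,82,M,171,80.5"), f)
  p <- readParticipants(f)
  expect_equal(nrow(p), 2L)
  expect_equal(p$bmi[1], 65 / 1.55^2, tolerance = 1e-12)
  expect_s3_class(p$sex, "factor")

  writeLines("id,age,sex,height_cm,weight_kg", f)
  expect_equal(nrow(readParticipants(f)), 0L)

  writeLines(c("id,age,sex,height_cm,weight_kg", "p1,70,F,155,65", "p1,71,M,170,70"), f)
  expect_error(readParticipants(f), "duplicate")
  writeLines(c("id,age,sex,height_cm,weight_kg", "p1,70,X,155,65"), f)
  expect_error(readParticipants(f), "sex")
  writeLines(c("id,age,sex,height_cm,weight_kg", "p1,70,F,155,banana"), f)
  expect_error(readParticipants(f), "non-numeric")
  writeLines(c("id,age,sex,height_cm,weight_kg", "p1,140,F,155,65"), f)
  expect_error(readParticipants(f), "age out of range")
  writeLines(c("id,age,sex,height_cm", "p1,70,F,155"), f)
  expect_error(readParticipants(f), "missing required column")
})

test_that("bout reader validates, warns on step inconsistency, sorts by time", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- "participant_id,start,duration_s,n_steps,cadence_spm,speed_ms,stride_length_cm,stride_duration_s"
  writeLines(c(hdr, "p1,2013-05-02T09:15:00,12.0,17,85.0,0.64,90.0,1.41"), f)
  b <- readBouts(f)
  expect_equal(nrow(b), 1L)  # 12 * 85 / 60 = 17, consistency ok
  expect_equal(b$duration, 12)

  writeLines(c(hdr, "p1,2013-05-02T09:15:00,-1,17,85.0,0.64,90.0,1.41"), f)
  expect_error(readBouts(f), "non-positive duration")
  writeLines(c(hdr, "p1,not-a-time,12,17,85.0,0.64,90.0,1.41"), f)
  expect_error(readBouts(f), "malformed")
  writeLines(c(hdr, "p1,2013-05-02T09:15:00,12,99,85.0,0.64,90.0,1.41"), f)
  expect_warning(readBouts(f), "step count")

  writeLines(c(hdr,
               "p1,2013-05-02T11:00:00,12,17,85,0.64,90,1.41",
               "p1,2013-05-02T09:00:00,12,17,85,0.64,90,1.41",
               "p1,2013-05-02T10:00:00,12,17,85,0.64,90,1.41"), f)
  b <- readBouts(f)
  expect_false(is.unsorted(b$start))
})

test_that("wear-interval merging preserves union measure (minute-grid oracle)", {
  w <- data.frame(participant_id = "p1",
                  start = posix(c("2013-05-02 09:00:00", "2013-05-02 11:00:00")),
                  end = posix(c("2013-05-02 12:00:00", "2013-05-02 13:00:00")))
  m <- mergeWearIntervals(w)
  expect_equal(nrow(m), 1L)
  expect_equal(as.numeric(difftime(m$end, m$start, units = "hours")), 4)

  disj <- data.frame(participant_id = "p1",
                     start = posix(c("2013-05-02 09:00:00", "2013-05-02 11:00:00")),
                     end = posix(c("2013-05-02 10:00:00", "2013-05-02 12:00:00")))
  expect_equal(nrow(mergeWearIntervals(disj)), 2L)

  expect_error(mergeWearIntervals(data.frame(participant_id = "p1",
                                             start = posix("2013-05-02 10:00:00"),
                                             end = posix("2013-05-02 10:00:00"))),
               "end <= start")

  set.seed(42)
  day0 <- as.numeric(posix("2013-05-02 00:00:00"))
  for (rep in 1:25) {
    n <- sample(1:12, 1)
    sMin <- sample(0:2000, n, replace = TRUE)
    eMin <- sMin + sample(1:400, n, replace = TRUE)
    w <- data.frame(participant_id = "p1",
                    start = as.POSIXct(day0 + sMin * 60, origin = "1970-01-01", tz = "UTC"),
                    end = as.POSIXct(day0 + eMin * 60, origin = "1970-01-01", tz = "UTC"))
    m <- mergeWearIntervals(w)
    got <- sum(as.numeric(m$end) - as.numeric(m$start)) / 3600
    expect_equal(got, oracleUnionHours(sMin, eMin), tolerance = 1e-9)
    # disjointness after merging
    if (nrow(m) > 1L)
      expect_true(all(as.numeric(m$start[-1]) > as.numeric(m$end[-nrow(m)])))
  }
})

test_that("cohorts survive a write/read round trip exactly", {
  coh <- generateCohort(syntheticConfig(nParticipants = 6, nDays = 3), seed = 11)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_equal(back$participants$id, coh$participants$id)
  expect_equal(back$participants$height, coh$participants$height, tolerance = 1e-9)
  expect_equal(back$participants$bmi, coh$participants$bmi, tolerance = 1e-9)
  expect_equal(nrow(back$bouts), nrow(coh$bouts))
  # timestamps to the second
  expect_equal(as.numeric(back$bouts$start), floor(as.numeric(coh$bouts$start)))
  expect_equal(back$bouts$speed, coh$bouts$speed, tolerance = 1e-9)
  expect_equal(as.numeric(back$wear$start), floor(as.numeric(coh$wear$start)))
  expect_true(is.list(back$truth))
})
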