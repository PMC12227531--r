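## The DMO engine: bout-to-day assignment, wear-time validity
## filtering, bout stratification by duration, the daily statistics of
## the 24 DMOs, and weekly aggregation into the cohort table.

#' Assign walking bouts to calendar days
#'
#' Each bout belongs to exactly one calendar day: the day containing
#' its start time. Bouts are atomic and never split, so a bout starting
#' just before midnight is credited wholly to its start day.
#'
#' @param bouts A bout `data.frame` for one participant.
#' @return A named list (one element per calendar day, `"YYYY-MM-DD"`)
#'   of bout `data.frame`s.
#' @export
assignBoutsToDays <- function(bouts) {
  if (nrow(bouts) == 0L) return(structure(list(), names = character()))
  d <- as.Date(bouts$start, tz = .DMO_TZ)
  split(bouts, as.character(d))
}

## Per-date wear hours from merged intervals; intervals crossing
## midnight are credited to each day by clock-time intersection.
.wearHoursByDate <- function(wear) {
  if (nrow(wear) == 0L)
    return(data.frame(participant_id = character(), date = as.Date(character()),
                      wear_hours = numeric()))
  s <- as.numeric(wear$start)
  e <- as.numeric(wear$end)
  d0 <- floor(s / 86400)
  d1 <- floor((e - 1e-6) / 86400)  # an end exactly at midnight belongs to the previous day
  nd <- as.integer(d1 - d0 + 1)
  idx <- rep.int(seq_along(s), nd)
  day <- d0[idx] + (sequence(nd) - 1L)
  dayStart <- day * 86400
  ov <- pmin(e[idx], dayStart + 86400) - pmax(s[idx], dayStart)
  dt <- data.table::data.table(participant_id = wear$participant_id[idx],
                               date = as.Date(day, origin = "1970-01-01"),
                               h = ov / 3600)
  out <- dt[, .(wear_hours = sum(h)), by = .(participant_id, date)]
  as.data.frame(out)
}

#' Flag valid monitoring days from wear intervals
#'
#' Computes the wear time credited to each calendar day (intersecting
#' merged wear intervals with the day's clock-time boundaries) and
#' flags a day as valid when wear strictly exceeds
#' `config$minWearHours` (default 12 h). The monitored range per
#' participant runs from the first to the last wear interval, capped at
#' `config$maxMonitoredDays` calendar days; in-range days without any
#' wear appear with 0 h and `valid = FALSE`.
#'
#' @param wear A wear-interval `data.frame`; overlaps are merged
#'   internally via [mergeWearIntervals()].
#' @param dates Optional `Date` vector overriding the monitored range
#'   (applied to every participant).
#' @param config A [dmoConfig()] object.
#' @return A `data.frame` with columns `participant_id`, `date`,
#'   `wear_hours`, `valid`.
#' @examples
#' w <- data.frame(participant_id = "p1",
#'                 start = as.POSIXct("2013-05-02 08:00:00", tz = "UTC"),
#'                 end   = as.POSIXct("2013-05-02 21:00:00", tz = "UTC"))
#' flagValidDays(w)  # 13 h, valid
#' @export
flagValidDays <- function(wear, dates = NULL, config = dmoConfig()) {
  config <- .asDMOConfig(config)
  wear <- mergeWearIntervals(wear)
  wh <- .wearHoursByDate(wear)
  ids <- unique(wear$participant_id)
  grids <- lapply(ids, function(pid) {
    if (is.null(dates)) {
      sub <- wear[wear$participant_id == pid, , drop = FALSE]
      d0 <- as.Date(min(sub$start), tz = .DMO_TZ)
      d1 <- as.Date(max(sub$end - 1e-6), tz = .DMO_TZ)
      dd <- seq(d0, d1, by = "day")
      if (length(dd) > config$maxMonitoredDays)
        dd <- dd[seq_len(config$maxMonitoredDays)]
    } else dd <- as.Date(dates)
    data.frame(participant_id = pid, date = dd)
  })
  grid <- do.call(rbind, grids)
  out <- merge(grid, wh, by = c("participant_id", "date"), all.x = TRUE)
  out$wear_hours[is.na(out$wear_hours)] <- 0
  out$wear_hours <- pmin(out$wear_hours, 24)
  out$valid <- out$wear_hours > config$minWearHours
  out[order(out$participant_id, out$date), , drop = FALSE]
}

#' Stratify one day's bouts by duration
#'
#' Splits bouts into the duration strata used by the DMO definitions:
#' `all` (every bout), `gt10`, `gt30`, `gt60` (duration strictly greater
#' than 10, 30, 60 s) and `shorter` (duration in `(10, 30]` s). By
#' construction `gt10 = shorter + gt30` (disjoint) and
#' `gt10 >= gt30 >= gt60`.
#'
#' @param bouts A bout `data.frame` (one day's bouts).
#' @param config A [dmoConfig()] object supplying the thresholds.
#' @return A named list of bout `data.frame`s:
#'   `all`, `gt10`, `gt30`, `gt60`, `shorter`.
#' @export
stratifyBouts <- function(bouts, config = dmoConfig()) {
  config <- .asDMOConfig(config)
  th <- config$strataThresholds
  d <- bouts$duration
  list(all = bouts,
       gt10 = bouts[d > th[1], , drop = FALSE],
       gt30 = bouts[d > th[2], , drop = FALSE],
       gt60 = bouts[d > th[3], , drop = FALSE],
       shorter = bouts[d > th[1] & d <= th[2], , drop = FALSE])
}

#' Percentile of a per-bout measure (robust "maximum")
#'
#' The upper percentile (default 90th) of a set of per-bout values,
#' using linear interpolation between closest order statistics
#' (position `1 + p/100 * (n - 1)`). With no defined values the result
#' is `NA` (undefined).
#'
#' @param values Numeric vector; `NA`s are dropped.
#' @param percentile Percentile in (0, 100). Default 90.
#' @return A single numeric value, or `NA_real_` when `values` is empty.
#' @examples
#' percentileP90(1:10)  # 9.1
#' @export
percentileP90 <- function(values, percentile = 90) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) return(NA_real_)
  stats::quantile(values, percentile / 100, type = 7, names = FALSE)
}

#' Bout-to-bout coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of
#' a day's per-bout values. Undefined (`NA`) with fewer than
#' `covMinBouts` values or a non-positive mean: the variability of a
#' single bout is meaningless.
#'
#' @param values Numeric vector of per-bout values; `NA`s are dropped.
#' @param covMinBouts Minimum number of values required. Default 2.
#' @return A single numeric value, or `NA_real_` when undefined.
#' @examples
#' boutCoV(c(2, 4))  # sqrt(2) / 3
#' @export
boutCoV <- function(values, covMinBouts = 2) {
  values <- values[!is.na(values)]
  if (length(values) < covMinBouts) return(NA_real_)
  m <- mean(values)
  if (m <= 0) return(NA_real_)
  stats::sd(values) / m
}

#' Compute the 24 daily DMOs for one valid day
#'
#' Applies the daily calculation of each DMO to one participant-day:
#' sums (walking duration, steps) and bout counts over the duration
#' strata, the median and upper percentile of bout duration, per-bout
#' means of speed, stride length, cadence and stride duration over the
#' relevant strata, percentile "maxima", and bout-to-bout COVs. On a
#' valid day without bouts, sums and counts are 0 while every mean,
#' percentile and COV is undefined (`NA`): absence of walking is real
#' data for volume metrics, but statistics of an empty set are not.
#'
#' @param day A list with elements `participant_id`, `date`,
#'   `wear_hours`, `valid`, and `bouts` (a bout `data.frame`), e.g. one
#'   row of [flagValidDays()] output plus that day's bouts.
#' @param config A [dmoConfig()] object.
#' @return A one-row `data.frame` with `participant_id`, `date`,
#'   `wear_hours` and one column per DMO (see [dmoNames()]).
#' @export
computeDailyDMOs <- function(day, config = dmoConfig()) {
  config <- .asDMOConfig(config)
  if (!isTRUE(day$valid))
    stop("computeDailyDMOs() called on an invalid day (",
         day$participant_id, " ", day$date, ")")
  st <- stratifyBouts(day$bouts, config)
  p <- config$percentile
  k <- config$covMinBouts
  mn <- function(x) if (length(x)) mean(x) else NA_real_
  md <- function(x) if (length(x)) stats::median(x) else NA_real_
  out <- data.frame(
    participant_id = day$participant_id,
    date = as.Date(day$date),
    wear_hours = day$wear_hours,
    walking_duration = sum(st$all$duration) / 3600,
    n_steps = sum(st$all$n_steps),
    n_wb = nrow(st$all),
    n_wb_gt10 = nrow(st$gt10),
    n_wb_gt30 = nrow(st$gt30),
    n_wb_gt60 = nrow(st$gt60),
    wb_duration_median = md(st$all$duration),
    wb_duration_p90 = percentileP90(st$all$duration, p),
    wb_duration_cov = boutCoV(st$all$duration, k),
    speed_short = mn(st$shorter$speed),
    speed_long = mn(st$gt30$speed),
    speed_p90_gt10 = percentileP90(st$gt10$speed, p),
    speed_p90_long = percentileP90(st$gt30$speed, p),
    stride_len_short = mn(st$shorter$stride_length),
    stride_len_long = mn(st$gt30$stride_length),
    cadence_all = mn(st$all$cadence),
    cadence_long = mn(st$gt30$cadence),
    cadence_p90_long = percentileP90(st$gt30$cadence, p),
    stride_dur_all = mn(st$all$stride_duration),
    stride_dur_long = mn(st$gt30$stride_duration),
    speed_cov_long = boutCoV(st$gt30$speed, k),
    stride_len_cov_long = boutCoV(st$gt30$stride_length, k),
    cadence_cov = boutCoV(st$all$cadence, k),
    stride_dur_cov = boutCoV(st$all$stride_duration, k),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Vectorized daily DMO table over many participant-days (valid days
## only). Must agree exactly with computeDailyDMOs(); both are checked
## against each other and an independent oracle in the test suite.
.dailyDMOTable <- function(bouts, validDays, config) {
  config <- .asDMOConfig(config)
  th <- config$strataThresholds
  p <- config$percentile / 100
  k <- config$covMinBouts
  days <- data.table::as.data.table(validDays[validDays$valid,
                                              c("participant_id", "date", "wear_hours")])
  if (nrow(days) == 0L) stop("no valid days to aggregate")
  b <- data.table::as.data.table(bouts)
  b[, date := as.Date(start, tz = .DMO_TZ)]
  # keep only bouts falling on a valid monitored day
  b <- b[days, on = c("participant_id", "date"), nomatch = NULL]
  q90 <- function(x) stats::quantile(x, p, type = 7, names = FALSE)
  by <- c("participant_id", "date")
  aAll <- b[, .(walking_duration = sum(duration) / 3600,
                n_steps = sum(n_steps),
                n_wb = .N,
                wb_duration_median = stats::median(duration),
                wb_duration_p90 = q90(duration),
                .dur_sd = stats::sd(duration), .dur_mn = mean(duration),
                cadence_all = mean(cadence), .cad_sd = stats::sd(cadence),
                stride_dur_all = mean(stride_duration),
                .sdur_sd = stats::sd(stride_duration)), by = by]
  a10 <- b[duration > th[1], .(n_wb_gt10 = .N, speed_p90_gt10 = q90(speed)), by = by]
  a30 <- b[duration > th[2], .(n_wb_gt30 = .N,
                               speed_long = mean(speed), .sp_sd = stats::sd(speed),
                               speed_p90_long = q90(speed),
                               stride_len_long = mean(stride_length),
                               .sl_sd = stats::sd(stride_length),
                               cadence_long = mean(cadence),
                               cadence_p90_long = q90(cadence),
                               stride_dur_long = mean(stride_duration)), by = by]
  a60 <- b[duration > th[3], .(n_wb_gt60 = .N), by = by]
  aSh <- b[duration > th[1] & duration <= th[2],
           .(speed_short = mean(speed), stride_len_short = mean(stride_length)), by = by]
  out <- Reduce(function(x, y) merge(x, y, by = by, all.x = TRUE),
                list(days, aAll, a10, a30, a60, aSh))
  for (col in c("walking_duration", "n_steps", "n_wb", "n_wb_gt10", "n_wb_gt30", "n_wb_gt60"))
    data.table::set(out, which(is.na(out[[col]])), col, 0)
  cov <- function(sdv, mnv, n) ifelse(n >= k & !is.na(mnv) & mnv > 0, sdv / mnv, NA_real_)
  out[, `:=`(wb_duration_cov = cov(.dur_sd, .dur_mn, n_wb),
             cadence_cov = cov(.cad_sd, cadence_all, n_wb),
             stride_dur_cov = cov(.sdur_sd, stride_dur_all, n_wb),
             speed_cov_long = cov(.sp_sd, speed_long, n_wb_gt30),
             stride_len_cov_long = cov(.sl_sd, stride_len_long, n_wb_gt30))]
  out[, c(".dur_sd", ".dur_mn", ".cad_sd", ".sdur_sd", ".sp_sd", ".sl_sd") := NULL]
  data.table::setcolorder(out, c("participant_id", "date", "wear_hours", dmoNames()))
  data.table::setorder(out, participant_id, date)
  as.data.frame(out)
}

#' Aggregate one participant's daily DMO records into a weekly record
#'
#' The weekly value of each DMO is the unweighted mean of its defined
#' daily values over the participant's valid days; the number of days
#' contributing to each DMO is recorded. Participants with fewer than
#' `config$minValidDays` valid days (default 3) are excluded: the
#' function then returns `NULL` as the exclusion marker.
#'
#' @param daily A `data.frame` of daily DMO records (rows from
#'   [computeDailyDMOs()]) for one participant's valid days.
#' @param config A [dmoConfig()] object.
#' @return A one-row `data.frame` with `participant_id`,
#'   `n_valid_days` and one column per DMO, carrying an
#'   `nDaysContributing` attribute (named integer vector per DMO), or
#'   `NULL` when the participant is excluded.
#' @export
aggregateWeekly <- function(daily, config = dmoConfig()) {
  config <- .asDMOConfig(config)
  if (nrow(daily) < config$minValidDays) return(NULL)
  if (length(unique(daily$participant_id)) != 1L)
    stop("aggregateWeekly() expects the daily records of one participant")
  vals <- daily[, dmoNames(), drop = FALSE]
  wk <- vapply(vals, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE),
               numeric(1))
  ndc <- vapply(vals, function(x) sum(!is.na(x)), integer(1))
  out <- data.frame(participant_id = daily$participant_id[1],
                    n_valid_days = nrow(daily), as.list(wk),
                    stringsAsFactors = FALSE)
  attr(out, "nDaysContributing") <- ndc
  out
}

#' Compute the weekly cohort DMO table
#'
#' Runs the full aggregation for a cohort: merges wear intervals, flags
#' valid days, assigns bouts to days, computes the daily DMOs on valid
#' days, averages them into weekly records, applies the valid-week
#' filter, and returns the result as a [DMOExperiment] joined to the
#' demographics. Counts of excluded days and participants are reported
#' via `message()` and stored in the object's metadata.
#'
#' @param participants Demographics `data.frame` from
#'   [readParticipants()] or [sampleDemographics()].
#' @param bouts Bout `data.frame`.
#' @param wear Wear-interval `data.frame`.
#' @param config A [dmoConfig()] object.
#' @param verbose Emit exclusion messages? Default `TRUE`.
#' @return A [DMOExperiment] with one column per retained participant.
#' @export
computeCohortTable <- function(participants, bouts, wear,
                               config = dmoConfig(), verbose = TRUE) {
  config <- .asDMOConfig(config)
  flags <- flagValidDays(wear, config = config)
  flags <- flags[flags$participant_id %in% participants$id, , drop = FALSE]
  daily <- .dailyDMOTable(bouts, flags, config)
  dt <- data.table::as.data.table(daily)
  nd <- dt[, .N, by = participant_id]
  keep <- nd$participant_id[nd$N >= config$minValidDays]
  if (length(keep) == 0L)
    stop("no participant has at least ", config$minValidDays,
         " valid days; nothing to aggregate")
  cols <- dmoNames()
  wkMean <- dt[participant_id %in% keep,
               c(list(n_valid_days = .N),
                 lapply(.SD, function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))),
               by = participant_id, .SDcols = cols]
  wkN <- dt[participant_id %in% keep,
            lapply(.SD, function(x) sum(!is.na(x))),
            by = participant_id, .SDcols = cols]
  excludedParticipants <- setdiff(unique(participants$id), keep)
  nInvalidDays <- sum(!flags$valid)
  if (verbose) {
    message(sprintf("computeCohortTable: %d invalid day(s) removed; %d participant(s) excluded (<%d valid days); %d retained",
                    nInvalidDays, length(excludedParticipants),
                    config$minValidDays, length(keep)))
  }
  DMOExperiment(weekly = as.data.frame(wkMean),
                participants = participants,
                nDaysContributing = as.data.frame(wkN),
                daily = daily,
                exclusions = list(invalid_days = nInvalidDays,
                                  excluded_participants = excludedParticipants,
                                  n_retained = length(keep)),
                config = config)
}
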