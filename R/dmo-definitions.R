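## Registry of the 24 digital mobility outcomes and their aggregation
## rules, plus the configuration object governing bout stratification,
## validity filtering and weekly aggregation.

# Internal registry. `stat` and `stratum` encode the daily calculation:
#  stat  in {sum, count, median, p90, mean, cov}
#  var   in {duration, n_steps, speed, stride_length, cadence, stride_duration}
#  stratum in {all, gt10, gt30, gt60, shorter}  (shorter = (10, 30] s)
.dmoRegistry <- function() {
  reg <- rbind(
    data.frame(dmo = "walking_duration",   stat = "sum",    var = "duration",        stratum = "all",     domain = "Amount",      unit = "h/day"),
    data.frame(dmo = "n_steps",            stat = "sum",    var = "n_steps",         stratum = "all",     domain = "Amount",      unit = "steps/day"),
    data.frame(dmo = "n_wb",               stat = "count",  var = "duration",        stratum = "all",     domain = "Pattern",     unit = "WB/day"),
    data.frame(dmo = "n_wb_gt10",          stat = "count",  var = "duration",        stratum = "gt10",    domain = "Pattern",     unit = "WB/day"),
    data.frame(dmo = "n_wb_gt30",          stat = "count",  var = "duration",        stratum = "gt30",    domain = "Pattern",     unit = "WB/day"),
    data.frame(dmo = "n_wb_gt60",          stat = "count",  var = "duration",        stratum = "gt60",    domain = "Pattern",     unit = "WB/day"),
    data.frame(dmo = "wb_duration_median", stat = "median", var = "duration",        stratum = "all",     domain = "Pattern",     unit = "s"),
    data.frame(dmo = "wb_duration_p90",    stat = "p90",    var = "duration",        stratum = "all",     domain = "Pattern",     unit = "s"),
    data.frame(dmo = "wb_duration_cov",    stat = "cov",    var = "duration",        stratum = "all",     domain = "Pattern",     unit = "-"),
    data.frame(dmo = "speed_short",        stat = "mean",   var = "speed",           stratum = "shorter", domain = "Pace",        unit = "m/s"),
    data.frame(dmo = "speed_long",         stat = "mean",   var = "speed",           stratum = "gt30",    domain = "Pace",        unit = "m/s"),
    data.frame(dmo = "speed_p90_gt10",     stat = "p90",    var = "speed",           stratum = "gt10",    domain = "Pace",        unit = "m/s"),
    data.frame(dmo = "speed_p90_long",     stat = "p90",    var = "speed",           stratum = "gt30",    domain = "Pace",        unit = "m/s"),
    data.frame(dmo = "stride_len_short",   stat = "mean",   var = "stride_length",   stratum = "shorter", domain = "Pace",        unit = "cm"),
    data.frame(dmo = "stride_len_long",    stat = "mean",   var = "stride_length",   stratum = "gt30",    domain = "Pace",        unit = "cm"),
    data.frame(dmo = "cadence_all",        stat = "mean",   var = "cadence",         stratum = "all",     domain = "Rhythm",      unit = "steps/min"),
    data.frame(dmo = "cadence_long",       stat = "mean",   var = "cadence",         stratum = "gt30",    domain = "Rhythm",      unit = "steps/min"),
    data.frame(dmo = "cadence_p90_long",   stat = "p90",    var = "cadence",         stratum = "gt30",    domain = "Rhythm",      unit = "steps/min"),
    data.frame(dmo = "stride_dur_all",     stat = "mean",   var = "stride_duration", stratum = "all",     domain = "Rhythm",      unit = "s"),
    data.frame(dmo = "stride_dur_long",    stat = "mean",   var = "stride_duration", stratum = "gt30",    domain = "Rhythm",      unit = "s"),
    data.frame(dmo = "speed_cov_long",     stat = "cov",    var = "speed",           stratum = "gt30",    domain = "Variability", unit = "-"),
    data.frame(dmo = "stride_len_cov_long",stat = "cov",    var = "stride_length",   stratum = "gt30",    domain = "Variability", unit = "-"),
    data.frame(dmo = "cadence_cov",        stat = "cov",    var = "cadence",         stratum = "all",     domain = "Variability", unit = "-"),
    data.frame(dmo = "stride_dur_cov",     stat = "cov",    var = "stride_duration", stratum = "all",     domain = "Variability", unit = "-")
  )
  rownames(reg) <- reg$dmo
  reg
}

#' Names, domains and units of the 24 digital mobility outcomes
#'
#' `dmoNames()` returns the stable snake_case identifiers of the 24 DMOs
#' in their canonical order; `dmoDomains()` the a-priori mobility domain
#' (Amount, Pattern, Pace, Rhythm, Variability) of each; `dmoUnits()`
#' the measurement unit of each.
#'
#' @return A character vector of length 24 (named for `dmoDomains` and
#'   `dmoUnits`).
#' @examples
#' dmoNames()
#' table(dmoDomains())
#' @export
dmoNames <- function() .dmoRegistry()$dmo

#' @rdname dmoNames
#' @export
dmoDomains <- function() {
  reg <- .dmoRegistry()
  setNames(reg$domain, reg$dmo)
}

#' @rdname dmoNames
#' @export
dmoUnits <- function() {
  reg <- .dmoRegistry()
  setNames(reg$unit, reg$dmo)
}

#' Configuration of the DMO computation
#'
#' Bundles the thresholds and filters that define the daily and weekly
#' DMO computation: bout-duration strata boundaries, the wear-time
#' validity rule, the valid-week rule, the percentile used as a robust
#' maximum, and the minimum number of bouts required for a
#' coefficient-of-variation (COV) statistic.
#'
#' Strata are defined on bout duration `d` as: `gtX` means `d > X`
#' strictly; the "shorter" stratum is `10 < d <= 30`, so that the
#' shorter and `gt30` strata exactly partition `gt10`. A monitored day
#' is valid when its wear time strictly exceeds `minWearHours`; a
#' participant-week enters the analysis only with at least
#' `minValidDays` valid days.
#'
#' @param strataThresholds Increasing bout-duration thresholds in
#'   seconds. Default `c(10, 30, 60)`.
#' @param minWearHours Wear-time threshold (hours) a day must strictly
#'   exceed to count as valid. Default 12.
#' @param minValidDays Minimum number of valid days for a valid week.
#'   Default 3.
#' @param percentile Upper percentile reported as the robust "maximum"
#'   of a per-bout measure. Default 90.
#' @param covMinBouts Minimum number of bouts for a defined COV.
#'   Default 2.
#' @param maxMonitoredDays Cap on the monitored calendar-day range per
#'   participant (first to last wear interval). Default 8, i.e. a
#'   one-week protocol with possibly partial first and last days.
#' @return An object of class `DMOConfig` (a validated list).
#' @examples
#' cfg <- dmoConfig()
#' cfg$minWearHours
#' @export
dmoConfig <- function(strataThresholds = c(10, 30, 60),
                      minWearHours = 12,
                      minValidDays = 3,
                      percentile = 90,
                      covMinBouts = 2,
                      maxMonitoredDays = 8) {
  if (length(strataThresholds) != 3L || any(diff(strataThresholds) <= 0))
    stop("`strataThresholds` must be three strictly increasing values")
  if (percentile <= 0 || percentile >= 100)
    stop("`percentile` must lie strictly between 0 and 100")
  if (minValidDays < 1) stop("`minValidDays` must be >= 1")
  if (minWearHours < 0 || minWearHours > 24)
    stop("`minWearHours` must be in [0, 24]")
  if (covMinBouts < 2) stop("`covMinBouts` must be >= 2")
  structure(list(strataThresholds = as.numeric(strataThresholds),
                 minWearHours = as.numeric(minWearHours),
                 minValidDays = as.integer(minValidDays),
                 percentile = as.numeric(percentile),
                 covMinBouts = as.integer(covMinBouts),
                 maxMonitoredDays = as.integer(maxMonitoredDays)),
            class = "DMOConfig")
}

.asDMOConfig <- function(config) {
  if (inherits(config, "DMOConfig")) return(config)
  if (is.null(config)) return(dmoConfig())
  do.call(dmoConfig, config)
}
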