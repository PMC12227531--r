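## CSV readers/writers and validation for the three cohort input tables:
## demographics, walking bouts, and wear intervals. All timestamps are
## naive local clock time in ISO-8601 (no timezone); internally they are
## stored as POSIXct with tz = "UTC" purely as a fixed-offset carrier so
## that calendar-day arithmetic follows the participant's clock.

.DMO_TZ <- "UTC"
.TS_FORMATS <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")

.parseTimestamp <- function(x, what = "timestamp") {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = .DMO_TZ)
  for (fmt in .TS_FORMATS) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = fmt, tz = .DMO_TZ)
  }
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad))
    stop(sprintf("malformed %s in row %d: '%s'", what, bad[1], x[bad[1]]))
  if (anyNA(out)) stop(sprintf("missing %s in row %d", what, which(is.na(out))[1]))
  out
}

.formatTimestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = .DMO_TZ)

.requireColumns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
}

.numericColumn <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x)) x[!nzchar(trimws(x))] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' in column '%s', row %d of '%s'",
                 x[bad[1]], col, bad[1], path))
  out
}

#' Read and validate a participant demographics table
#'
#' Expects a UTF-8 comma-separated file with header columns `id`, `age`,
#' `sex`, `height_cm`, `weight_kg` and optionally
#' `clinical_speed_usual`, `clinical_speed_fast` (4-m gait speeds in
#' m/s). Body mass index is always recomputed from height and weight;
#' any `bmi` column in the file is ignored.
#'
#' Load errors (naming the offending row) are raised for missing
#' columns, non-numeric fields, duplicated ids, sex codes outside
#' \{F, M\}, and out-of-range values: age outside 60-110 years,
#' height outside 120-220 cm, weight outside 30-200 kg.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `id`, `age`, `sex` (factor with
#'   levels F, M), `height`, `weight`, `bmi`, `clinical_speed_usual`,
#'   `clinical_speed_fast` (the last two `NA` when absent).
#' @seealso [readBouts()], [readWearIntervals()], [generateCohort()]
#' @export
readParticipants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .requireColumns(df, c("id", "age", "sex", "height_cm", "weight_kg"), path)
  if (nrow(df) == 0L)
    return(data.frame(id = character(), age = integer(), sex = factor(levels = c("F", "M")),
                      height = numeric(), weight = numeric(), bmi = numeric(),
                      clinical_speed_usual = numeric(), clinical_speed_fast = numeric()))
  id <- as.character(df$id)
  dup <- which(duplicated(id))
  if (length(dup))
    stop(sprintf("duplicate participant id '%s' in row %d of '%s'", id[dup[1]], dup[1], path))
  sex <- as.character(df$sex)
  badSex <- which(!sex %in% c("F", "M"))
  if (length(badSex))
    stop(sprintf("invalid sex code '%s' in row %d of '%s' (must be F or M)",
                 sex[badSex[1]], badSex[1], path))
  age <- .numericColumn(df, "age", path)
  height <- .numericColumn(df, "height_cm", path)
  weight <- .numericColumn(df, "weight_kg", path)
  .checkRange <- function(x, lo, hi, what) {
    bad <- which(is.na(x) | x < lo | x > hi)
    if (length(bad))
      stop(sprintf("%s out of range [%g, %g] in row %d of '%s'", what, lo, hi, bad[1], path))
  }
  .checkRange(age, 60, 110, "age")
  .checkRange(height, 120, 220, "height_cm")
  .checkRange(weight, 30, 200, "weight_kg")
  opt <- function(col) if (col %in% names(df)) .numericColumn(df, col, path) else rep(NA_real_, nrow(df))
  data.frame(id = id, age = as.integer(round(age)), sex = factor(sex, levels = c("F", "M")),
             height = height, weight = weight,
             bmi = weight / (height / 100)^2,
             clinical_speed_usual = opt("clinical_speed_usual"),
             clinical_speed_fast = opt("clinical_speed_fast"),
             stringsAsFactors = FALSE)
}

#' Read and validate a walking-bout table
#'
#' Expects a CSV with header columns `participant_id`, `start`
#' (ISO-8601 local timestamp), `duration_s`, `n_steps`, `cadence_spm`,
#' `speed_ms`, `stride_length_cm`, `stride_duration_s`. Rows are
#' returned sorted by `(participant_id, start)`. Durations and all gait
#' measures must be strictly positive (load error otherwise). A step
#' count further than 2 steps from `duration * cadence / 60` raises a
#' consistency warning, not an error.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `participant_id`, `start`
#'   (POSIXct), `duration`, `n_steps`, `cadence`, `speed`,
#'   `stride_length`, `stride_duration`.
#' @export
readBouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  cols <- c("participant_id", "start", "duration_s", "n_steps", "cadence_spm",
            "speed_ms", "stride_length_cm", "stride_duration_s")
  .requireColumns(df, cols, path)
  out <- data.frame(participant_id = as.character(df$participant_id),
                    start = if (nrow(df)) .parseTimestamp(df$start, "bout start") else
                      as.POSIXct(character(), tz = .DMO_TZ),
                    duration = .numericColumn(df, "duration_s", path),
                    n_steps = .numericColumn(df, "n_steps", path),
                    cadence = .numericColumn(df, "cadence_spm", path),
                    speed = .numericColumn(df, "speed_ms", path),
                    stride_length = .numericColumn(df, "stride_length_cm", path),
                    stride_duration = .numericColumn(df, "stride_duration_s", path),
                    stringsAsFactors = FALSE)
  validateBouts(out, context = path)
}

#' Validate a walking-bout table
#'
#' Applies the bout invariants (positive duration and gait measures,
#' integer step count of at least 1, step-count consistency warning)
#' and returns the table sorted by `(participant_id, start)`.
#'
#' @param bouts A bout `data.frame` as returned by [readBouts()].
#' @param context Label used in error messages (e.g. a file path).
#' @return The validated, sorted bout table.
#' @export
validateBouts <- function(bouts, context = "bouts") {
  if (nrow(bouts) == 0L) return(bouts)
  for (col in c("duration", "cadence", "speed", "stride_length", "stride_duration")) {
    bad <- which(!is.finite(bouts[[col]]) | bouts[[col]] <= 0)
    if (length(bad))
      stop(sprintf("non-positive %s in row %d of '%s'", col, bad[1], context))
  }
  badSteps <- which(!is.finite(bouts$n_steps) | bouts$n_steps < 1 |
                      bouts$n_steps != round(bouts$n_steps))
  if (length(badSteps))
    stop(sprintf("n_steps must be an integer >= 1 (row %d of '%s')", badSteps[1], context))
  expSteps <- bouts$duration * bouts$cadence / 60
  off <- which(abs(bouts$n_steps - expSteps) > 2)
  if (length(off))
    warning(sprintf("%d bout(s) have a step count further than 2 from duration*cadence/60 (first: row %d of '%s')",
                    length(off), off[1], context))
  bouts[order(bouts$participant_id, bouts$start), , drop = FALSE]
}

#' Read and validate a wear-interval table
#'
#' Expects a CSV with header columns `participant_id`, `start`, `end`
#' (ISO-8601 local timestamps). Intervals with `end <= start` are load
#' errors. Overlapping intervals are allowed on input; merge them with
#' [mergeWearIntervals()] before computing wear time.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `participant_id`, `start`, `end`.
#' @export
readWearIntervals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  .requireColumns(df, c("participant_id", "start", "end"), path)
  out <- data.frame(participant_id = as.character(df$participant_id),
                    start = if (nrow(df)) .parseTimestamp(df$start, "wear start") else
                      as.POSIXct(character(), tz = .DMO_TZ),
                    end = if (nrow(df)) .parseTimestamp(df$end, "wear end") else
                      as.POSIXct(character(), tz = .DMO_TZ),
                    stringsAsFactors = FALSE)
  bad <- which(as.numeric(out$end) <= as.numeric(out$start))
  if (length(bad))
    stop(sprintf("wear interval with end <= start in row %d of '%s'", bad[1], path))
  out[order(out$participant_id, out$start), , drop = FALSE]
}

#' Merge overlapping and abutting wear intervals
#'
#' Within each participant, unions overlapping or abutting intervals so
#' the result is a disjoint set covering exactly the same total time.
#'
#' @param intervals A wear-interval `data.frame` (columns
#'   `participant_id`, `start`, `end`).
#' @return A `data.frame` of the same shape with disjoint intervals,
#'   sorted by `(participant_id, start)`.
#' @examples
#' w <- data.frame(participant_id = "p1",
#'                 start = as.POSIXct(c("2013-05-02 09:00:00", "2013-05-02 11:00:00"), tz = "UTC"),
#'                 end   = as.POSIXct(c("2013-05-02 12:00:00", "2013-05-02 13:00:00"), tz = "UTC"))
#' mergeWearIntervals(w)  # one interval 09:00-13:00
#' @export
mergeWearIntervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  bad <- which(as.numeric(intervals$end) <= as.numeric(intervals$start))
  if (length(bad))
    stop(sprintf("wear interval with end <= start (row %d)", bad[1]))
  dt <- data.table::as.data.table(intervals)
  data.table::setorder(dt, participant_id, start)
  # a new run starts whenever an interval begins after the running max end
  dt[, `:=`(s = as.numeric(start), e = as.numeric(end))]
  dt[, grp := {
    cm <- cummax(data.table::shift(cummax(e), fill = -Inf))
    cumsum(s > cm)
  }, by = participant_id]
  merged <- dt[, .(start = start[1],
                   end = as.POSIXct(max(e), origin = "1970-01-01", tz = .DMO_TZ)),
               by = .(participant_id, grp)][, grp := NULL]
  out <- as.data.frame(merged)
  out[order(out$participant_id, out$start), , drop = FALSE]
}

#' Write a cohort to the standard CSV formats
#'
#' Writes `participants.csv`, `bouts.csv` and `wear.csv` (and
#' `truth.json` when the cohort carries a ground-truth effect ledger)
#' into `dir`, using the column schemas accepted by the readers, so
#' that writing and re-reading reproduces the cohort exactly
#' (timestamps to the second).
#'
#' @param cohort A list with elements `participants`, `bouts`, `wear`
#'   and optionally `truth`, e.g. from [generateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- cohort$participants
  pf <- data.frame(id = p$id, age = p$age, sex = as.character(p$sex),
                   height_cm = p$height, weight_kg = p$weight,
                   clinical_speed_usual = p$clinical_speed_usual,
                   clinical_speed_fast = p$clinical_speed_fast)
  b <- cohort$bouts
  bf <- data.frame(participant_id = b$participant_id,
                   start = .formatTimestamp(b$start),
                   duration_s = b$duration, n_steps = b$n_steps,
                   cadence_spm = b$cadence, speed_ms = b$speed,
                   stride_length_cm = b$stride_length,
                   stride_duration_s = b$stride_duration)
  w <- cohort$wear
  wf <- data.frame(participant_id = w$participant_id,
                   start = .formatTimestamp(w$start),
                   end = .formatTimestamp(w$end))
  paths <- file.path(dir, c("participants.csv", "bouts.csv", "wear.csv"))
  utils::write.csv(pf, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(bf, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(wf, paths[3], row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    tp <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$truth, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read a cohort previously written by [writeCohort()]
#'
#' @param dir Directory containing `participants.csv`, `bouts.csv`,
#'   `wear.csv`.
#' @return A list with elements `participants`, `bouts`, `wear` (and
#'   `truth` if `truth.json` is present).
#' @export
readCohort <- function(dir) {
  out <- list(participants = readParticipants(file.path(dir, "participants.csv")),
              bouts = readBouts(file.path(dir, "bouts.csv")),
              wear = readWearIntervals(file.path(dir, "wear.csv")))
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) out$truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  out
}
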