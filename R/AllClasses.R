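## The central analysis container: a SummarizedExperiment whose assay
## is the DMO-by-participant matrix of weekly means, with demographics
## in colData and DMO annotation (domain, unit) in rowData.

#' DMOExperiment: weekly DMO values joined to demographics
#'
#' An S4 container (extending
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class])
#' for the weekly cohort table: the `"dmo"` assay holds the 24
#' digital mobility outcomes (rows, see [dmoNames()]) by retained
#' participant (columns); the `"nDays"` assay the number of valid days
#' contributing to each weekly value; `colData` the demographics plus
#' `n_valid_days`; `rowData` the mobility domain and unit of each DMO.
#' Metadata carries the daily table, the exclusion log and the
#' [dmoConfig()] used.
#'
#' @slot .. see SummarizedExperiment; no additional slots.
#' @aliases DMOExperiment-class
#' @seealso [computeCohortTable()], [dmoMatrix()], [summarizeDMOs()]
#' @export
setClass("DMOExperiment", contains = "SummarizedExperiment")

setValidity("DMOExperiment", function(object) {
  msg <- character()
  if (!"dmo" %in% names(assays(object)))
    msg <- c(msg, "assay 'dmo' is required")
  else {
    m <- assay(object, "dmo")
    if (!identical(rownames(m), dmoNames()))
      msg <- c(msg, "assay rows must be the 24 DMOs in canonical order")
    if (ncol(m) > 0 && any(apply(m, 1, function(x) all(is.na(x)))))
      msg <- c(msg, "a DMO row is entirely undefined")
  }
  need <- c("id", "age", "sex", "height", "weight", "bmi", "n_valid_days")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData is missing: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a DMOExperiment
#'
#' Normally called by [computeCohortTable()]; exported for building the
#' container from externally computed weekly tables.
#'
#' @param weekly `data.frame` with `participant_id`, `n_valid_days` and
#'   one column per DMO.
#' @param participants Demographics `data.frame` (see
#'   [readParticipants()]); joined by id.
#' @param nDaysContributing Optional `data.frame` with `participant_id`
#'   and per-DMO counts of contributing days.
#' @param daily Optional daily DMO `data.frame` kept in metadata.
#' @param exclusions Optional exclusion log (list) kept in metadata.
#' @param config The [dmoConfig()] used.
#' @return A validated `DMOExperiment`.
#' @export
DMOExperiment <- function(weekly, participants, nDaysContributing = NULL,
                          daily = NULL, exclusions = NULL, config = dmoConfig()) {
  ids <- weekly$participant_id
  m <- t(as.matrix(weekly[, dmoNames(), drop = FALSE]))
  colnames(m) <- ids
  rownames(m) <- dmoNames()
  pi <- participants[match(ids, participants$id), , drop = FALSE]
  if (anyNA(pi$id))
    stop("weekly table contains participant ids absent from demographics")
  cd <- S4Vectors::DataFrame(pi, n_valid_days = weekly$n_valid_days, row.names = ids)
  rd <- S4Vectors::DataFrame(domain = unname(dmoDomains()), unit = unname(dmoUnits()),
                             row.names = dmoNames())
  al <- list(dmo = m)
  if (!is.null(nDaysContributing)) {
    nm <- t(as.matrix(nDaysContributing[match(ids, nDaysContributing$participant_id),
                                        dmoNames(), drop = FALSE]))
    dimnames(nm) <- dimnames(m)
    al$nDays <- nm
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = al, colData = cd, rowData = rd)
  obj <- methods::new("DMOExperiment", se)
  S4Vectors::metadata(obj) <- list(daily = daily, exclusions = exclusions,
                                   config = config)
  methods::validObject(obj)
  obj
}

#' Accessors for DMOExperiment
#'
#' `dmoMatrix()` returns the DMO-by-participant matrix of weekly means;
#' `participantData()` the demographics `DataFrame` (one row per
#' retained participant); `nValidDays()` the named vector of valid-day
#' counts; `dmoDaily()` the per-day DMO table stored at construction
#' (or `NULL`).
#'
#' @param x A [DMOExperiment].
#' @return See individual descriptions.
#' @rdname dmoMatrix
#' @export
setGeneric("dmoMatrix", function(x) standardGeneric("dmoMatrix"))

#' @rdname dmoMatrix
#' @export
setMethod("dmoMatrix", "DMOExperiment", function(x) assay(x, "dmo"))

#' @rdname dmoMatrix
#' @export
setGeneric("participantData", function(x) standardGeneric("participantData"))

#' @rdname dmoMatrix
#' @export
setMethod("participantData", "DMOExperiment", function(x) colData(x))

#' @rdname dmoMatrix
#' @export
setGeneric("nValidDays", function(x) standardGeneric("nValidDays"))

#' @rdname dmoMatrix
#' @export
setMethod("nValidDays", "DMOExperiment", function(x)
  setNames(colData(x)$n_valid_days, colnames(x)))

#' @rdname dmoMatrix
#' @export
setGeneric("dmoDaily", function(x) standardGeneric("dmoDaily"))

#' @rdname dmoMatrix
#' @export
setMethod("dmoDaily", "DMOExperiment", function(x) S4Vectors::metadata(x)$daily)

setMethod("show", "DMOExperiment", function(object) {
  cat("DMOExperiment:", nrow(object), "DMOs x", ncol(object), "participants\n")
  cd <- colData(object)
  if (ncol(object)) {
    cat(sprintf("  age %d-%d y; %d F / %d M; mean valid days %.1f\n",
                min(cd$age), max(cd$age), sum(cd$sex == "F"), sum(cd$sex == "M"),
                mean(cd$n_valid_days)))
  }
  ex <- S4Vectors::metadata(object)$exclusions
  if (!is.null(ex))
    cat(sprintf("  exclusions: %d invalid day(s), %d participant(s) below the valid-week rule\n",
                ex$invalid_days, length(ex$excluded_participants)))
  cat("  domains:", paste(unique(rowData(object)$domain), collapse = ", "), "\n")
})
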