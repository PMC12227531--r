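## Non-linear age trends: per-DMO, per-sex Gaussian additive models
## with a penalized-spline smooth of age plus linear height and BMI
## terms; explained deviance, approximate smooth-term p-values, and
## partial-dependence curves with pointwise 95% bands.

#' Fit the age-trend additive model for one DMO
#'
#' Fits `y = s(age) + b1 * height + b2 * bmi + intercept` with a
#' Gaussian identity-link response, a penalized B-spline basis for the
#' age smooth (default 10 basis functions, second-order difference
#' penalty) and the smoothing parameter chosen by generalized
#' cross-validation. Model fit is summarised as explained deviance
#' `1 - residual deviance / null deviance`, and the age effect by the
#' approximate (Wald-type, effective-degrees-of-freedom) significance
#' of the smooth term.
#'
#' @param y Numeric response (one DMO's weekly values).
#' @param age,height,bmi Numeric covariates, same length as `y`.
#' @param k Basis dimension of the age smooth. Default 10.
#' @param dmo,sex Optional labels carried into the result.
#' @return An object of class `dmoGAM`: a list with `fit` (the mgcv
#'   model), `explained_deviance`, `age_term_p`, `edf`, `sp`
#'   (smoothing parameter), `k`, `age_range`, `cov_means`, `n`,
#'   `dmo`, `sex`.
#' @seealso [partialDependenceCurve()], [summarizeGAMFits()],
#'   [gamAgeTrends()]
#' @export
fitDmoGAM <- function(y, age, height, bmi, k = 10, dmo = NA_character_,
                      sex = NA_character_) {
  ok <- stats::complete.cases(y, age, height, bmi)
  d <- data.frame(y = y[ok], age = age[ok], height = height[ok], bmi = bmi[ok])
  if (nrow(d) < 30L)
    stop("fitDmoGAM() needs at least 30 complete observations, got ", nrow(d))
  if (nrow(d) < k + 3L)
    stop("fewer observations than model coefficients (n = ", nrow(d), ", k = ", k, ")")
  fit <- mgcv::gam(y ~ s(age, k = k, bs = "ps", m = 2) + height + bmi,
                   data = d, method = "GCV.Cp")
  sm <- summary(fit)
  structure(list(fit = fit,
                 explained_deviance = unname(sm$dev.expl),
                 age_term_p = unname(sm$s.table[1, "p-value"]),
                 edf = unname(sm$s.table[1, "edf"]),
                 sp = unname(fit$sp),
                 k = k,
                 age_range = range(d$age),
                 cov_means = c(height = mean(d$height), bmi = mean(d$bmi)),
                 n = nrow(d), dmo = dmo, sex = sex),
            class = "dmoGAM")
}

#' @export
print.dmoGAM <- function(x, ...) {
  cat(sprintf("Age-trend GAM%s%s: n = %d, explained deviance = %.1f%%, age p = %.3g (edf %.2f)\n",
              if (is.na(x$dmo)) "" else paste0(" for ", x$dmo),
              if (is.na(x$sex)) "" else paste0(" (", x$sex, ")"),
              x$n, 100 * x$explained_deviance, x$age_term_p, x$edf))
  invisible(x)
}

#' Partial-dependence curve of the age smooth
#'
#' Evaluates the centred partial effect of age on a grid inside the
#' observed age range, with covariates held at their sample means, and
#' a pointwise 95% band (estimate +/- 1.96 standard errors from the
#' penalized-coefficient covariance). Grid points outside the observed
#' range raise an error: the model does not extrapolate.
#'
#' @param fit A `dmoGAM` object.
#' @param ageGrid Numeric grid of ages; default 100 equally spaced
#'   points over the observed range.
#' @param level Band coverage. Default 0.95.
#' @return A `data.frame` with columns `age`, `fit`, `lo`, `hi`.
#' @export
partialDependenceCurve <- function(fit, ageGrid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "dmoGAM"))
  if (is.null(ageGrid))
    ageGrid <- seq(fit$age_range[1], fit$age_range[2], length.out = 100)
  if (any(ageGrid < fit$age_range[1] - 1e-9 | ageGrid > fit$age_range[2] + 1e-9))
    stop("age grid outside the observed range [", fit$age_range[1], ", ",
         fit$age_range[2], "]: no extrapolation")
  nd <- data.frame(age = ageGrid,
                   height = unname(fit$cov_means["height"]),
                   bmi = unname(fit$cov_means["bmi"]))
  pr <- predict(fit$fit, newdata = nd, type = "terms", se.fit = TRUE)
  col <- grep("s\\(age\\)", colnames(pr$fit))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- pr$fit[, col]
  se <- pr$se.fit[, col]
  data.frame(age = ageGrid, fit = est, lo = est - z * se, hi = est + z * se)
}

#' Summarise a family of age-trend fits
#'
#' Tabulates explained deviance (as a percentage), the raw age-term
#' p-value with star coding (* p < 0.05, ** p < 0.01, *** p < 0.001)
#' and the Benjamini-Hochberg adjusted p-value across the family.
#'
#' @param fits A list of `dmoGAM` objects.
#' @return A `data.frame` with columns `dmo`, `sex`, `n`,
#'   `explained_deviance_pct`, `edf`, `age_p`, `stars`, `fdr_p`.
#' @export
summarizeGAMFits <- function(fits) {
  if (!length(fits)) stop("summarizeGAMFits() needs at least one fit")
  out <- do.call(rbind, lapply(fits, function(f)
    data.frame(dmo = f$dmo, sex = f$sex, n = f$n,
               explained_deviance_pct = 100 * f$explained_deviance,
               edf = f$edf, age_p = f$age_term_p, stringsAsFactors = FALSE)))
  out$stars <- cut(out$age_p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", ""))
  out$stars <- as.character(out$stars)
  out$fdr_p <- bhAdjust(out$age_p)
  rownames(out) <- NULL
  out
}

#' Fit age-trend models for every DMO, stratified by sex
#'
#' Convenience wrapper over [fitDmoGAM()] for a [DMOExperiment]: one
#' Gaussian additive model per DMO and sex (height and BMI as linear
#' covariates), skipping combinations with fewer than 30 complete
#' observations.
#'
#' @param x A [DMOExperiment].
#' @param dmos DMOs to fit; default all 24.
#' @param k Basis dimension of the age smooth.
#' @return A list with `fits` (list of `dmoGAM`), `summary` (from
#'   [summarizeGAMFits()]) and `curves` (stacked partial-dependence
#'   curves with `dmo` and `sex` columns).
#' @export
gamAgeTrends <- function(x, dmos = dmoNames(), k = 10) {
  stopifnot(methods::is(x, "DMOExperiment"))
  mat <- dmoMatrix(x)
  cd <- as.data.frame(colData(x))
  fits <- list()
  for (sx in c("F", "M")) {
    sel <- which(cd$sex == sx)
    for (d in dmos) {
      f <- tryCatch(fitDmoGAM(mat[d, sel], cd$age[sel], cd$height[sel], cd$bmi[sel],
                              k = k, dmo = d, sex = sx),
                    error = function(e) NULL)
      if (!is.null(f)) fits[[paste(d, sx, sep = ".")]] <- f
    }
  }
  if (!length(fits)) stop("no DMO x sex combination had enough observations to fit")
  curves <- do.call(rbind, lapply(fits, function(f) {
    cv <- partialDependenceCurve(f)
    data.frame(dmo = f$dmo, sex = f$sex, cv, stringsAsFactors = FALSE)
  }))
  rownames(curves) <- NULL
  list(fits = fits, summary = summarizeGAMFits(fits), curves = curves)
}
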