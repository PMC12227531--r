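## Reference statistics: descriptive summaries, the skewness-gated log
## transform, covariate-adjusted two-group comparisons (ANCOVA),
## Benjamini-Hochberg FDR, Kolmogorov-Smirnov distribution comparison,
## and the sex-specific height split.

#' Adjusted Fisher-Pearson sample skewness
#'
#' The bias-adjusted skewness coefficient
#' `g1 * sqrt(n (n - 1)) / (n - 2)` where `g1 = m3 / m2^(3/2)` with
#' central sample moments `m2`, `m3`.
#'
#' @param x Numeric vector; `NA`s are dropped. Needs at least 3 values.
#' @return The skewness coefficient.
#' @export
sampleSkewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("sampleSkewness() needs at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Skewness-gated log transform
#'
#' Computes the adjusted Fisher-Pearson skewness of the values and,
#' when its absolute value exceeds `threshold` (default 2),
#' natural-log-transforms them. The Shapiro-Wilk normality p-value is
#' reported alongside, but only the skewness gate decides whether the
#' transform fires.
#'
#' @param values Numeric vector with at least 3 defined values.
#' @param threshold Absolute-skewness threshold. Default 2.
#' @return A list with `values` (possibly transformed), `transformed`
#'   (logical), `skewness`, and `shapiro_p` (`NA` when not computable).
#' @examples
#' skewnessGate(c(1, 1, 1, 1, 100))$transformed  # TRUE
#' @export
skewnessGate <- function(values, threshold = 2) {
  ok <- !is.na(values)
  if (sum(ok) < 3L) stop("skewnessGate() needs at least 3 defined values")
  sk <- sampleSkewness(values[ok])
  sw <- tryCatch(stats::shapiro.test(values[ok])$p.value, error = function(e) NA_real_)
  if (abs(sk) > threshold) {
    if (any(values[ok] <= 0))
      stop("cannot log-transform: skewness gate fired but values include non-positives")
    list(values = log(values), transformed = TRUE, skewness = sk, shapiro_p = sw)
  } else {
    list(values = values, transformed = FALSE, skewness = sk, shapiro_p = sw)
  }
}

#' Descriptive reference values per DMO
#'
#' For each DMO over its defined weekly values: mean, sample standard
#' deviation, median, 25th and 75th percentiles (same linear
#' interpolation convention as the percentile "maximum"), the number of
#' defined values, the adjusted skewness and a non-normality flag
#' (|skewness| > 2), plus the Shapiro-Wilk p-value.
#'
#' @param x A [DMOExperiment] or a numeric matrix with DMOs as rows.
#' @return A `data.frame` with one row per DMO: `dmo`, `unit`, `n`,
#'   `mean`, `sd`, `median`, `p25`, `p75`, `skewness`, `shapiro_p`,
#'   `non_normal`.
#' @export
summarizeDMOs <- function(x) {
  m <- if (methods::is(x, "DMOExperiment")) dmoMatrix(x) else as.matrix(x)
  if (ncol(m) == 0L) stop("summarizeDMOs() needs a non-empty table")
  units <- dmoUnits()
  rows <- lapply(rownames(m), function(d) {
    v <- m[d, ]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0L)
      return(data.frame(dmo = d, unit = unname(units[d]), n = 0L, mean = NA_real_,
                        sd = NA_real_, median = NA_real_, p25 = NA_real_, p75 = NA_real_,
                        skewness = NA_real_, shapiro_p = NA_real_, non_normal = NA))
    sk <- if (n >= 3) sampleSkewness(v) else NA_real_
    sw <- if (n >= 3 && n <= 5000) tryCatch(stats::shapiro.test(v)$p.value,
                                            error = function(e) NA_real_) else NA_real_
    data.frame(dmo = d, unit = unname(units[d]), n = n, mean = mean(v),
               sd = if (n > 1) stats::sd(v) else NA_real_,
               median = stats::median(v),
               p25 = stats::quantile(v, 0.25, type = 7, names = FALSE),
               p75 = stats::quantile(v, 0.75, type = 7, names = FALSE),
               skewness = sk, shapiro_p = sw,
               non_normal = if (is.na(sk)) NA else abs(sk) > 2)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted two-group comparison (ANCOVA)
#'
#' Fits `y ~ group + covariates` by least squares and reports the
#' p-value of the group term. With a single two-level factor this
#' partial F-test equals the squared-t test on the group coefficient
#' (type-III equivalent). Covariates with zero variance are dropped
#' (the model then reduces exactly to the two-sample t-test); a
#' covariate that is collinear with the group indicator or with other
#' covariates raises an error naming it.
#'
#' @param y Numeric response (possibly transformed by the skewness
#'   gate; group descriptives are reported on the scale supplied in
#'   `yOriginal`).
#' @param group Two-level factor.
#' @param covariates A `data.frame` (or named list) of numeric
#'   covariate vectors; may be empty.
#' @param yOriginal Values used for the reported group means/sds
#'   (defaults to `y`).
#' @return A list: `groups`, `n`, `means`, `sds` (per group, original
#'   scale), `estimate` (adjusted difference, level 2 minus level 1,
#'   model scale), `F`, `df`, `raw_p`, `covariates_used`.
#' @export
ancovaGroupTest <- function(y, group, covariates = NULL, yOriginal = y) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("ancovaGroupTest() needs exactly two groups, got ", nlevels(group))
  covariates <- if (is.null(covariates)) data.frame() else as.data.frame(covariates)
  ok <- !is.na(y) & !is.na(group)
  if (ncol(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- y[ok]; group <- droplevels(group[ok])
  covariates <- covariates[ok, , drop = FALSE]
  yOriginal <- yOriginal[ok]
  if (nlevels(group) != 2L || any(table(group) < 3L))
    stop("ancovaGroupTest() needs at least 3 observations per group")
  dropped <- names(covariates)[vapply(covariates, function(v) stats::var(v) == 0, logical(1))]
  used <- setdiff(names(covariates), dropped)
  X <- cbind(`(Intercept)` = 1, g = as.numeric(group == levels(group)[2]))
  for (cv in used) {
    X2 <- cbind(X, stats::setNames(data.frame(covariates[[cv]]), cv))
    if (qr(as.matrix(X2))$rank < ncol(X2))
      stop("singular design: covariate '", cv, "' is collinear with the group term")
    X <- X2
  }
  df <- data.frame(y = y, group = group, covariates[, used, drop = FALSE])
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  gRow <- grep("^group", rownames(sm))
  tval <- sm[gRow, "t value"]
  rdf <- fit$df.residual
  lv <- levels(group)
  list(groups = lv,
       n = as.integer(table(group)),
       means = vapply(lv, function(g) mean(yOriginal[group == g]), numeric(1)),
       sds = vapply(lv, function(g) stats::sd(yOriginal[group == g]), numeric(1)),
       estimate = unname(sm[gRow, "Estimate"]),
       F = unname(tval^2), df = c(1, rdf),
       raw_p = unname(sm[gRow, "Pr(>|t|)"]),
       covariates_used = used, covariates_dropped = dropped)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `p_i = min_{j: p_(j) >= p_(i)} m p_(j)/j`,
#' capped at 1; monotone in the raw p-values.
#'
#' @param pvalues Numeric vector of p-values between 0 and 1 (`NA` allowed
#'   and propagated).
#' @return The adjusted p-values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(pvalues) {
  bad <- which(!is.na(pvalues) & (pvalues < 0 | pvalues > 1))
  if (length(bad))
    stop("p-value outside [0, 1] at position ", bad[1])
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |F̂x - F̂y|` over the pooled sample with the asymptotic
#' p-value.
#'
#' @param x,y Non-empty numeric vectors.
#' @return A list with `D` and `p`.
#' @export
ksTwoSample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("ksTwoSample() needs two non-empty samples")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Split participants into short and tall within each sex
#'
#' Within each sex, participants at or below the sex-specific median
#' height are labelled `short`, the rest `tall` (ties at the median go
#' to `short`, deterministically).
#'
#' @param participants Demographics `data.frame` with `id`, `sex`,
#'   `height`.
#' @return A factor (levels `short`, `tall`) named by participant id.
#' @export
splitByHeight <- function(participants) {
  out <- rep(NA_character_, nrow(participants))
  for (sx in levels(factor(participants$sex))) {
    i <- which(participants$sex == sx)
    if (!length(i)) next
    med <- stats::median(participants$height[i])
    if (all(participants$height[i] == med))
      warning("all heights equal within sex ", sx, "; every participant labelled 'short'")
    out[i] <- ifelse(participants$height[i] <= med, "short", "tall")
  }
  setNames(factor(out, levels = c("short", "tall")), participants$id)
}

## One FDR family: the 24 DMOs of a single stratum comparison.
.subgroupFamily <- function(mat, keepIds, group, covariates, comparison, stratum,
                            minPerGroup = 3L) {
  rows <- list()
  for (d in rownames(mat)) {
    y0 <- mat[d, keepIds]
    ok <- !is.na(y0) & !is.na(group)
    testable <- length(unique(group[ok])) == 2L && all(table(droplevels(group[ok])) >= minPerGroup)
    gate <- if (sum(ok) >= 3L) tryCatch(skewnessGate(y0[ok]), error = function(e) NULL) else NULL
    transformed <- !is.null(gate) && gate$transformed
    res <- NULL
    if (testable) {
      yTest <- y0
      if (transformed) yTest[ok] <- gate$values
      res <- tryCatch(ancovaGroupTest(yTest[ok], group[ok],
                                      covariates[ok, , drop = FALSE],
                                      yOriginal = y0[ok]),
                      error = function(e) NULL)
      if (is.null(res)) testable <- FALSE
    }
    lv <- levels(group)
    rows[[d]] <- data.frame(
      comparison = comparison, stratum = stratum, dmo = d,
      group1 = lv[1], group2 = lv[2],
      n1 = if (testable) res$n[1] else sum(group[ok] == lv[1]),
      n2 = if (testable) res$n[2] else sum(group[ok] == lv[2]),
      mean1 = if (testable) res$means[1] else NA_real_,
      sd1 = if (testable) res$sds[1] else NA_real_,
      mean2 = if (testable) res$means[2] else NA_real_,
      sd2 = if (testable) res$sds[2] else NA_real_,
      estimate = if (testable) res$estimate else NA_real_,
      transformed = transformed,
      covariates = paste(colnames(covariates), collapse = "+"),
      testable = testable,
      raw_p = if (testable) res$raw_p else NA_real_,
      stringsAsFactors = FALSE)
  }
  fam <- do.call(rbind, rows)
  fam$fdr_p <- NA_real_
  idx <- which(fam$testable)
  fam$fdr_p[idx] <- bhAdjust(fam$raw_p[idx])
  rownames(fam) <- NULL
  fam
}

#' Covariate-adjusted subgroup comparison tables
#'
#' Builds the two families of subgroup comparisons over the weekly DMO
#' table: (a) female vs male within each age group (65-74, 75-84,
#' 85-94), adjusted for height and weight (or height and BMI, see
#' `covariateSet`); (b) short vs tall (sex-specific median height
#' split) within each sex, adjusted for age and weight. Each DMO whose
#' cohort-wide weekly distribution trips the skewness gate is tested on
#' the log scale while group means and sds are always reported on the
#' original scale. Benjamini-Hochberg adjustment is applied across the
#' 24 DMOs within each stratum family; strata with fewer than 3
#' participants per group are flagged untestable and excluded from the
#' family.
#'
#' @param x A [DMOExperiment].
#' @param covariateSet `"height_weight"` (default) or `"height_bmi"`
#'   for the sex comparison.
#' @return A `data.frame` with one row per comparison x stratum x DMO:
#'   group sizes, original-scale means (sd), the adjusted difference,
#'   `transformed` flag, `raw_p` and `fdr_p`.
#' @export
buildSubgroupTables <- function(x, covariateSet = c("height_weight", "height_bmi")) {
  covariateSet <- match.arg(covariateSet)
  stopifnot(methods::is(x, "DMOExperiment"))
  mat <- dmoMatrix(x)
  cd <- as.data.frame(colData(x))
  ag <- ageGroups(cd$age)
  out <- list()
  for (g in levels(ag)) {
    sel <- which(!is.na(ag) & ag == g)
    if (!length(sel)) next
    covs <- if (covariateSet == "height_weight")
      data.frame(height = cd$height[sel], weight = cd$weight[sel])
    else data.frame(height = cd$height[sel], bmi = cd$bmi[sel])
    out[[paste0("sex_", g)]] <- .subgroupFamily(
      mat, keepIds = sel, group = factor(cd$sex[sel], levels = c("F", "M")),
      covariates = covs, comparison = "sex_within_age", stratum = g)
  }
  hs <- splitByHeight(cd)
  for (sx in c("F", "M")) {
    sel <- which(cd$sex == sx)
    if (!length(sel)) next
    out[[paste0("height_", sx)]] <- .subgroupFamily(
      mat, keepIds = sel, group = factor(hs[sel], levels = c("short", "tall")),
      covariates = data.frame(age = cd$age[sel], weight = cd$weight[sel]),
      comparison = "height_within_sex", stratum = sx)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Age-group factor used throughout the analyses
#'
#' Decade bins on integer age: 65-74, 75-84, 85-94. Ages outside
#' 65-94 yield `NA`.
#'
#' @param age Integer ages in years.
#' @return A factor with levels `"65-74"`, `"75-84"`, `"85-94"`.
#' @export
ageGroups <- function(age) {
  cut(age, breaks = c(65, 75, 85, 95), right = FALSE,
      labels = c("65-74", "75-84", "85-94"))
}
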