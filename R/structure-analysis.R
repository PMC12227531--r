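## DMO structure: age-stratified correlation matrices (displayed as
## networks) and principal-axis factor analysis with varimax rotation
## and the 0.4-loading domain-assignment rule.

#' Age-stratified DMO correlation matrices
#'
#' Pearson correlations between the 24 weekly DMOs, computed on
#' pairwise-complete observations within each age group. Age groups
#' with fewer than `minN` participants are omitted with a warning. The
#' a-priori domain of each DMO is attached for block annotation.
#'
#' @param x A [DMOExperiment].
#' @param minN Minimum participants per age group. Default 5.
#' @return A named list (one element per age group) of 24 x 24
#'   correlation matrices, each with attributes `ageGroup`, `n` and
#'   `domains`.
#' @export
correlationByAgeGroup <- function(x, minN = 5L) {
  stopifnot(methods::is(x, "DMOExperiment"))
  mat <- dmoMatrix(x)
  ag <- ageGroups(colData(x)$age)
  out <- list()
  for (g in levels(ag)) {
    sel <- which(!is.na(ag) & ag == g)
    if (length(sel) < minN) {
      warning("age group ", g, " has fewer than ", minN,
              " participants; correlation matrix omitted")
      next
    }
    cm <- stats::cor(t(mat[, sel]), use = "pairwise.complete.obs")
    attr(cm, "ageGroup") <- g
    attr(cm, "n") <- length(sel)
    attr(cm, "domains") <- dmoDomains()
    out[[g]] <- cm
  }
  out
}

## Principal-axis factoring: iterate communalities on the reduced
## correlation matrix, extracting k factors from its leading
## eigenstructure. Written in-package because no installed package
## provides this extraction method.
.principalAxis <- function(R, nFactors, maxIter = 1000L, tol = 1e-5) {
  p <- ncol(R)
  # initial communalities: squared multiple correlations
  h2 <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  h2 <- pmin(pmax(h2, 0.05), 0.995)
  L <- NULL
  for (it in seq_len(maxIter)) {
    Rr <- R
    diag(Rr) <- h2
    eig <- eigen(Rr, symmetric = TRUE)
    ev <- pmax(eig$values[seq_len(nFactors)], 0)
    L <- eig$vectors[, seq_len(nFactors), drop = FALSE] %*% diag(sqrt(ev), nFactors)
    h2new <- pmin(rowSums(L^2), 0.9995)
    if (max(abs(h2new - h2)) < tol) {
      return(list(loadings = L, communalities = h2new, iterations = it, converged = TRUE))
    }
    h2 <- h2new
  }
  list(loadings = L, communalities = h2, iterations = maxIter, converged = FALSE)
}

#' Principal-axis factor model of the weekly DMO table
#'
#' Standardizes the complete-case weekly DMO matrix, extracts
#' `nFactors` factors by principal-axis factoring (iterated
#' communalities) and applies varimax rotation. The proportion of
#' total variance explained by each rotated factor is the sum of its
#' squared loadings divided by the number of DMOs.
#'
#' @param x A [DMOExperiment], or a numeric matrix with variables as
#'   rows (DMO layout) and observations as columns.
#' @param nFactors Number of factors. Default 5.
#' @param maxIter Cap on communality iterations (error past it). Default 1000.
#' @param tol Convergence tolerance on communalities.
#' @return An object of class `dmoFactorModel`: a list with `loadings`
#'   (variables x factors, varimax-rotated, Kaiser-normalized),
#'   `var_prop` (per-factor proportion of total variance, sorted
#'   decreasing), `cum_var`, `communalities`, `n`, `iterations`.
#' @export
fitFactorModel <- function(x, nFactors = 5L, maxIter = 1000L, tol = 1e-5) {
  if (nFactors < 1L) stop("`nFactors` must be at least 1")
  m <- if (methods::is(x, "DMOExperiment")) dmoMatrix(x) else as.matrix(x)
  X <- t(m)  # observations x variables
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= nFactors * 3L)
    stop("factor analysis needs more than ", nFactors * 3L,
         " complete cases, got ", nrow(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant DMO column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  R <- stats::cor(X)
  pa <- .principalAxis(R, nFactors, maxIter = maxIter, tol = tol)
  if (!pa$converged)
    stop("principal-axis communality iteration did not converge within ",
         maxIter, " iterations")
  L <- pa$loadings
  if (nFactors > 1L) {
    vr <- stats::varimax(L, normalize = TRUE)
    L <- unclass(vr$loadings)
  }
  rownames(L) <- colnames(X)
  varProp <- colSums(L^2) / ncol(X)
  ord <- order(varProp, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  varProp <- varProp[ord]
  colnames(L) <- paste0("F", seq_len(nFactors))
  names(varProp) <- colnames(L)
  structure(list(loadings = L, var_prop = varProp,
                 cum_var = sum(varProp),
                 communalities = setNames(pa$communalities, colnames(X)),
                 n = nrow(X), iterations = pa$iterations),
            class = "dmoFactorModel")
}

#' @export
print.dmoFactorModel <- function(x, ...) {
  cat(sprintf("Principal-axis factor model: %d variables, %d factors, n = %d\n",
              nrow(x$loadings), ncol(x$loadings), x$n))
  cat(sprintf("  variance explained: %s (cumulative %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$var_prop), collapse = ", "),
              100 * x$cum_var))
  invisible(x)
}

#' Assign DMOs to factors by the loading-threshold rule
#'
#' Each variable is assigned to the factor on which it has the largest
#' absolute rotated loading, provided that absolute loading exceeds
#' `threshold`; otherwise it stays unassigned. Absolute loadings are
#' used so that inversely related measures (e.g. stride duration vs
#' cadence) land in the same domain.
#'
#' @param model A `dmoFactorModel`.
#' @param threshold Minimum absolute loading. Default 0.4.
#' @return A `data.frame` with columns `dmo`, `factor` (`NA` when
#'   unassigned), `loading` (signed loading on the chosen factor) and
#'   `assigned`.
#' @export
assignDmoDomains <- function(model, threshold = 0.4) {
  stopifnot(inherits(model, "dmoFactorModel"))
  L <- model$loadings
  best <- apply(abs(L), 1, which.max)
  bestLoad <- L[cbind(seq_len(nrow(L)), best)]
  assigned <- abs(bestLoad) > threshold
  data.frame(dmo = rownames(L),
             factor = ifelse(assigned, colnames(L)[best], NA_character_),
             loading = bestLoad,
             assigned = assigned,
             stringsAsFactors = FALSE)
}
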