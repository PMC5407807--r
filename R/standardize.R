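#' @include AllClasses.R AllGenerics.R
NULL

#' Natural-log transform of BMI
#'
#' BMI distributions are right-skewed, so all BMI analyses operate on
#' ln BMI. Alongside the transform, a Shapiro-Wilk statistic on the raw
#' input is attached as a diagnostic (computed on at most 5000 values,
#' the test's implementation limit); it gates nothing. The subsample is
#' a deterministic quantile grid, so repeated calls agree exactly.
#'
#' @param bmi Numeric BMI values in kg/m^2, all > 0.
#' @return `log(bmi)`, with attribute `"shapiro"` carrying the
#'   Shapiro-Wilk `statistic` and `p.value` of the untransformed input.
#' @examples
#' lnBMI(c(25, 30))        # log(25), log(30)
#' log(25) - log(30)       # the -0.182 step used for the 30 -> 25 move
#' @export
lnBMI <- function(bmi) {
  if (any(is.na(bmi))) stop("BMI contains missing values")
  if (any(bmi <= 0)) stop("BMI must be strictly positive")
  out <- log(bmi)
  sw <- tryCatch({
    v <- bmi
    if (length(v) > 5000) {
      ## deterministic quantile subsample (Shapiro-Wilk caps at n = 5000;
      ## avoids touching the global RNG stream mid-pipeline)
      v <- sort(v)[round(seq(1, length(v), length.out = 5000))]
    }
    if (length(v) >= 3 && stats::sd(v) > 0)
      stats::shapiro.test(v)[c("statistic", "p.value")]
    else NULL
  }, error = function(e) NULL)
  attr(out, "shapiro") <- sw
  out
}

#' Covariate-adjusted Z-score standardization
#'
#' Regresses a (possibly ln-transformed) phenotype on an adjustment set
#' by ordinary least squares and returns the residuals scaled to unit
#' variance -- the working scale of every association and IV analysis
#' here. Character/factor covariates (site, cohort) enter as categorical
#' indicators; numeric covariates as linear terms. Individuals with a
#' missing phenotype or covariate are dropped from the fit (complete
#' case) and carry `NA` in the result.
#'
#' @param values Numeric phenotype vector, or the name of a column in
#'   `data`.
#' @param data A `data.frame`/`DataFrame` of covariates (e.g.
#'   `phenotypes(cohort)`), required when `adjustmentSet` is non-empty.
#' @param adjustmentSet Character vector of covariate column names; empty
#'   for a plain Z-score.
#' @param logTransform Apply [lnBMI()]-style natural log first.
#' @param phenotypeName Label stored on the result.
#' @return A [StandardizedPhenotype-class]; its `zValues` have mean 0 and
#'   SD 1 over non-missing individuals and are orthogonal to every
#'   adjustment covariate.
#' @examples
#' specs <- simulateVariants(5, 2, c(0.02, 0.02), seed = 3)
#' params <- structuralParams(cohortProfiles = defaultCohortProfiles()[1, ])
#' x <- simulateCohort(specs, n = 300, params = params, cohort = "GOOD")
#' z <- standardizePhenotype("bmi", data = phenotypes(x),
#'                           adjustmentSet = c("age", "smoking"),
#'                           logTransform = TRUE)
#' z
#' @export
standardizePhenotype <- function(values, data = NULL,
                                 adjustmentSet = character(),
                                 logTransform = FALSE,
                                 phenotypeName = NULL) {
  if (is.character(values) && length(values) == 1) {
    if (is.null(data) || !values %in% colnames(data))
      stop("phenotype column '", values, "' not found in data")
    if (is.null(phenotypeName)) phenotypeName <- values
    values <- as.numeric(data[[values]])
  }
  if (is.null(phenotypeName)) phenotypeName <- "phenotype"
  transform <- "none"
  if (logTransform) {
    ok <- !is.na(values)
    if (any(values[ok] <= 0))
      stop("cannot ln-transform non-positive phenotype values")
    values[ok] <- log(values[ok])
    transform <- "natural_log"
  }
  n <- length(values)
  ids <- if (!is.null(data) && !is.null(rownames(data))) rownames(data)
         else names(values)
  z <- rep(NA_real_, n)

  if (length(adjustmentSet)) {
    if (is.null(data)) stop("adjustmentSet given but no data")
    miss <- setdiff(adjustmentSet, colnames(data))
    if (length(miss))
      stop("adjustment covariates not in data: ",
           paste(miss, collapse = ", "))
    df <- as.data.frame(data[, adjustmentSet, drop = FALSE])
    ## drop covariates constant in the analysis sample (e.g. a single
    ## cohort's own label) rather than fail on a zero-variance column
    keep <- vapply(df, function(v) length(unique(v[!is.na(v)])) > 1,
                   logical(1))
    df <- df[, keep, drop = FALSE]
    cc <- stats::complete.cases(df) & !is.na(values)
    if (sum(cc) <= ncol(df) + 2)
      stop("too few complete cases for the adjustment set")
    if (ncol(df)) {
      mm <- stats::model.matrix(~ ., data = df[cc, , drop = FALSE])
      qrm <- qr(mm)
      if (qrm$rank < ncol(mm)) {
        aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
        stop("rank-deficient adjustment set; collinear column(s): ",
             paste(aliased, collapse = ", "))
      }
      res <- qr.resid(qrm, values[cc])
    } else {
      res <- values[cc] - mean(values[cc])
    }
  } else {
    cc <- !is.na(values)
    if (sum(cc) < 3) stop("too few non-missing values")
    res <- values[cc] - mean(values[cc])
  }
  sdr <- sqrt(sum(res^2) / (sum(cc) - 1))
  if (sdr < 1e-10)
    stop("degenerate fit: phenotype is (numerically) fully explained by ",
         "the adjustment set")
  z[cc] <- res / sdr
  ## residuals already have mean ~0; remove floating-point drift so the
  ## class invariant holds exactly
  z[cc] <- (z[cc] - mean(z[cc]))
  z[cc] <- z[cc] / sqrt(sum(z[cc]^2) / (sum(cc) - 1))
  if (!is.null(ids)) names(z) <- ids
  new("StandardizedPhenotype", zValues = z,
      phenotypeName = phenotypeName,
      adjustmentSet = as.character(adjustmentSet),
      transform = transform)
}
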