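#' @include AllClasses.R AllGenerics.R diagnostics.R
NULL

.Z95 <- stats::qnorm(0.975)

.ivResult <- function(ratio, se, p = NULL, method, direction, adjustment,
                      instrument, firstStageF = NA_real_, n = NA_integer_,
                      ciLow = NULL, ciHigh = NULL) {
  if (is.null(p))
    p <- if (se > 0) 2 * stats::pnorm(-abs(ratio) / se) else 1
  if (is.null(ciLow)) ciLow <- ratio - .Z95 * se
  if (is.null(ciHigh)) ciHigh <- ratio + .Z95 * se
  new("IVResult", ratio = ratio, se = se, ciLow = ciLow, ciHigh = ciHigh,
      p = max(p, .Machine$double.xmin), method = method,
      direction = direction, adjustment = as.character(adjustment),
      instrument = instrument, firstStageF = firstStageF,
      n = as.integer(n))
}

#' Wald (IV) ratio from two association summaries
#'
#' The instrument-outcome association divided by the
#' instrument-exposure association: a consistent causal-effect estimator
#' under the IV assumptions. The standard error is the first-order delta
#' method, `|ratio| * sqrt((se_out/beta_out)^2 + (se_exp/beta_exp)^2)`,
#' with the `beta_out = 0` case handled as `se_out / |beta_exp|`;
#' numerator and denominator are treated as independent. Confidence
#' limits and p-value use the normal approximation (adequate for strong
#' instruments); Fieller limits are available behind `ci = "fieller"`.
#'
#' @param assocOutcome [AssocResult-class] (or list with `beta`, `se`)
#'   of the score with the *outcome*.
#' @param assocExposure [AssocResult-class] of the score with the
#'   *intermediate (exposure) trait*; its `beta` must be non-zero.
#' @param direction `"bmi_to_t"` or `"t_to_bmi"`; fixes the unit label.
#' @param instrument Instrument name carried on the result.
#' @param ci `"delta"` (default) or `"fieller"`.
#' @return An [IVResult-class] with `method = "wald_ratio"`.
#' @examples
#' ## reproduce a published-style ratio from printed coefficients
#' out <- new("AssocResult", beta = -0.020, se = 0.0204, p = 0.33,
#'            r2 = 0.001, n = 7446L, label = "")
#' exp <- new("AssocResult", beta = -0.281, se = 0.0199, p = 1e-44,
#'            r2 = 0.025, n = 7446L, label = "")
#' round(estimate(waldRatio(out, exp, direction = "t_to_bmi")), 2)  # 0.07
#' @export
waldRatio <- function(assocOutcome, assocExposure,
                      direction = c("bmi_to_t", "t_to_bmi"),
                      instrument = "GRS", ci = c("delta", "fieller")) {
  direction <- match.arg(direction)
  ci <- match.arg(ci)
  bo <- estimate(assocOutcome); so <- stdError(assocOutcome)
  be <- estimate(assocExposure); se_ <- stdError(assocExposure)
  if (be == 0)
    stop("weak instrument: zero association with the exposure")
  ratio <- bo / be
  seR <- if (bo == 0) so / abs(be)
         else abs(ratio) * sqrt((so / bo)^2 + (se_ / be)^2)
  res <- .ivResult(ratio, seR, method = "wald_ratio",
                   direction = direction, adjustment = character(),
                   instrument = instrument,
                   n = if (is(assocOutcome, "AssocResult"))
                     sampleSize(assocOutcome) else NA_integer_)
  if (ci == "fieller") {
    z2 <- .Z95^2
    A <- be^2 - z2 * se_^2
    B <- -2 * bo * be
    C <- bo^2 - z2 * so^2
    disc <- B^2 - 4 * A * C
    if (A > 0 && disc >= 0) {
      rts <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
      res@ciLow <- rts[1]; res@ciHigh <- rts[2]
    } else {
      warning("Fieller interval unbounded (weak instrument); ",
              "keeping delta-method limits")
    }
  }
  res
}

.alignFrame <- function(...) {
  vs <- list(...)
  vs <- vs[!vapply(vs, is.null, logical(1))]
  nms <- lapply(vs, names)
  named <- !vapply(nms, is.null, logical(1))
  if (all(named)) {
    common <- Reduce(intersect, nms)
    if (!length(common)) stop("no overlapping individuals")
    vs <- lapply(vs, function(v) v[common])
  } else if (length(unique(lengths(vs))) != 1) {
    stop("inputs cover different numbers of individuals and share no ids")
  }
  do.call(cbind, lapply(vs, unname))
}

.asCovMatrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  if (is(covariates, "StandardizedPhenotype"))
    covariates <- list(adj = zValues(covariates))
  if (is.numeric(covariates)) covariates <- list(adj = covariates)
  if (is.data.frame(covariates) || is(covariates, "DataFrame"))
    covariates <- as.list(as.data.frame(covariates))
  lapply(covariates, .asNumericInput)
}

#' Two-stage least squares IV estimation
#'
#' Stage one regresses the exposure Z-score on the instrument (plus any
#' extra covariates); stage two regresses the outcome Z-score on the
#' fitted exposure (plus the same covariates). The coefficient on the
#' fitted exposure is the causal estimate; its standard error uses the
#' proper 2SLS variance (residuals formed with the *observed* exposure,
#' so the generated-regressor correction is built in, homoskedastic
#' classical form). With a single instrument and no covariates the point
#' estimate equals the Wald ratio identically.
#'
#' The first-stage partial F of the instrument is reported; below
#' `fFloor` (default 10) a weak-instrument warning is raised, and below
#' 1 the fit is refused.
#'
#' @param score Instrument: a [RiskScore-class] or numeric vector.
#' @param exposure,outcome [StandardizedPhenotype-class] objects (or
#'   numeric vectors) for the intermediate trait and the outcome.
#' @param covariates Optional extra covariates entering both stages: a
#'   named list / data.frame of numeric vectors, a single vector, or a
#'   `StandardizedPhenotype` (e.g. the SHBG Z-score).
#' @param direction,instrument Labels carried on the result.
#' @param fFloor Weak-instrument warning threshold on the first-stage F.
#' @param robust Use heteroskedasticity-robust (HC0) second-stage
#'   standard errors instead of the classical homoskedastic form.
#' @return An [IVResult-class] with `method = "tsls"`.
#' @export
tsls <- function(score, exposure, outcome, covariates = NULL,
                 direction = c("bmi_to_t", "t_to_bmi"),
                 instrument = "GRS", fFloor = 10, robust = FALSE) {
  direction <- match.arg(direction)
  sv <- .asNumericInput(score)
  ev <- .asNumericInput(exposure)
  ov <- .asNumericInput(outcome)
  covs <- .asCovMatrix(covariates)
  adjNames <- names(covs)
  if (is.null(adjNames)) adjNames <- character()
  M <- do.call(.alignFrame, c(list(sv, ev, ov), covs))
  M <- M[stats::complete.cases(M), , drop = FALSE]
  n <- nrow(M)
  if (n <= 50) stop("need more than 50 complete observations for 2SLS")
  s <- M[, 1]; xE <- M[, 2]; y <- M[, 3]
  C <- if (ncol(M) > 3) M[, -(1:3), drop = FALSE] else NULL

  Zm <- cbind(1, s, C)
  Xm <- cbind(1, xE, C)
  k <- ncol(Xm)
  Zqr <- qr(Zm)
  if (Zqr$rank < ncol(Zm)) stop("collinear instrument/covariate matrix")

  ## first-stage partial F of the instrument
  st1 <- qr.coef(Zqr, xE)
  st1res <- qr.resid(Zqr, xE)
  sig1 <- sum(st1res^2) / (n - ncol(Zm))
  ZtZinv <- chol2inv(qr.R(Zqr))
  seS <- sqrt(sig1 * ZtZinv[2, 2])
  f1 <- (st1[2] / seS)^2
  if (!is.finite(f1) || f1 < 1)
    stop(sprintf("instrument too weak (first-stage F = %.2f < 1)", f1))
  if (f1 < fFloor)
    warning(sprintf("weak instrument: first-stage F = %.1f < %g", f1,
                    fFloor))

  Xhat <- qr.fitted(Zqr, Xm)
  XtPX <- crossprod(Xhat)
  bhat <- solve(XtPX, crossprod(Xhat, y))
  resid <- y - Xm %*% bhat
  if (robust) {
    meat <- crossprod(Xhat * as.vector(resid))
    V <- solve(XtPX, meat) %*% solve(XtPX)
  } else {
    sigma2 <- sum(resid^2) / (n - k)
    V <- sigma2 * solve(XtPX)
  }
  ratio <- bhat[2]
  seR <- sqrt(V[2, 2])
  .ivResult(ratio, seR, method = "tsls", direction = direction,
            adjustment = adjNames, instrument = instrument,
            firstStageF = unname(f1), n = n)
}

#' SHBG- (or testosterone-) conditioned IV estimates
#'
#' Re-runs the two-stage least squares fit with an additional trait
#' Z-score in both stages: the causal effect of BMI on testosterone
#' adjusted for SHBG, or on SHBG adjusted for testosterone. Separating a
#' direct effect from one mediated by the binding protein. When the
#' adjustment phenotype is entirely missing the analysis is skipped
#' (returns `NULL` with a message).
#'
#' @param score Instrument.
#' @param exposure Exposure Z-score.
#' @param outcome Outcome Z-score.
#' @param adjustFor A `StandardizedPhenotype` (or named numeric) added to
#'   both stages, e.g. the SHBG Z-score.
#' @param adjustName Label for the adjustment variable.
#' @param ... Passed to [tsls()].
#' @return An [IVResult-class], or `NULL` when `adjustFor` is all-`NA`.
#' @export
adjustedIV <- function(score, exposure, outcome, adjustFor,
                       adjustName = "SHBG", ...) {
  av <- .asNumericInput(adjustFor)
  if (all(is.na(av))) {
    message("adjustment phenotype '", adjustName,
            "' is entirely missing; analysis skipped")
    return(NULL)
  }
  covs <- stats::setNames(list(av), adjustName)
  tsls(score, exposure, outcome, covariates = covs, ...)
}

#' Independent-instrument pleiotropy split
#'
#' Partitions the instrument variants into two disjoint sub-instruments
#' (canonically: one lead locus versus a weighted score on all remaining
#' variants), estimates the causal effect independently with each, and
#' tests the difference of the two estimates with a two-sample z test on
#' independent standard errors. Similar point estimates (difference
#' p > alpha) argue against pleiotropy driving the combined estimate.
#'
#' @param x A harmonized [MRCohort-class] (or combined cohort).
#' @param partition List of two non-overlapping character vectors of
#'   rsIDs that together cover the trait's variants.
#' @param exposure,outcome Z-scores as in [tsls()].
#' @param trait Trait whose variants are split, default
#'   `"bmi_increasing"`.
#' @param covariates,direction Passed to [tsls()].
#' @return A list: `iv1`, `iv2` ([IVResult-class] per side), `zDiff`,
#'   `differenceP`, and `consistent` (difference p > 0.05).
#' @export
instrumentSplit <- function(x, partition, exposure, outcome,
                            trait = "bmi_increasing", covariates = NULL,
                            direction = c("bmi_to_t", "t_to_bmi")) {
  direction <- match.arg(direction)
  stopifnot(is(x, "MRCohort"), is.list(partition),
            length(partition) == 2)
  sp <- rowData(x)
  traitIds <- sp$rsid[sp$trait == trait]
  p1 <- partition[[1]]; p2 <- partition[[2]]
  if (!length(p1) || !length(p2))
    stop("both partition sides must be non-empty")
  if (length(intersect(p1, p2)))
    stop("partition sides overlap")
  if (!setequal(c(p1, p2), traitIds))
    stop("partition must cover exactly the '", trait, "' variants")
  ivs <- lapply(list(p1, p2), function(ids) {
    sc <- weightedScore(x, trait = trait,
                        specs = sp[sp$rsid %in% ids, , drop = FALSE])
    tsls(sc, exposure, outcome, covariates = covariates,
         direction = direction,
         instrument = if (length(ids) == 1) ids else
           sprintf("wGRS[%d variants]", length(ids)))
  })
  zd <- (estimate(ivs[[1]]) - estimate(ivs[[2]])) /
    sqrt(stdError(ivs[[1]])^2 + stdError(ivs[[2]])^2)
  pd <- 2 * stats::pnorm(-abs(zd))
  list(iv1 = ivs[[1]], iv2 = ivs[[2]], zDiff = zd, differenceP = pd,
       consistent = pd > 0.05)
}

#' Observational-versus-IV comparison (Hausman-type)
#'
#' Tests whether the confounded observational slope and the IV estimate
#' differ: `z = (beta_obs - ratio) / sqrt(se_iv^2 - se_obs^2)`, the
#' classic efficient-versus-consistent variance difference. The variance
#' difference is floored at `se_iv^2 * 1e-6`; when it falls below the
#' floor (IV nominally more precise than OLS, a finite-sample boundary
#' case) the p-value is computed on the floored variance with a warning.
#'
#' @param assocObs [AssocResult-class]: the observational
#'   exposure-outcome slope on the same standardized scale.
#' @param iv [IVResult-class] for the same pair.
#' @return Two-sided p-value; equality of estimates gives exactly 1.
#' @export
obsVsIV <- function(assocObs, iv) {
  bo <- estimate(assocObs); so <- stdError(assocObs)
  ri <- estimate(iv); si <- stdError(iv)
  floorv <- si^2 * 1e-6
  v <- si^2 - so^2
  if (v < floorv) {
    warning("IV variance not larger than observational variance; ",
            "p computed on floored variance difference")
    v <- floorv
  }
  if (bo == ri) return(1)
  2 * stats::pnorm(-abs(bo - ri) / sqrt(v))
}

#' Translate a standardized IV ratio into percent change in testosterone
#'
#' Chains the exact unit conversions: the ratio (SD testosterone per SD
#' ln BMI) times `SD(T)/SD(ln BMI)` gives ng/ml per unit ln BMI;
#' times `ln(bmiTo) - ln(bmiFrom)` gives the testosterone difference for
#' the BMI move; divided by the predicted testosterone at `bmiFrom` and
#' scaled by 100 gives the percent change. No approximation is involved.
#'
#' @param iv An [IVResult-class] in the BMI-to-testosterone direction,
#'   or a bare numeric ratio.
#' @param sdT SD of serum testosterone, ng/ml (> 0).
#' @param sdLogBmi SD of ln BMI, unitless (> 0).
#' @param tPredAtFrom Predicted testosterone at `bmiFrom`, ng/ml (> 0);
#'   see [predictedTestosterone()].
#' @param bmiFrom,bmiTo BMI endpoints in kg/m^2 (> 0); default the
#'   obesity and overweight cut-offs 30 and 25.
#' @return A [TranslationResult-class].
#' @examples
#' translateToPercent(-0.25, sdT = 1.6, sdLogBmi = 0.148,
#'                    tPredAtFrom = 4.2)
#' @export
translateToPercent <- function(iv, sdT, sdLogBmi, tPredAtFrom,
                               bmiFrom = 30, bmiTo = 25) {
  ratio <- if (is(iv, "IVResult")) estimate(iv) else as.numeric(iv)
  if (is(iv, "IVResult") && iv@direction != "bmi_to_t")
    stop("translation requires a BMI-to-testosterone direction ratio")
  if (sdT <= 0 || sdLogBmi <= 0 || tPredAtFrom <= 0 ||
      bmiFrom <= 0 || bmiTo <= 0)
    stop("all SDs, predicted testosterone and BMI endpoints must be > 0")
  pct <- 100 * ratio * (sdT / sdLogBmi) * (log(bmiTo) - log(bmiFrom)) /
    tPredAtFrom
  new("TranslationResult", percentChange = pct, bmiFrom = bmiFrom,
      bmiTo = bmiTo, ratio = ratio, sdT = sdT, sdLogBmi = sdLogBmi,
      tPredAtFrom = tPredAtFrom)
}

#' Predicted testosterone at a given BMI
#'
#' Pooled OLS of raw testosterone on ln BMI plus an adjustment set, with
#' every covariate held at its sample mean: since the model is linear,
#' the prediction reduces to `mean(T) + b_lnBMI * (ln(bmiAt) -
#' mean(ln BMI))` over the complete-case sample.
#'
#' @param data A `data.frame`/`DataFrame` with columns `testosterone`,
#'   `bmi` and the adjustment covariates, or an [MRCohort-class].
#' @param bmiAt BMI (kg/m^2) at which to predict.
#' @param adjustmentSet Covariates in the prediction model; defaults to
#'   age, smoking, sampling time and cohort where present.
#' @return Predicted testosterone in ng/ml.
#' @export
predictedTestosterone <- function(data, bmiAt = 30,
                                  adjustmentSet = c("age", "smoking",
                                                    "samplingTime",
                                                    "cohort")) {
  if (is(data, "MRCohort")) data <- phenotypes(data)
  df <- as.data.frame(data)
  adjustmentSet <- intersect(adjustmentSet, colnames(df))
  df$lnbmi <- log(df$bmi)
  use <- c("testosterone", "lnbmi", adjustmentSet)
  df <- df[stats::complete.cases(df[, use]), use, drop = FALSE]
  keep <- vapply(df[, -1, drop = FALSE],
                 function(v) length(unique(v)) > 1, logical(1))
  form <- stats::reformulate(c("lnbmi", adjustmentSet)[c(TRUE, keep[-1])],
                             response = "testosterone")
  fit <- stats::lm(form, data = df)
  unname(mean(df$testosterone) +
           stats::coef(fit)["lnbmi"] * (log(bmiAt) - mean(df$lnbmi)))
}
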