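#' @include AllClasses.R AllGenerics.R
NULL

.metaCore <- function(betas, ses, tau2, model) {
  k <- length(betas)
  wFix <- 1 / ses^2
  pooledFix <- sum(wFix * betas) / sum(wFix)
  Q <- sum(wFix * (betas - pooledFix)^2)
  qP <- if (k > 1) stats::pchisq(Q, df = k - 1, lower.tail = FALSE) else 1
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  w <- 1 / (ses^2 + tau2)
  pooled <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  p <- 2 * stats::pnorm(-abs(pooled) / se)
  new("MetaResult", pooledBeta = pooled, se = se,
      ciLow = pooled - .Z95 * se, ciHigh = pooled + .Z95 * se,
      p = max(p, .Machine$double.xmin), qStat = Q, qP = qP,
      iSquared = i2, tauSquared = tau2, model = model, k = as.integer(k))
}

.checkMetaInput <- function(betas, ses, kMin) {
  if (length(betas) != length(ses))
    stop("betas and ses must have equal length")
  if (length(betas) < kMin)
    stop("need at least ", kMin, " studies")
  if (any(!is.finite(betas)) || any(!is.finite(ses)) || any(ses <= 0))
    stop("estimates must be finite with ses > 0")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines per-cohort estimates with weights `1/se^2`. Reports
#' Cochran's Q, its p-value and `I^2 = max(0, (Q - (k-1))/Q) * 100`.
#'
#' @param betas Per-study estimates.
#' @param ses Their standard errors (> 0).
#' @return A [MetaResult-class] with `model = "fixed"` and
#'   `tauSquared = 0`.
#' @examples
#' fixedMeta(c(1, 3), c(1, 1))  # pooled 2, Q = 2, I^2 = 50%
#' @export
fixedMeta <- function(betas, ses) {
  .checkMetaInput(betas, ses, 1)
  .metaCore(betas, ses, tau2 = 0, model = "fixed")
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/se^2`, then inverse-variance pooling with
#' weights `1/(se^2 + tau^2)`. When `Q <= k - 1`, `tau^2 = 0` and the
#' result coincides with the fixed-effect analysis exactly.
#'
#' @inheritParams fixedMeta
#' @return A [MetaResult-class] with `model = "random"`.
#' @export
randomMeta <- function(betas, ses) {
  .checkMetaInput(betas, ses, 2)
  k <- length(betas)
  w <- 1 / ses^2
  pooledFix <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooledFix)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  .metaCore(betas, ses, tau2 = tau2, model = "random")
}

#' Heterogeneity-guided model selection
#'
#' Runs the Q test for heterogeneity; when `q_p < alpha` the
#' DerSimonian-Laird random-effects model is returned, otherwise the
#' fixed-effect model -- the decision rule of combining cohorts only
#' when they estimate a common effect.
#'
#' @inheritParams fixedMeta
#' @param alpha Level of the Q test, default 0.05.
#' @return A [MetaResult-class]; inspect `@model` for the decision.
#' @export
modelSelect <- function(betas, ses, alpha = 0.05) {
  .checkMetaInput(betas, ses, 1)
  fix <- fixedMeta(betas, ses)
  if (length(betas) >= 2 && fix@qP < alpha) randomMeta(betas, ses)
  else fix
}

#' Combine cohorts into one pooled individual-level data set
#'
#' Concatenates the individuals of several cohorts over the variants all
#' of them share (the intersection; dropped variants are messaged). The
#' result carries the cohort label per individual, so pooled analyses
#' can absorb site differences with cohort indicators.
#'
#' @param cohorts Named list of [MRCohort-class] objects with
#'   harmonizable variant sets.
#' @return One [MRCohort-class] spanning all individuals.
#' @export
combineCohorts <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  if (length(cohorts) == 1) return(cohorts[[1]])
  cohorts <- lapply(cohorts, harmonizeDosages)
  common <- Reduce(intersect, lapply(cohorts, rownames))
  if (!length(common)) stop("cohorts share no variants")
  total <- sum(vapply(cohorts, nrow, integer(1)))
  if (length(common) < max(vapply(cohorts, nrow, integer(1))))
    message("pooling on ", length(common),
            " shared variants (intersection across cohorts)")
  parts <- lapply(cohorts, function(co) co[common, ])
  g <- do.call(cbind, lapply(parts, function(co) assay(co, "dosage")))
  ph <- do.call(rbind, lapply(parts, function(co)
    as.data.frame(phenotypes(co))))
  MRCohort(t(g), rowData(parts[[1]]), ph, cohort = "pooled")
}

#' Pooled individual-level analysis
#'
#' The pooled counterpart of the meta-analytic combination: concatenates
#' the cohorts ([combineCohorts()]), standardizes both traits over the
#' pooled sample with cohort indicators in the adjustment set, and runs
#' either the score-trait association or the two-stage least squares IV
#' fit on the pooled data.
#'
#' @param cohorts Named list of [MRCohort-class] objects.
#' @param type `"iv"` (default) or `"association"`.
#' @param direction `"bmi_to_t"` or `"t_to_bmi"`.
#' @param weighted Use the weighted (default) or unweighted score.
#' @param adjustFor Optional extra adjustment: `"shbg"` or
#'   `"testosterone"` Z-score added to both IV stages.
#' @return An [IVResult-class] (`type = "iv"`) or [AssocResult-class].
#' @export
pooledAnalysis <- function(cohorts, type = c("iv", "association"),
                           direction = c("bmi_to_t", "t_to_bmi"),
                           weighted = TRUE, adjustFor = NULL) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  pooled <- combineCohorts(cohorts)
  ph <- phenotypes(pooled)
  zBmi <- standardizePhenotype("bmi", ph,
                               adjustmentSet = c("age", "smoking",
                                                 "cohort"),
                               logTransform = TRUE,
                               phenotypeName = "lnBMI")
  zT <- standardizePhenotype("testosterone", ph,
                             adjustmentSet = c("age", "smoking",
                                               "cohort", "samplingTime"))
  scoreTrait <- if (direction == "bmi_to_t") "bmi_increasing"
                else "t_decreasing"
  sc <- if (weighted) weightedScore(pooled, scoreTrait)
        else unweightedScore(pooled, scoreTrait)
  expos <- if (direction == "bmi_to_t") zBmi else zT
  outc <- if (direction == "bmi_to_t") zT else zBmi
  inst <- paste0(if (weighted) "w" else "uw", "GRS_",
                 if (direction == "bmi_to_t") "BMI" else "T")
  if (type == "association") return(associate(sc, outc))
  covs <- NULL
  if (!is.null(adjustFor)) {
    zAdj <- standardizePhenotype(adjustFor, ph,
                                 adjustmentSet = c("age", "smoking",
                                                   "cohort",
                                                   "samplingTime"))
    covs <- stats::setNames(list(zValues(zAdj)), adjustFor)
  }
  tsls(sc, expos, outc, covariates = covs, direction = direction,
       instrument = inst)
}
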