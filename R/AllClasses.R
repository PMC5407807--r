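#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData rowData<- assay<-
NULL

.CHROM_CLASSES <- c("autosomal", "x_male")
.TRAITS <- c("bmi_increasing", "t_decreasing")
.NUCLEOTIDES <- c("A", "C", "G", "T")

## maximum dosage per chromosome class: 2 copies autosomal, 1 for
## X-linked variants in males (hemizygous)
.ploidy <- function(chromClass) ifelse(chromClass == "x_male", 1, 2)

# ---------------------------------------------------------------------------
# MRCohort: dosage + phenotype container
# ---------------------------------------------------------------------------

#' MRCohort: genotype dosages and phenotypes for one cohort
#'
#' An `MRCohort` couples an instrument-variant dosage matrix with the
#' per-individual phenotypes and covariates used in Mendelian randomization
#' of BMI and serum testosterone. It extends
#' [SummarizedExperiment::SummarizedExperiment] with variants as rows and
#' individuals as columns: the `"dosage"` assay holds effect-allele copy
#' numbers (in `[0, 2]` for autosomal variants, `[0, 1]` for X-linked
#' variants in males, `NA` allowed), `rowData` the variant annotation
#' (alleles, per-allele weight, effect-allele frequency, target trait and
#' the allele the stored dosage currently counts), and `colData` the
#' phenotype table (BMI in kg/m^2, testosterone in ng/ml, optional SHBG in
#' nmol/l, age, smoking, optional blood-sampling time, cohort label).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [variantSpecs()] for the variant annotation contract,
#'   [simulateCohort()] to generate one, [harmonizeDosages()] for allele
#'   orientation.
#' @export
setClass("MRCohort", contains = "SummarizedExperiment")

.REQUIRED_VARIANT_COLS <- c("rsid", "chromClass", "effectAllele",
                            "otherAllele", "weight", "eaf", "trait",
                            "countedAllele")
.REQUIRED_PHENO_COLS <- c("bmi", "testosterone", "age", "smoking")

.validMRCohort <- function(object) {
  msg <- character()
  rd <- rowData(object)
  cd <- colData(object)
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is missing")
  missR <- setdiff(.REQUIRED_VARIANT_COLS, colnames(rd))
  if (length(missR))
    return(paste("rowData lacks variant columns:",
                 paste(missR, collapse = ", ")))
  missC <- setdiff(.REQUIRED_PHENO_COLS, colnames(cd))
  if (length(missC))
    return(paste("colData lacks phenotype columns:",
                 paste(missC, collapse = ", ")))
  if (!all(rd$chromClass %in% .CHROM_CLASSES))
    msg <- c(msg, "chromClass must be 'autosomal' or 'x_male'")
  if (any(rd$effectAllele == rd$otherAllele))
    msg <- c(msg, "effectAllele must differ from otherAllele")
  ok <- rd$countedAllele == rd$effectAllele |
    rd$countedAllele == rd$otherAllele
  if (!all(ok))
    msg <- c(msg, paste("countedAllele matches neither allele for:",
                        paste(rd$rsid[!ok], collapse = ", ")))
  if (any(rd$eaf <= 0 | rd$eaf >= 1))
    msg <- c(msg, "eaf must lie strictly in (0, 1)")
  if (any(rd$weight < 0))
    msg <- c(msg, "weights must be >= 0 (trait-oriented alleles)")
  g <- assay(object, "dosage")
  lim <- .ploidy(rd$chromClass)
  bad <- sweep(g, 1, lim, ">") | g < 0
  if (any(bad, na.rm = TRUE))
    msg <- c(msg, "dosages outside [0, ploidy] for their chromosome class")
  if (nrow(cd)) {
    if (any(cd$bmi <= 0, na.rm = TRUE)) msg <- c(msg, "bmi must be > 0")
    if (any(cd$testosterone <= 0, na.rm = TRUE))
      msg <- c(msg, "testosterone must be > 0")
    if (any(cd$age <= 0, na.rm = TRUE)) msg <- c(msg, "age must be > 0")
    if (!all(cd$smoking %in% c(0, 1, NA)))
      msg <- c(msg, "smoking must be 0/1")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MRCohort", .validMRCohort)

#' Construct an MRCohort
#'
#' @param dosages Numeric matrix of effect-allele dosages with
#'   *individuals in rows* and *variants in columns* (the layout of the
#'   dosage TSV interchange format); it is transposed into the
#'   features-by-samples orientation internally. Row names are individual
#'   ids, column names rsIDs.
#' @param variants A `DataFrame`/`data.frame` of variant annotation as
#'   produced by [variantSpecs()], one row per dosage column.
#' @param phenotypes A `DataFrame`/`data.frame` with one row per
#'   individual: columns `bmi`, `testosterone`, `age`, `smoking` required;
#'   `shbg`, `samplingTime`, `cohort` optional.
#' @param cohort Cohort label; defaults to the `cohort` column of
#'   `phenotypes` or `"cohort1"`.
#' @return A validated [MRCohort-class] object.
#' @examples
#' specs <- variantSpecs(rsid = c("rs1", "rs2"), chromClass = "autosomal",
#'                       effectAllele = c("A", "C"), otherAllele = c("G", "T"),
#'                       weight = c(0.02, 0.03), eaf = c(0.3, 0.6),
#'                       trait = "bmi_increasing")
#' g <- matrix(c(0, 1, 2, 1), nrow = 2,
#'             dimnames = list(c("id1", "id2"), c("rs1", "rs2")))
#' ph <- data.frame(bmi = c(24, 31), testosterone = c(5.1, 3.9),
#'                  age = c(45, 52), smoking = c(0, 1))
#' MRCohort(g, specs, ph)
#' @export
MRCohort <- function(dosages, variants, phenotypes, cohort = NULL) {
  variants <- .asVariantSpecs(variants)
  if (is.null(dim(dosages)))
    dosages <- matrix(dosages, nrow = 1)
  if (ncol(dosages) != nrow(variants))
    stop("dosages must have one column per variant spec")
  storage.mode(dosages) <- "double"
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$rsid
  if (!identical(colnames(dosages), variants$rsid))
    dosages <- dosages[, variants$rsid, drop = FALSE]
  phenotypes <- DataFrame(phenotypes)
  if (nrow(phenotypes) != nrow(dosages))
    stop("phenotypes must have one row per dosage row (individual)")
  if (is.null(cohort))
    cohort <- if ("cohort" %in% colnames(phenotypes))
      as.character(phenotypes$cohort[1]) else "cohort1"
  if (!"cohort" %in% colnames(phenotypes))
    phenotypes$cohort <- cohort
  ids <- rownames(dosages)
  if (is.null(ids)) ids <- sprintf("%s_%06d", cohort, seq_len(nrow(dosages)))
  rownames(phenotypes) <- ids
  se <- SummarizedExperiment(
    assays = list(dosage = t(dosages)),
    rowData = variants, colData = phenotypes)
  rownames(se) <- variants$rsid
  colnames(se) <- ids
  S4Vectors::metadata(se)$cohort <- cohort
  new("MRCohort", se)
}

#' @rdname accessors
#' @export
setMethod("dosages", "MRCohort", function(x, ...) assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("variants", "MRCohort", function(x, ...) rowData(x))

#' @rdname accessors
#' @export
setMethod("phenotypes", "MRCohort", function(x, ...) colData(x))

#' @rdname accessors
#' @export
setMethod("cohortName", "MRCohort", function(x, ...) {
  cn <- S4Vectors::metadata(x)$cohort
  if (is.null(cn)) as.character(colData(x)$cohort[1]) else cn
})

setMethod("show", "MRCohort", function(object) {
  cat("MRCohort '", cohortName(object), "': ", ncol(object),
      " individuals x ", nrow(object), " variants\n", sep = "")
  tr <- table(rowData(object)$trait)
  cat("  variants by trait:",
      paste(names(tr), tr, sep = "=", collapse = ", "), "\n")
  nm <- sum(is.na(assay(object, "dosage")))
  if (nm) cat("  missing dosage entries:", nm, "\n")
  cat("  phenotypes:", paste(colnames(colData(object)), collapse = ", "),
      "\n")
})

# ---------------------------------------------------------------------------
# Variant specifications
# ---------------------------------------------------------------------------

#' Variant specification table for instrument SNPs
#'
#' Builds the annotation table describing the instrument variants in the
#' orientation convention used throughout the package: the `effectAllele`
#' is the trait-increasing allele for BMI variants and the
#' testosterone-*decreasing* allele for testosterone variants, so all
#' `weight`s are non-negative.
#'
#' @param rsid Character rsIDs (unique).
#' @param chromClass `"autosomal"` or `"x_male"` (X-linked, males carry a
#'   single copy). Recycled.
#' @param effectAllele,otherAllele Single-letter nucleotides; must differ.
#' @param weight Per-allele effect size in SD of the standardized trait
#'   (ln BMI or testosterone Z-score); `>= 0` under the orientation above.
#' @param eaf Effect-allele frequency, strictly in (0, 1).
#' @param trait `"bmi_increasing"` or `"t_decreasing"`. Recycled.
#' @return A `DataFrame` with one row per variant and a `countedAllele`
#'   column initialized to the effect allele.
#' @export
variantSpecs <- function(rsid, chromClass = "autosomal", effectAllele,
                         otherAllele, weight, eaf,
                         trait = "bmi_increasing") {
  n <- length(rsid)
  df <- DataFrame(
    rsid = as.character(rsid),
    chromClass = rep_len(as.character(chromClass), n),
    effectAllele = rep_len(as.character(effectAllele), n),
    otherAllele = rep_len(as.character(otherAllele), n),
    weight = rep_len(as.numeric(weight), n),
    eaf = rep_len(as.numeric(eaf), n),
    trait = rep_len(as.character(trait), n))
  df$countedAllele <- df$effectAllele
  rownames(df) <- df$rsid
  .asVariantSpecs(df)
}

.asVariantSpecs <- function(df) {
  df <- DataFrame(df)
  need <- setdiff(.REQUIRED_VARIANT_COLS, "countedAllele")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("variant table lacks columns: ", paste(miss, collapse = ", "))
  if (!"countedAllele" %in% colnames(df))
    df$countedAllele <- df$effectAllele
  if (anyDuplicated(df$rsid)) stop("duplicated rsid in variant table")
  if (!all(df$chromClass %in% .CHROM_CLASSES))
    stop("chromClass must be one of: ", paste(.CHROM_CLASSES, collapse = ", "))
  if (!all(df$trait %in% .TRAITS))
    stop("trait must be one of: ", paste(.TRAITS, collapse = ", "))
  if (any(df$effectAllele == df$otherAllele))
    stop("effectAllele and otherAllele must differ")
  if (any(df$eaf <= 0 | df$eaf >= 1)) stop("eaf must be in (0, 1)")
  if (any(df$weight < 0)) stop("weights must be >= 0")
  rownames(df) <- df$rsid
  df
}

# ---------------------------------------------------------------------------
# Risk scores and standardized phenotypes
# ---------------------------------------------------------------------------

#' RiskScore: per-individual genetic risk score
#'
#' @slot values Named numeric, one score per individual.
#' @slot weighted Logical; `TRUE` for an effect-size-weighted score.
#' @slot nVariantsUsed Integer per individual: variants contributing.
#' @slot trait Which trait the score instruments.
#' @slot scaleNote Human-readable description of the scale convention.
#' @export
setClass("RiskScore", representation(
  values = "numeric", weighted = "logical", nVariantsUsed = "integer",
  trait = "character", scaleNote = "character"))

setValidity("RiskScore", function(object) {
  if (!all(is.finite(object@values))) return("score values must be finite")
  if (length(object@nVariantsUsed) != length(object@values))
    return("nVariantsUsed must match values in length")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("scoreValues", "RiskScore", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("sampleSize", "RiskScore", function(x, ...) length(x@values))

setMethod("show", "RiskScore", function(object) {
  cat(if (object@weighted) "Weighted " else "Unweighted ",
      "genetic risk score (", object@trait, "), ",
      length(object@values), " individuals\n", sep = "")
  cat("  mean ", format(mean(object@values), digits = 4), ", SD ",
      format(stats::sd(object@values), digits = 4), "\n", sep = "")
  cat(" ", object@scaleNote, "\n")
})

#' StandardizedPhenotype: covariate-adjusted Z-scores
#'
#' Residuals of a (possibly log-transformed) phenotype on an adjustment
#' set, scaled to unit variance: the working scale of every association
#' and IV estimate in the package.
#'
#' @slot zValues Named numeric; `NA` where covariates were missing.
#' @slot phenotypeName Character.
#' @slot adjustmentSet Covariate names absorbed into the residual.
#' @slot transform `"none"` or `"natural_log"`.
#' @export
setClass("StandardizedPhenotype", representation(
  zValues = "numeric", phenotypeName = "character",
  adjustmentSet = "character", transform = "character"))

setValidity("StandardizedPhenotype", function(object) {
  z <- object@zValues[!is.na(object@zValues)]
  if (length(z) < 2) return("need at least two non-missing z values")
  if (abs(mean(z)) > 1e-8) return("z values must have mean 0")
  sdz <- sqrt(sum(z^2) / (length(z) - 1))
  if (abs(sdz - 1) > 1e-6) return("z values must have SD 1")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("zValues", "StandardizedPhenotype", function(x, ...) x@zValues)

setMethod("show", "StandardizedPhenotype", function(object) {
  cat("Standardized ", object@phenotypeName,
      if (object@transform == "natural_log") " (ln-transformed)" else "",
      ": n = ", sum(!is.na(object@zValues)), "\n", sep = "")
  cat("  adjusted for: ",
      if (length(object@adjustmentSet))
        paste(object@adjustmentSet, collapse = ", ") else "(nothing)",
      "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Result classes
# ---------------------------------------------------------------------------

#' AssocResult: a score-phenotype regression summary
#'
#' @slot beta Slope, in SD of the outcome per unit of predictor.
#' @slot se Standard error of the slope.
#' @slot p Two-sided p-value.
#' @slot r2 Fraction of outcome variance explained by the predictor.
#' @slot n Sample size used.
#' @slot label Description of the fitted pair.
#' @export
setClass("AssocResult", representation(
  beta = "numeric", se = "numeric", p = "numeric", r2 = "numeric",
  n = "integer", label = "character"))

setValidity("AssocResult", function(object) {
  if (object@se <= 0) return("se must be > 0")
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("estimate", "AssocResult", function(x, ...) x@beta)
#' @rdname accessors
#' @export
setMethod("stdError", "AssocResult", function(x, ...) x@se)
#' @rdname accessors
#' @export
setMethod("pValue", "AssocResult", function(x, ...) x@p)
#' @rdname accessors
#' @export
setMethod("rSquared", "AssocResult", function(x, ...) x@r2)
#' @rdname accessors
#' @export
setMethod("sampleSize", "AssocResult", function(x, ...) x@n)
#' @rdname accessors
#' @export
setMethod("confInt", "AssocResult", function(x, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  c(x@beta - zq * x@se, x@beta + zq * x@se)
})

setMethod("show", "AssocResult", function(object) {
  ci <- confInt(object)
  cat("Association", if (nzchar(object@label)) paste0("[", object@label, "]"),
      "\n")
  cat(sprintf("  beta = %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              object@beta, ci[1], ci[2], object@p))
  cat(sprintf("  R^2 = %.3g%%, n = %d\n", 100 * object@r2, object@n))
})

#' IVResult: an instrumental-variable causal estimate
#'
#' @slot ratio Causal estimate in SD of the outcome per SD of the
#'   exposure (SD testosterone per SD ln BMI for the BMI-to-testosterone
#'   direction; SD ln BMI per SD testosterone for the reverse).
#' @slot se Delta-method / 2SLS standard error.
#' @slot ciLow,ciHigh 95 percent confidence limits.
#' @slot p Two-sided p-value.
#' @slot method `"wald_ratio"` or `"tsls"`.
#' @slot direction `"bmi_to_t"` or `"t_to_bmi"`.
#' @slot adjustment Extra covariates conditioned on in both stages.
#' @slot instrument Name of the instrument used.
#' @slot firstStageF First-stage F statistic (`NA` for a Wald ratio
#'   computed from summary associations).
#' @slot n Sample size (`NA` when unknown).
#' @export
setClass("IVResult", representation(
  ratio = "numeric", se = "numeric", ciLow = "numeric", ciHigh = "numeric",
  p = "numeric", method = "character", direction = "character",
  adjustment = "character", instrument = "character",
  firstStageF = "numeric", n = "integer"))

setValidity("IVResult", function(object) {
  if (!(object@ciLow <= object@ratio && object@ratio <= object@ciHigh))
    return("confidence interval must bracket the ratio")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  if (!object@method %in% c("wald_ratio", "tsls"))
    return("method must be 'wald_ratio' or 'tsls'")
  if (!object@direction %in% c("bmi_to_t", "t_to_bmi"))
    return("direction must be 'bmi_to_t' or 't_to_bmi'")
  TRUE
})

#' Unit label for an IV estimate's direction
#' @param x An `IVResult`.
#' @return Character scalar naming the units of the ratio.
#' @export
ivUnits <- function(x) {
  stopifnot(is(x, "IVResult"))
  if (x@direction == "bmi_to_t")
    "SD testosterone per SD ln-transformed BMI"
  else "SD ln-transformed BMI per SD testosterone"
}

#' @rdname accessors
#' @export
setMethod("estimate", "IVResult", function(x, ...) x@ratio)
#' @rdname accessors
#' @export
setMethod("stdError", "IVResult", function(x, ...) x@se)
#' @rdname accessors
#' @export
setMethod("pValue", "IVResult", function(x, ...) x@p)
#' @rdname accessors
#' @export
setMethod("confInt", "IVResult", function(x, ...) c(x@ciLow, x@ciHigh))
#' @rdname accessors
#' @export
setMethod("sampleSize", "IVResult", function(x, ...) x@n)

setMethod("show", "IVResult", function(object) {
  cat("IV estimate (", object@method, ", ",
      sub("_to_", " -> ", object@direction), ") instrument: ",
      object@instrument, "\n", sep = "")
  cat(sprintf("  ratio = %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
              object@ratio, object@ciLow, object@ciHigh, object@p))
  cat("  units:", ivUnits(object), "\n")
  if (length(object@adjustment) && any(nzchar(object@adjustment)))
    cat("  additionally adjusted for:",
        paste(object@adjustment, collapse = ", "), "\n")
  if (is.finite(object@firstStageF))
    cat(sprintf("  first-stage F = %.1f\n", object@firstStageF))
})

#' MetaResult: an inverse-variance meta-analysis summary
#'
#' @slot pooledBeta Combined estimate.
#' @slot se Its standard error.
#' @slot ciLow,ciHigh 95 percent confidence limits.
#' @slot p Two-sided p-value for the pooled estimate.
#' @slot qStat Cochran's Q heterogeneity chi-square.
#' @slot qP Its p-value on k - 1 degrees of freedom.
#' @slot iSquared Percent of variability attributable to heterogeneity.
#' @slot tauSquared Between-study variance (0 under the fixed model).
#' @slot model `"fixed"` or `"random"`.
#' @slot k Number of studies combined.
#' @export
setClass("MetaResult", representation(
  pooledBeta = "numeric", se = "numeric", ciLow = "numeric",
  ciHigh = "numeric", p = "numeric", qStat = "numeric", qP = "numeric",
  iSquared = "numeric", tauSquared = "numeric", model = "character",
  k = "integer"))

setValidity("MetaResult", function(object) {
  if (object@iSquared < 0 || object@iSquared > 100)
    return("I^2 must lie in [0, 100]")
  if (object@tauSquared < 0) return("tau^2 must be >= 0")
  if (object@model == "fixed" && object@tauSquared != 0)
    return("fixed-effect model must have tau^2 = 0")
  if (!(object@ciLow <= object@pooledBeta &&
        object@pooledBeta <= object@ciHigh))
    return("confidence interval must bracket the pooled estimate")
  TRUE
})

#' @rdname accessors
#' @export
setMethod("estimate", "MetaResult", function(x, ...) x@pooledBeta)
#' @rdname accessors
#' @export
setMethod("stdError", "MetaResult", function(x, ...) x@se)
#' @rdname accessors
#' @export
setMethod("pValue", "MetaResult", function(x, ...) x@p)
#' @rdname accessors
#' @export
setMethod("confInt", "MetaResult", function(x, ...) c(x@ciLow, x@ciHigh))

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("%s-effect%s meta-analysis of %d studies\n",
              if (object@model == "fixed") "Fixed" else "Random",
              if (object@model == "random") "s (DerSimonian-Laird)" else "",
              object@k))
  cat(sprintf("  pooled = %.4g (95%% CI %.4g to %.4g), p = %.3g\n",
              object@pooledBeta, object@ciLow, object@ciHigh, object@p))
  cat(sprintf("  Q = %.3g (p = %.3g), I^2 = %.0f%%, tau^2 = %.3g\n",
              object@qStat, object@qP, object@iSquared, object@tauSquared))
})

#' PowerResult: power of an IV regression analysis
#'
#' @slot power Probability of rejecting the null at the stated alpha.
#' @slot n Sample size.
#' @slot r2Instrument Fraction of exposure variance explained by the
#'   instrument.
#' @slot betaTrue Assumed causal effect, SD per SD.
#' @slot alpha Two-sided significance level.
#' @slot method `"analytic"` or `"empirical"`.
#' @export
setClass("PowerResult", representation(
  power = "numeric", n = "numeric", r2Instrument = "numeric",
  betaTrue = "numeric", alpha = "numeric", method = "character"))

setValidity("PowerResult", function(object) {
  if (object@power < 0 || object@power > 1)
    return("power must lie in [0, 1]")
  TRUE
})

setMethod("show", "PowerResult", function(object) {
  cat(sprintf(
    "IV power (%s): %.1f%% at n = %g, instrument R^2 = %.3g%%,\n",
    object@method, 100 * object@power, object@n,
    100 * object@r2Instrument))
  cat(sprintf("  true effect %.3g SD/SD, two-sided alpha = %.3g\n",
              object@betaTrue, object@alpha))
})

#' TranslationResult: causal effect as percent change in testosterone
#'
#' Re-expresses a standardized IV ratio as the percent change in serum
#' testosterone implied by moving BMI between two clinical values.
#'
#' @slot percentChange Percent change in testosterone for the BMI move.
#' @slot bmiFrom,bmiTo BMI endpoints in kg/m^2.
#' @slot ratio The standardized IV ratio translated.
#' @slot sdT SD of testosterone, ng/ml.
#' @slot sdLogBmi SD of ln BMI (unitless).
#' @slot tPredAtFrom Predicted testosterone at `bmiFrom`, ng/ml.
#' @export
setClass("TranslationResult", representation(
  percentChange = "numeric", bmiFrom = "numeric", bmiTo = "numeric",
  ratio = "numeric", sdT = "numeric", sdLogBmi = "numeric",
  tPredAtFrom = "numeric"))

setMethod("show", "TranslationResult", function(object) {
  cat(sprintf(
    "BMI %g -> %g kg/m^2: %+.1f%% change in serum testosterone\n",
    object@bmiFrom, object@bmiTo, object@percentChange))
  cat(sprintf(
    "  (ratio %.3g SD/SD, SD(T) %.3g ng/ml, SD(ln BMI) %.3g, T at BMI %g: %.3g ng/ml)\n",
    object@ratio, object@sdT, object@sdLogBmi, object@bmiFrom,
    object@tPredAtFrom))
})
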