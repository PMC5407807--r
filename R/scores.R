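#' @include AllClasses.R AllGenerics.R
NULL

#' Orient dosages to count the effect allele
#'
#' Mendelian randomization requires every instrument variant's dosage to
#' count the trait-oriented allele (BMI-increasing, testosterone-
#' decreasing). Variants whose stored dosage counts the other allele are
#' flipped (`2 - g`, or `1 - g` for X-linked variants in males) and the
#' `countedAllele` annotation updated. Idempotent: harmonizing an already
#' harmonized object is a no-op. A counted allele matching neither spec
#' allele is rejected (at construction) with the offending variant named.
#'
#' @param x An [MRCohort-class].
#' @param ... Unused.
#' @return An [MRCohort-class] whose dosages all count the effect allele.
#' @examples
#' specs <- simulateVariants(5, 2, c(0.02, 0.02), seed = 3)
#' params <- structuralParams(cohortProfiles = defaultCohortProfiles()[1, ])
#' x <- simulateCohort(specs, n = 100, params = params, cohort = "GOOD")
#' y <- harmonizeDosages(scrambleAlleles(x, seed = 9))
#' identical(dosages(y), dosages(x))
#' @export
#' @name harmonizeDosages
#' @aliases harmonizeDosages,MRCohort-method
setMethod("harmonizeDosages", "MRCohort", function(x, ...) {
  rd <- rowData(x)
  bad <- !(rd$countedAllele == rd$effectAllele |
             rd$countedAllele == rd$otherAllele)
  if (any(bad))
    stop("counted allele matches neither spec allele for variant(s): ",
         paste(rd$rsid[bad], collapse = ", "))
  flip <- rd$countedAllele == rd$otherAllele
  if (any(flip)) {
    g <- assay(x, "dosage")
    lim <- .ploidy(rd$chromClass)
    g[flip, ] <- lim[flip] - g[flip, , drop = FALSE]
    rd$countedAllele[flip] <- rd$effectAllele[flip]
    assay(x, "dosage") <- g
    rowData(x) <- rd
  }
  x
})

.checkHarmonized <- function(x) {
  rd <- rowData(x)
  if (any(rd$countedAllele != rd$effectAllele))
    stop("dosages are not harmonized; run harmonizeDosages() first")
}

## shared engine for both score flavours. Works on the variants of `x`
## whose trait matches; spec variants absent from the matrix are handled
## per absentPolicy, per-individual sporadic NAs per missingPolicy.
.riskScoreEngine <- function(x, trait, weighted,
                             missingPolicy = c("impute_eaf", "omit"),
                             absentPolicy = c("omit", "rescale"),
                             specs = NULL, rescale = TRUE,
                             xDoseScale = c("native", "doubled")) {
  stopifnot(is(x, "MRCohort"))
  missingPolicy <- match.arg(missingPolicy)
  absentPolicy <- match.arg(absentPolicy)
  xDoseScale <- match.arg(xDoseScale)
  .checkHarmonized(x)
  if (is.null(specs)) specs <- rowData(x)
  specs <- .asVariantSpecs(specs)
  specs <- specs[specs$trait == trait, , drop = FALSE]
  if (!nrow(specs)) stop("no variants with trait '", trait, "' in spec")
  present <- specs$rsid %in% rownames(x)
  nTotal <- nrow(specs)
  specs <- specs[present, , drop = FALSE]
  if (!nrow(specs)) stop("none of the spec variants present in the matrix")

  g <- assay(x, "dosage")[specs$rsid, , drop = FALSE]
  if (xDoseScale == "doubled") {
    xm <- specs$chromClass == "x_male"
    g[xm, ] <- 2 * g[xm, , drop = FALSE]
  }
  w <- if (weighted) specs$weight else rep(1, nrow(specs))
  if (weighted && all(w == 0)) stop("all-zero weights")

  nUsed <- colSums(!is.na(g))
  if (missingPolicy == "impute_eaf") {
    exp_g <- .ploidy(specs$chromClass) * specs$eaf
    if (xDoseScale == "doubled")
      exp_g[specs$chromClass == "x_male"] <-
        2 * specs$eaf[specs$chromClass == "x_male"]
    idx <- which(is.na(g))
    if (length(idx)) g[idx] <- exp_g[(idx - 1) %% nrow(g) + 1]
    nUsed <- rep.int(nrow(g), ncol(g))
  } else {
    g[is.na(g)] <- 0
  }

  vals <- drop(crossprod(g, w))
  note <- "raw weighted sum of effect-allele dosages"
  if (weighted && rescale) {
    ## per-individual allele-count rescaling M / sum(w) over the variants
    ## that actually contributed; equals the unweighted score when all
    ## weights are equal
    if (missingPolicy == "impute_eaf") {
      vals <- vals * (nrow(g) / sum(w))
    } else {
      wSumUsed <- drop(crossprod(!is.na(assay(x, "dosage")[specs$rsid, ,
                                                           drop = FALSE]),
                                 w))
      wSumUsed[wSumUsed == 0] <- 1
      vals <- vals * (nUsed / wSumUsed)
    }
    note <- "allele-count scale: weighted sum rescaled by M / sum(weights)"
  }
  if (!weighted) note <- "sum of effect-allele dosages (allele count)"
  if (nrow(specs) < nTotal) {
    if (absentPolicy == "rescale") {
      vals <- vals * (nTotal / nrow(specs))
      note <- paste0(note, "; ", nTotal - nrow(specs),
                     " absent variant(s), proportionally rescaled")
    } else {
      note <- paste0(note, "; ", nTotal - nrow(specs),
                     " absent variant(s) omitted without rescaling")
    }
  }
  names(vals) <- colnames(x)
  new("RiskScore", values = vals, weighted = weighted,
      nVariantsUsed = as.integer(nUsed),
      trait = trait, scaleNote = note)
}

#' Unweighted genetic risk score
#'
#' Sum of harmonized effect-allele dosages over the trait's instrument
#' variants: the count of BMI-increasing (or testosterone-decreasing)
#' alleles each man carries.
#'
#' @param x A harmonized [MRCohort-class].
#' @param trait `"bmi_increasing"` or `"t_decreasing"`.
#' @param missingPolicy For sporadic missing dosages: `"impute_eaf"`
#'   (default; a missing entry contributes its Hardy-Weinberg expectation
#'   `ploidy * eaf`, leaving the score mean unbiased under MCAR) or
#'   `"omit"` (contributes 0; `nVariantsUsed` records the shortfall).
#' @param absentPolicy For spec variants missing from the matrix
#'   entirely (a cohort never genotyped for them): `"omit"` (default, no
#'   rescaling -- the score mean shifts down, as observed in cohorts
#'   scored on 96 of 97 variants) or `"rescale"` (multiply by
#'   total/present).
#' @param specs Variant table defining the score; defaults to the
#'   object's own `rowData`.
#' @param xDoseScale `"native"` keeps X-linked male dosages on [0, 1];
#'   `"doubled"` maps them to [0, 2] for sensitivity analysis.
#' @return A [RiskScore-class].
#' @export
unweightedScore <- function(x, trait = c("bmi_increasing", "t_decreasing"),
                            missingPolicy = c("impute_eaf", "omit"),
                            absentPolicy = c("omit", "rescale"),
                            specs = NULL,
                            xDoseScale = c("native", "doubled")) {
  trait <- match.arg(trait)
  .riskScoreEngine(x, trait, weighted = FALSE,
                   missingPolicy = missingPolicy,
                   absentPolicy = absentPolicy, specs = specs,
                   rescale = FALSE, xDoseScale = xDoseScale)
}

#' Weighted genetic risk score
#'
#' Effect-size-weighted sum of harmonized effect-allele dosages,
#' `sum(w_i * g_i)`. With `rescale = TRUE` (default) the sum is
#' multiplied by `M / sum(w_i)` over the contributing variants, putting
#' the score on the allele-count scale (so a 97-variant score averages
#' near twice the mean effect-allele frequency times 97, directly
#' comparable to the unweighted score); the raw weighted sum is kept with
#' `rescale = FALSE`. IV ratio estimates are invariant to this (or any)
#' positive affine rescaling of the instrument.
#'
#' @inheritParams unweightedScore
#' @param rescale Apply the allele-count rescaling (default `TRUE`).
#' @return A [RiskScore-class].
#' @examples
#' specs <- simulateVariants(5, 2, c(0.02, 0.02), seed = 3)
#' params <- structuralParams(cohortProfiles = defaultCohortProfiles()[1, ])
#' x <- simulateCohort(specs, n = 200, params = params, cohort = "GOOD")
#' weightedScore(x, "bmi_increasing")
#' @export
weightedScore <- function(x, trait = c("bmi_increasing", "t_decreasing"),
                          rescale = TRUE,
                          missingPolicy = c("impute_eaf", "omit"),
                          absentPolicy = c("omit", "rescale"),
                          specs = NULL,
                          xDoseScale = c("native", "doubled")) {
  trait <- match.arg(trait)
  .riskScoreEngine(x, trait, weighted = TRUE,
                   missingPolicy = missingPolicy,
                   absentPolicy = absentPolicy, specs = specs,
                   rescale = rescale, xDoseScale = xDoseScale)
}
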