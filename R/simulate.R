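#' @include AllClasses.R AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Structural parameters
# ---------------------------------------------------------------------------

#' Default cohort profiles for the five-cohort male study design
#'
#' Per-cohort sample sizes and phenotype moments (mean, SD) for BMI
#' (kg/m^2), total testosterone (ng/ml), SHBG (nmol/l), age (years) and
#' smoking prevalence, describing five population-based cohorts of
#' European men totalling 7446 individuals.
#'
#' @return A `data.frame`, one row per cohort.
#' @export
defaultCohortProfiles <- function() {
  data.frame(
    cohort = c("GOOD", "MrOS", "SHIP", "SHIP-Trend", "Inter99"),
    n = c(929L, 1682L, 1912L, 427L, 2496L),
    bmiMean = c(22.4, 26.3, 27.7, 27.8, 26.8),
    bmiSd = c(3.2, 3.6, 4.0, 3.7, 4.0),
    tMean = c(4.7, 4.5, 4.8, 4.0, 4.4),
    tSd = c(1.5, 1.7, 1.7, 1.3, 1.6),
    shbgMean = c(20.4, 46.0, 51.3, 38.3, 31.8),
    shbgSd = c(7.2, 22.9, 25.6, 14.2, 13.1),
    ageMean = c(18.9, 75.4, 50.8, 50.1, 46.7),
    ageSd = c(0.6, 3.2, 16.4, 14.2, 7.9),
    smokingPrev = c(0.09, 0.09, 0.34, 0.22, 0.36),
    stringsAsFactors = FALSE)
}

#' StructuralParams: the generator's linear-Gaussian structural model
#'
#' Parameters of the confounded structural model the synthetic cohorts are
#' drawn from. All structural coefficients act on the standardized
#' (Z-score) scale; phenotypes are mapped to each cohort's native mean/SD
#' afterwards, so only second moments matter for the downstream analyses.
#'
#' @slot betaCausal True causal effect of ln BMI on testosterone, in SD of
#'   testosterone per SD of ln BMI.
#' @slot confAgeBmi,confAgeT,confSmokeBmi,confSmokeT Confounder
#'   coefficients (SD units) of standardized age and smoking on the two
#'   traits; these create the observational confounding the IV analysis
#'   must remove.
#' @slot confTimeT Effect of standardized blood-sampling time on
#'   testosterone (diurnal decline).
#' @slot r2GrsBmi,r2GrsT Target fractions of trait variance explained by
#'   the BMI and testosterone risk scores.
#' @slot shbgTCorr Target SHBG-testosterone correlation, generated through
#'   a shared latent component.
#' @slot shbgBmiCoef Direct coefficient of standardized ln BMI on SHBG
#'   (negative: adiposity suppresses SHBG).
#' @slot heterogeneitySd Between-cohort SD of the causal slope (0 = a
#'   common slope in every cohort).
#' @slot bmiScoreAgeInteraction Coefficient of (standardized BMI score) x
#'   (standardized age) on ln BMI; 0 = purely additive model.
#' @slot pleiotropyEffect Direct (exclusion-restriction-violating) effect
#'   of the first BMI variant's standardized dosage on testosterone.
#' @slot mediatedBySHBG If `TRUE`, the whole BMI-to-testosterone path is
#'   routed through SHBG, for mediation sensitivity checks.
#' @slot missingRate Per-entry probability of a missing dosage (MCAR).
#' @slot nBmiVariants,nTVariants Number of instrument variants per trait.
#' @slot dropVariantCohort Name of a cohort from which the last BMI
#'   variant is removed entirely (emulating a cohort genotyped for 96 of
#'   97 variants); `""` disables.
#' @slot cohortProfiles Per-cohort design `data.frame`
#'   (see [defaultCohortProfiles()]).
#' @slot seed Integer seed anchoring all draws.
#' @seealso [structuralParams()], [simulateStudy()].
#' @export
setClass("StructuralParams", representation(
  betaCausal = "numeric",
  confAgeBmi = "numeric", confAgeT = "numeric",
  confSmokeBmi = "numeric", confSmokeT = "numeric",
  confTimeT = "numeric",
  r2GrsBmi = "numeric", r2GrsT = "numeric",
  shbgTCorr = "numeric", shbgBmiCoef = "numeric",
  heterogeneitySd = "numeric",
  bmiScoreAgeInteraction = "numeric",
  pleiotropyEffect = "numeric",
  mediatedBySHBG = "logical",
  missingRate = "numeric",
  nBmiVariants = "integer", nTVariants = "integer",
  dropVariantCohort = "character",
  cohortProfiles = "data.frame",
  seed = "integer"))

setValidity("StructuralParams", function(object) {
  msg <- character()
  if (object@r2GrsBmi < 0 || object@r2GrsBmi > 0.2 ||
      object@r2GrsT < 0 || object@r2GrsT > 0.2)
    msg <- c(msg, "r2 targets must lie in [0, 0.2]")
  pr <- object@cohortProfiles
  if (!nrow(pr)) msg <- c(msg, "cohortProfiles must be non-empty")
  sdCols <- intersect(c("bmiSd", "tSd", "shbgSd", "ageSd"), colnames(pr))
  if (nrow(pr) && any(as.matrix(pr[, sdCols]) <= 0))
    msg <- c(msg, "all profile SDs must be > 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct structural parameters for the synthetic study
#'
#' Defaults encode the study design the package validates against: five
#' male cohorts totalling 7446 individuals with realistic BMI,
#' testosterone, SHBG, age and smoking moments; 97 autosomal
#' BMI-associated variants explaining 1.9 percent of ln-BMI variance;
#' 3 testosterone-associated variants (one X-linked) explaining 2.5
#' percent of testosterone variance; a true causal effect of -0.25 SD
#' testosterone per SD ln BMI; and an SHBG component giving an
#' SHBG-testosterone correlation near 0.51 (about 26 percent of
#' testosterone variance).
#'
#' @param betaCausal,confAgeBmi,confAgeT,confSmokeBmi,confSmokeT,confTimeT
#'   Structural coefficients; see [StructuralParams-class].
#' @param r2GrsBmi,r2GrsT Instrument strength targets.
#' @param shbgTCorr,shbgBmiCoef SHBG model.
#' @param heterogeneitySd,bmiScoreAgeInteraction,pleiotropyEffect,mediatedBySHBG
#'   Sensitivity knobs, all off by default.
#' @param missingRate MCAR dosage missingness, default 0.
#' @param nBmiVariants,nTVariants Variant counts.
#' @param dropVariantCohort Cohort to strip of the last BMI variant.
#' @param cohortProfiles Cohort design table.
#' @param seed Integer seed.
#' @return A validated `StructuralParams` object.
#' @examples
#' params <- structuralParams(betaCausal = -0.25, seed = 42)
#' params
#' @export
structuralParams <- function(betaCausal = -0.25,
                             confAgeBmi = 0.10, confAgeT = -0.25,
                             confSmokeBmi = -0.10, confSmokeT = 0.10,
                             confTimeT = -0.05,
                             r2GrsBmi = 0.019, r2GrsT = 0.025,
                             shbgTCorr = 0.51, shbgBmiCoef = -0.15,
                             heterogeneitySd = 0,
                             bmiScoreAgeInteraction = 0,
                             pleiotropyEffect = 0,
                             mediatedBySHBG = FALSE,
                             missingRate = 0,
                             nBmiVariants = 97L, nTVariants = 3L,
                             dropVariantCohort = "",
                             cohortProfiles = defaultCohortProfiles(),
                             seed = 1L) {
  new("StructuralParams",
      betaCausal = betaCausal,
      confAgeBmi = confAgeBmi, confAgeT = confAgeT,
      confSmokeBmi = confSmokeBmi, confSmokeT = confSmokeT,
      confTimeT = confTimeT,
      r2GrsBmi = r2GrsBmi, r2GrsT = r2GrsT,
      shbgTCorr = shbgTCorr, shbgBmiCoef = shbgBmiCoef,
      heterogeneitySd = heterogeneitySd,
      bmiScoreAgeInteraction = bmiScoreAgeInteraction,
      pleiotropyEffect = pleiotropyEffect,
      mediatedBySHBG = mediatedBySHBG,
      missingRate = missingRate,
      nBmiVariants = as.integer(nBmiVariants),
      nTVariants = as.integer(nTVariants),
      dropVariantCohort = dropVariantCohort,
      cohortProfiles = cohortProfiles,
      seed = as.integer(seed))
}

setMethod("show", "StructuralParams", function(object) {
  pr <- object@cohortProfiles
  cat("Structural model:", nrow(pr), "cohort(s), total n =", sum(pr$n),
      "\n")
  cat(sprintf("  true causal effect %.3g SD(T)/SD(ln BMI); instrument R^2 targets %.3g / %.3g\n",
              object@betaCausal, object@r2GrsBmi, object@r2GrsT))
  cat(sprintf("  variants: %d BMI + %d testosterone; seed %d\n",
              object@nBmiVariants, object@nTVariants, object@seed))
})

# ---------------------------------------------------------------------------
# Variant simulation
# ---------------------------------------------------------------------------

## per-variant dosage variance under Hardy-Weinberg at frequency p:
## 2p(1-p) autosomal, p(1-p) for hemizygous X in males
.dosageVar <- function(eaf, chromClass) {
  .ploidy(chromClass) * eaf * (1 - eaf)
}

#' Simulate instrument variant specifications
#'
#' Draws allele frequencies and per-allele weights for a set of
#' BMI-increasing and testosterone-decreasing instrument variants, then
#' rescales the weights so that, at the drawn frequencies and under
#' Hardy-Weinberg, the expected variance of the weighted score on the
#' standardized trait scale equals each target R-squared exactly
#' (sum over variants of ploidy * eaf * (1 - eaf) * weight^2).
#'
#' With `nT = 3` the three testosterone variants take the rsIDs of the
#' known testosterone loci (rs6258, rs12150660 and the X-linked
#' rs5934505), and with `nBmi = 97` the first BMI variant is labelled
#' rs1558902 (the FTO lead SNP). When `nBmi >= 5` the first BMI variant
#' is given a dominant, FTO-like 15 percent share of the score's
#' explained variance -- strong enough to act as a stand-alone
#' instrument in the pleiotropy split, mirroring the real lead locus.
#'
#' @param nBmi,nT Number of BMI and testosterone variants (each >= 1).
#' @param r2Targets Length-2 numeric: target score R-squared for
#'   (BMI, testosterone), each in (0, 0.2).
#' @param seed Integer seed.
#' @return A variant `DataFrame` (see [variantSpecs()]) with
#'   `nBmi + nT` rows.
#' @examples
#' specs <- simulateVariants(97, 3, c(0.019, 0.025), seed = 1)
#' table(specs$trait, specs$chromClass)
#' @export
simulateVariants <- function(nBmi, nT, r2Targets = c(0.019, 0.025),
                             seed = 1L) {
  if (nBmi < 1 || nT < 1) stop("nBmi and nT must both be >= 1")
  if (length(r2Targets) != 2 || any(r2Targets <= 0) ||
      any(r2Targets >= 0.2))
    stop("r2Targets must be two values in (0, 0.2)")
  set.seed(as.integer(seed))
  n <- nBmi + nT
  rsid <- sprintf("rs%07d", sample.int(9999999L, n))
  if (nBmi == 97) rsid[1] <- "rs1558902"
  if (nT == 3) rsid[nBmi + 1:3] <- c("rs6258", "rs12150660", "rs5934505")
  chromClass <- rep("autosomal", n)
  if (nT == 3) chromClass[nBmi + 3] <- "x_male"
  trait <- rep(c("bmi_increasing", "t_decreasing"), c(nBmi, nT))
  eaf <- stats::runif(n, 0.10, 0.90)
  if (nBmi >= 5) eaf[1] <- 0.42   # lead-locus (FTO-like) frequency
  ## raw weight dispersion mimics GWAS hit lists (coefficient of
  ## variation ~0.35); the absolute scale is fixed by the R^2 target
  ## below and the lead locus is boosted afterwards
  w <- stats::rgamma(n, shape = 8, rate = 8) + 0.10
  ea <- character(n); oa <- character(n)
  for (i in seq_len(n)) {
    al <- sample(.NUCLEOTIDES, 2)
    ea[i] <- al[1]; oa[i] <- al[2]
  }
  specs <- variantSpecs(rsid = rsid, chromClass = chromClass,
                        effectAllele = ea, otherAllele = oa,
                        weight = w, eaf = eaf, trait = trait)
  for (k in 1:2) {
    tr <- .TRAITS[k]
    idx <- specs$trait == tr
    v <- sum(.dosageVar(specs$eaf[idx], specs$chromClass[idx]) *
               specs$weight[idx]^2)
    specs$weight[idx] <- specs$weight[idx] * sqrt(r2Targets[k] / v)
  }
  ## give the lead BMI locus an FTO-like dominant share (~15% of the
  ## score's explained variance) so it can serve as a stand-alone
  ## instrument in the pleiotropy split, as the real lead locus does
  if (nBmi >= 5) {
    idx <- which(specs$trait == "bmi_increasing")
    vv <- .dosageVar(specs$eaf[idx], specs$chromClass[idx]) *
      specs$weight[idx]^2
    r2b <- r2Targets[1]
    share <- 0.15
    specs$weight[idx[1]] <-
      sqrt(share * r2b /
             .dosageVar(specs$eaf[idx[1]], specs$chromClass[idx[1]]))
    specs$weight[idx[-1]] <- specs$weight[idx[-1]] *
      sqrt((1 - share) * r2b / sum(vv[-1]))
  }
  specs
}

# ---------------------------------------------------------------------------
# Cohort simulation
# ---------------------------------------------------------------------------

## lognormal meanlog/sdlog matching a target mean/SD
.lnormPars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one cohort under the structural model
#'
#' Genotypes are drawn binomially at each variant's effect-allele
#' frequency (2 draws autosomal, 1 for X-linked in males), independently
#' of all confounders -- the defining property of a valid genetic
#' instrument. On the standardized scale, ln BMI is the sum of the BMI
#' score contribution, age and smoking confounder terms and Gaussian
#' noise; testosterone is the causal term `betaCausal * lnBMI_z`, minus
#' the testosterone score contribution, plus confounder, sampling-time
#' and shared-SHBG components and noise. Residual variances are chosen so
#' each standardized trait has unit variance, after which phenotypes are
#' mapped to the cohort's native moments (ln BMI to a moment-matched
#' lognormal; testosterone and SHBG affinely, floored just above zero).
#'
#' @param specs Variant `DataFrame` from [simulateVariants()] or
#'   [variantSpecs()].
#' @param n Number of individuals (>= 10); defaults to the profile's `n`.
#' @param params A [StructuralParams-class] object.
#' @param cohort Cohort name; must appear in `params@cohortProfiles`.
#' @param seed Integer seed; by default derived deterministically from
#'   `params@seed` and the cohort's position in the profile table.
#' @return An [MRCohort-class].
#' @examples
#' specs <- simulateVariants(5, 2, c(0.02, 0.02), seed = 3)
#' params <- structuralParams(cohortProfiles = defaultCohortProfiles()[2, ])
#' cohort <- simulateCohort(specs, n = 500, params = params, cohort = "MrOS")
#' cohort
#' @export
simulateCohort <- function(specs, n = NULL, params = structuralParams(),
                           cohort, seed = NULL) {
  pr <- params@cohortProfiles
  row <- match(cohort, pr$cohort)
  if (is.na(row))
    stop("unknown cohort '", cohort, "'; profiles define: ",
         paste(pr$cohort, collapse = ", "))
  if (is.null(n)) n <- pr$n[row]
  if (n < 10) stop("n must be >= 10")
  if (is.null(seed)) seed <- params@seed + 7919L * row
  set.seed(as.integer(seed %% .Machine$integer.max))

  betaC <- params@betaCausal
  if (params@heterogeneitySd > 0)
    betaC <- betaC + stats::rnorm(1, 0, params@heterogeneitySd)

  specs <- .asVariantSpecs(specs)
  nv <- nrow(specs)
  ploidy <- .ploidy(specs$chromClass)
  g <- matrix(stats::rbinom(n * nv, size = rep(ploidy, each = n),
                            prob = rep(specs$eaf, each = n)),
              nrow = n, ncol = nv,
              dimnames = list(NULL, specs$rsid))

  isB <- specs$trait == "bmi_increasing"
  isT <- specs$trait == "t_decreasing"
  wB <- specs$weight[isB]; wT <- specs$weight[isT]
  ## centered score contributions; their variances equal the R^2 targets
  ## at the drawn frequencies by the weight-scaling construction
  sB <- drop(g[, isB, drop = FALSE] %*% wB) -
    sum(ploidy[isB] * specs$eaf[isB] * wB)
  sT <- drop(g[, isT, drop = FALSE] %*% wT) -
    sum(ploidy[isT] * specs$eaf[isT] * wT)
  r2b <- sum(.dosageVar(specs$eaf[isB], specs$chromClass[isB]) * wB^2)
  r2t <- sum(.dosageVar(specs$eaf[isT], specs$chromClass[isT]) * wT^2)

  ageZ <- stats::rnorm(n)
  prev <- pr$smokingPrev[row]
  smoking <- stats::rbinom(n, 1, prev)
  smokeZ <- (smoking - prev) / sqrt(prev * (1 - prev))
  samplingTime <- stats::runif(n, 7, 11)
  timeZ <- (samplingTime - 9) / sqrt(16 / 12)

  aB <- params@confAgeBmi; sBc <- params@confSmokeBmi
  aT <- params@confAgeT; sTc <- params@confSmokeT
  cT <- params@confTimeT
  eta <- params@bmiScoreAgeInteraction

  v1 <- 1 - r2b - aB^2 - sBc^2 - eta^2
  if (v1 <= 0) stop("BMI variance budget exceeded; reduce coefficients")
  bmiZ <- sB + eta * (sB / sqrt(r2b)) * ageZ + aB * ageZ + sBc * smokeZ +
    stats::rnorm(n, 0, sqrt(v1))

  pleio <- params@pleiotropyEffect
  pleioTerm <- 0; pleioVar <- 0; pleioCross <- 0
  if (pleio != 0) {
    j <- which(isB)[1]
    sdj <- sqrt(.dosageVar(specs$eaf[j], specs$chromClass[j]))
    gstd <- (g[, j] - ploidy[j] * specs$eaf[j]) / sdj
    pleioTerm <- pleio * gstd
    pleioVar <- pleio^2
    pleioCross <- 2 * betaC * pleio * specs$weight[j] * sdj
  }

  confCross <- 2 * betaC * (aB * aT + sBc * sTc)
  if (params@mediatedBySHBG) {
    delta <- sqrt(max(params@shbgTCorr, 0.25))
    gB <- betaC / delta
    e3v <- 1 - gB^2
    if (e3v <= 0) stop("SHBG mediation variance budget exceeded")
    shbgZ <- gB * bmiZ + stats::rnorm(n, 0, sqrt(e3v))
    v2 <- 1 - (delta^2 + r2t + aT^2 + sTc^2 + cT^2 + pleioVar +
                 confCross + pleioCross)
    if (v2 <= 0) stop("testosterone variance budget exceeded")
    tZ <- delta * shbgZ - sT + aT * ageZ + sTc * smokeZ + cT * timeZ +
      pleioTerm + stats::rnorm(n, 0, sqrt(v2))
  } else {
    lam <- sqrt(params@shbgTCorr)
    latent <- stats::rnorm(n)
    e3v <- 1 - lam^2 - params@shbgBmiCoef^2
    if (e3v <= 0) stop("SHBG variance budget exceeded")
    shbgZ <- lam * latent + params@shbgBmiCoef * bmiZ +
      stats::rnorm(n, 0, sqrt(e3v))
    v2 <- 1 - (betaC^2 + r2t + aT^2 + sTc^2 + cT^2 + lam^2 + pleioVar +
                 confCross + pleioCross)
    if (v2 <= 0) stop("testosterone variance budget exceeded")
    tZ <- betaC * bmiZ - sT + aT * ageZ + sTc * smokeZ + cT * timeZ +
      lam * latent + pleioTerm + stats::rnorm(n, 0, sqrt(v2))
  }

  lp <- .lnormPars(pr$bmiMean[row], pr$bmiSd[row])
  pheno <- data.frame(
    bmi = exp(lp$meanlog + lp$sdlog * bmiZ),
    testosterone = pmax(pr$tMean[row] + pr$tSd[row] * tZ, 0.1),
    shbg = pmax(pr$shbgMean[row] + pr$shbgSd[row] * shbgZ, 0.5),
    age = pmax(pr$ageMean[row] + pr$ageSd[row] * ageZ, 18),
    smoking = smoking,
    samplingTime = samplingTime,
    cohort = cohort)

  if (params@missingRate > 0) {
    drop <- stats::runif(n * nv) < params@missingRate
    g[drop] <- NA_real_
  }
  rownames(g) <- sprintf("%s_%06d", gsub("[^A-Za-z0-9]", "", cohort),
                         seq_len(n))
  MRCohort(g, specs, pheno, cohort = cohort)
}

#' Simulate the full multi-cohort study
#'
#' One [MRCohort-class] per row of the parameter object's cohort profile
#' table, with variant specifications shared across cohorts. The default
#' configuration yields five cohorts totalling 7446 men. When
#' `params@dropVariantCohort` names a cohort, the last BMI variant is
#' removed from that cohort's matrix entirely, emulating a cohort
#' genotyped for 96 of the 97 BMI variants.
#'
#' @param params A [StructuralParams-class].
#' @param specs Optional variant table; simulated from `params` when
#'   `NULL`.
#' @return Named list of [MRCohort-class] objects.
#' @examples
#' params <- structuralParams(seed = 7)
#' study <- simulateStudy(params)
#' sum(vapply(study, ncol, integer(1)))  # 7446
#' @export
simulateStudy <- function(params = structuralParams(), specs = NULL) {
  if (is.null(specs))
    specs <- simulateVariants(params@nBmiVariants, params@nTVariants,
                              c(params@r2GrsBmi, params@r2GrsT),
                              seed = params@seed)
  pr <- params@cohortProfiles
  out <- lapply(seq_len(nrow(pr)), function(i) {
    co <- simulateCohort(specs, n = pr$n[i], params = params,
                         cohort = pr$cohort[i])
    if (nzchar(params@dropVariantCohort) &&
        pr$cohort[i] == params@dropVariantCohort) {
      bmiIdx <- which(rowData(co)$trait == "bmi_increasing")
      co <- co[-bmiIdx[length(bmiIdx)], ]
    }
    co
  })
  names(out) <- pr$cohort
  out
}

#' Randomly re-express dosages on the opposite counted allele
#'
#' For a random subset of variants, re-encodes the stored dosage as
#' copies of the *other* allele (`ploidy - dosage`) and updates the
#' `countedAllele` annotation accordingly. The information content is
#' unchanged; this exercises [harmonizeDosages()], which must restore the
#' effect-allele orientation exactly.
#'
#' @param x An [MRCohort-class].
#' @param prob Per-variant probability of swapping, default 0.5.
#' @param seed Integer seed.
#' @return An [MRCohort-class] with scrambled allele orientation.
#' @export
scrambleAlleles <- function(x, prob = 0.5, seed = 1L) {
  stopifnot(is(x, "MRCohort"))
  set.seed(as.integer(seed))
  rd <- rowData(x)
  flip <- stats::runif(nrow(rd)) < prob
  g <- assay(x, "dosage")
  lim <- .ploidy(rd$chromClass)
  g[flip, ] <- lim[flip] - g[flip, , drop = FALSE]
  newCounted <- ifelse(rd$countedAllele == rd$effectAllele,
                       rd$otherAllele, rd$effectAllele)
  rd$countedAllele[flip] <- newCounted[flip]
  assay(x, "dosage") <- g
  rowData(x) <- rd
  validObject(x)
  x
}
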