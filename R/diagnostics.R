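#' @include AllClasses.R AllGenerics.R
NULL

## closed-form simple linear regression of y on x (complete pairs):
## slope, its t-test SE/p, and R^2. This is the workhorse behind every
## score-phenotype association and the per-variant scan.
.simpleOLS <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx == 0) stop("degenerate instrument: predictor has zero variance")
  beta <- sum(xc * yc) / sxx
  res <- yc - beta * xc
  rss <- sum(res^2)
  tss <- sum(yc^2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  list(beta = beta, se = se, p = max(p, .Machine$double.xmin),
       r2 = min(max(r2, 0), 1), n = n)
}

.alignPair <- function(a, b) {
  na <- names(a); nb <- names(b)
  if (!is.null(na) && !is.null(nb) && !identical(na, nb)) {
    common <- intersect(na, nb)
    if (!length(common)) stop("no overlapping individuals")
    a <- a[common]; b <- b[common]
  }
  if (length(a) != length(b))
    stop("inputs cover different numbers of individuals and share no ids")
  list(a = a, b = b)
}

.asNumericInput <- function(x) {
  if (is(x, "RiskScore")) scoreValues(x)
  else if (is(x, "StandardizedPhenotype")) zValues(x)
  else as.numeric(x)
}

#' Score-phenotype association
#'
#' OLS slope of a standardized phenotype on a genetic risk score, with
#' standard error, two-sided p-value and the score's incremental
#' R-squared. Covariate adjustment is already absorbed into the Z-score
#' outcome, so this is a single-predictor regression on the residualized
#' scale -- the same form the instrument-strength F statistic assumes.
#'
#' @param score A [RiskScore-class] (or numeric vector).
#' @param z A [StandardizedPhenotype-class] (or numeric vector). Matched
#'   to the score by individual ids when both are named.
#' @param label Optional description stored on the result.
#' @return An [AssocResult-class].
#' @export
associate <- function(score, z, label = "") {
  sv <- .asNumericInput(score)
  zv <- .asNumericInput(z)
  al <- .alignPair(sv, zv)
  if (sum(!is.na(al$a) & !is.na(al$b)) < 30)
    stop("need at least 30 matched individuals")
  fit <- .simpleOLS(al$a, al$b)
  if (!nzchar(label) && is(score, "RiskScore") &&
      is(z, "StandardizedPhenotype"))
    label <- paste0(if (score@weighted) "w" else "uw", "GRS(",
                    score@trait, ") ~ ", z@phenotypeName)
  new("AssocResult", beta = fit$beta, se = fit$se, p = fit$p,
      r2 = fit$r2, n = as.integer(fit$n), label = label)
}

#' Instrument-strength F statistic
#'
#' `F = (n - 2) * R^2 / (1 - R^2)` for a single-predictor instrument
#' regression: the conventional strength measure for a genetic risk
#' score, with values far above 10 indicating a strong instrument.
#' Strictly increasing in both arguments.
#'
#' @param r2 Fraction of exposure variance explained by the instrument,
#'   in `[0, 1)`.
#' @param n Sample size, > 2.
#' @return The F statistic (numeric scalar, >= 0).
#' @examples
#' fStatistic(0.019, 7446)
#' fStatistic(0.025, 7446)
#' @export
fStatistic <- function(r2, n) {
  if (any(r2 < 0) || any(r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(n <= 2)) stop("n must exceed 2")
  (n - 2) * r2 / (1 - r2)
}

#' Confounder balance of an instrument
#'
#' A valid instrument is independent of confounders because alleles are
#' randomized at conception. This regresses the score on each candidate
#' confounder in turn (score as outcome) and returns the two-sided
#' p-value per covariate; under instrument validity these are uniform.
#' Constant covariates are skipped with a warning.
#'
#' @param score A [RiskScore-class] or numeric vector.
#' @param covariates A `data.frame`/`DataFrame` of candidate confounders,
#'   or an [MRCohort-class] (its phenotype table is used).
#' @param columns Which columns to test; default `c("age", "smoking")`
#'   intersected with what is present.
#' @return Named numeric vector of p-values (possibly empty).
#' @export
confounderBalance <- function(score, covariates,
                              columns = c("age", "smoking")) {
  sv <- .asNumericInput(score)
  if (is(covariates, "MRCohort")) covariates <- phenotypes(covariates)
  covariates <- as.data.frame(covariates)
  columns <- intersect(columns, colnames(covariates))
  out <- numeric(0)
  for (cv in columns) {
    v <- suppressWarnings(as.numeric(covariates[[cv]]))
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("covariate '", cv, "' is constant; skipped")
      next
    }
    fit <- .simpleOLS(v, sv)
    out[cv] <- fit$p
  }
  out
}

#' Effect-modification (interaction) test
#'
#' Adds a score-by-modifier product term to the association model
#' `z ~ score + modifier + score:modifier` and returns the two-sided
#' p-value of the product term.
#'
#' @param score,z As in [associate()].
#' @param modifier Numeric covariate vector (age, smoking, the other
#'   trait's Z-score, ...).
#' @return Two-sided p-value of the interaction coefficient.
#' @export
interactionTest <- function(score, z, modifier) {
  sv <- .asNumericInput(score)
  zv <- .asNumericInput(z)
  mv <- .asNumericInput(modifier)
  if (length(unique(mv[!is.na(mv)])) < 2)
    stop("modifier is constant")
  al <- .alignPair(sv, zv)
  if (length(mv) != length(al$a)) {
    al2 <- .alignPair(sv, mv)
    mv <- al2$b
  }
  df <- data.frame(z = al$b, s = al$a, m = mv)
  fit <- stats::lm(z ~ s * m, data = df)
  co <- summary(fit)$coefficients
  if (!"s:m" %in% rownames(co))
    stop("interaction term could not be estimated")
  unname(co["s:m", "Pr(>|t|)"])
}

#' Non-linearity (quadratic-term) test
#'
#' Adds a squared-score term to the association model and returns the
#' two-sided p-value of the quadratic coefficient; a small p flags
#' departure from the linear dose-response the IV ratio assumes.
#'
#' @param score,z As in [associate()].
#' @return Two-sided p-value of the squared-score term.
#' @export
nonlinearityTest <- function(score, z) {
  sv <- .asNumericInput(score)
  zv <- .asNumericInput(z)
  al <- .alignPair(sv, zv)
  df <- data.frame(z = al$b, s = al$a)
  fit <- stats::lm(z ~ s + I(s^2), data = df)
  co <- summary(fit)$coefficients
  unname(co["I(s^2)", "Pr(>|t|)"])
}

#' Per-variant association scan with Bonferroni flags
#'
#' Regresses the standardized phenotype on each harmonized variant
#' dosage separately, flagging nominal (`p < alpha`) and Bonferroni
#' (`p < alpha / m`) significance, where `m` is the number of
#' polymorphic variants scanned. Monomorphic variants are reported but
#' excluded from both testing and the Bonferroni denominator.
#'
#' @param x A harmonized [MRCohort-class].
#' @param z A [StandardizedPhenotype-class] or numeric vector for the
#'   same individuals.
#' @param trait Restrict the scan to one trait's variants (default: all).
#' @param alpha Nominal level, default 0.05.
#' @return A `data.frame` with one row per variant: `rsid`, `beta`,
#'   `se`, `p`, `r2`, `n`, `monomorphic`, `nominal`, `bonferroni`, plus
#'   attribute `"m"` (the Bonferroni denominator).
#' @export
perSnpScan <- function(x, z, trait = NULL, alpha = 0.05) {
  stopifnot(is(x, "MRCohort"))
  .checkHarmonized(x)
  zv <- .asNumericInput(z)
  g <- assay(x, "dosage")
  if (!is.null(trait)) g <- g[rowData(x)$trait == trait, , drop = FALSE]
  res <- data.frame(rsid = rownames(g), beta = NA_real_, se = NA_real_,
                    p = NA_real_, r2 = NA_real_, n = NA_integer_,
                    monomorphic = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    if (length(unique(gi[!is.na(gi)])) < 2) {
      res$monomorphic[i] <- TRUE
      next
    }
    fit <- .simpleOLS(gi, zv)
    res$beta[i] <- fit$beta; res$se[i] <- fit$se; res$p[i] <- fit$p
    res$r2[i] <- fit$r2; res$n[i] <- fit$n
  }
  m <- sum(!res$monomorphic)
  res$nominal <- !res$monomorphic & res$p < alpha
  res$bonferroni <- !res$monomorphic & res$p < alpha / max(m, 1)
  attr(res, "m") <- m
  res
}

#' Full instrument diagnostics report
#'
#' Bundles, for one risk score: its association with the instrumented
#' trait (slope, p, R-squared), the instrument-strength F statistic,
#' confounder-balance p-values, interaction p-values for a set of
#' modifiers, the quadratic non-linearity p, and the per-variant scan.
#'
#' @param x A harmonized [MRCohort-class] or combined cohort.
#' @param score A [RiskScore-class] computed from `x`.
#' @param z The standardized instrumented trait.
#' @param modifiers Named list of modifier vectors for interaction tests
#'   (default: age and smoking from the phenotype table).
#' @param alpha Level for the per-variant scan flags.
#' @return A list with elements `instrument`, `assoc` (an
#'   [AssocResult-class]), `fStat`, `confounderP`, `interactionP`,
#'   `quadraticP` and `perSnp`.
#' @export
diagnosticsReport <- function(x, score, z, modifiers = NULL,
                              alpha = 0.05) {
  assoc <- associate(score, z)
  ph <- as.data.frame(phenotypes(x))
  if (is.null(modifiers))
    modifiers <- as.list(ph[, intersect(c("age", "smoking"),
                                        colnames(ph)), drop = FALSE])
  interP <- vapply(modifiers, function(m)
    tryCatch(interactionTest(score, z, m), error = function(e) NA_real_),
    numeric(1))
  list(instrument = paste0(if (score@weighted) "w" else "uw",
                           "GRS(", score@trait, ")"),
       assoc = assoc,
       fStat = fStatistic(rSquared(assoc), sampleSize(assoc)),
       confounderP = confounderBalance(score, ph),
       interactionP = interP,
       quadraticP = nonlinearityTest(score, z),
       perSnp = perSnpScan(x, z, trait = score@trait, alpha = alpha))
}
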