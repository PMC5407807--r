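# IV estimation: Wald ratio arithmetic, 2SLS equivalences and recovery,
# SHBG adjustment, the pleiotropy split, Hausman comparison, clinical
# translation.

assocOf <- function(beta, se, n = 7446L) {
  new("AssocResult", beta = beta, se = se,
      p = max(2 * pnorm(-abs(beta / se)), 1e-300), r2 = 0.02, n = n,
      label = "")
}

test_that("the Wald ratio reproduces published-style coefficient pairs", {
  # T-direction rows: outcome and intermediate coefficients as printed
  r1 <- waldRatio(assocOf(-0.020, 0.0204), assocOf(-0.281, 0.0199),
                  direction = "t_to_bmi", instrument = "wGRS_T")
  expect_equal(round(estimate(r1), 2), 0.07)
  r2 <- waldRatio(assocOf(-0.004, 0.0150), assocOf(-0.191, 0.0148),
                  direction = "t_to_bmi", instrument = "uwGRS_T")
  expect_equal(round(estimate(r2), 2), 0.02)
  expect_match(ivUnits(r1), "SD ln-transformed BMI per SD testosterone")
})

test_that("Wald ratio handles the null numerator and rejects null denominator", {
  r <- waldRatio(assocOf(0, 0.02), assocOf(-0.2, 0.02))
  expect_equal(estimate(r), 0)
  expect_equal(stdError(r), 0.02 / 0.2)
  expect_equal(confInt(r), c(-1, 1) * qnorm(0.975) * 0.1,
               tolerance = 1e-10)
  expect_error(waldRatio(assocOf(0.1, 0.02), assocOf(0, 0.02)),
               "weak instrument")
})

test_that("delta-method SE follows the stated propagation formula", {
  bo <- -0.006; so <- 0.0018; be <- 0.022; se <- 0.0018
  r <- waldRatio(assocOf(bo, so), assocOf(be, se))
  expect_equal(stdError(r),
               abs(bo / be) * sqrt((so / bo)^2 + (se / be)^2),
               tolerance = 1e-12)
})

test_that("Fieller and delta intervals agree for strong instruments", {
  r1 <- waldRatio(assocOf(-0.006, 0.0018), assocOf(0.022, 0.0018))
  r2 <- waldRatio(assocOf(-0.006, 0.0018), assocOf(0.022, 0.0018),
                  ci = "fieller")
  expect_equal(confInt(r1), confInt(r2), tolerance = 0.05)
})

test_that("2SLS equals the Wald ratio for one instrument, no covariates", {
  co <- fixCohort(n = 3000, seed = 14)
  z <- fixZ(co)
  s <- weightedScore(co, "bmi_increasing")
  aO <- associate(s, z$t); aE <- associate(s, z$bmi)
  wr <- waldRatio(aO, aE, direction = "bmi_to_t")
  ts <- tsls(s, z$bmi, z$t, direction = "bmi_to_t")
  expect_lt(abs(estimate(ts) - estimate(wr)), 1e-10)
})

test_that("IV estimates are invariant to affine rescaling of the score", {
  co <- fixCohort(n = 3000, seed = 24)
  z <- fixZ(co)
  s <- scoreValues(weightedScore(co, "bmi_increasing"))
  t1 <- tsls(s, z$bmi, z$t)
  t2 <- tsls(s * 3.7 + 11, z$bmi, z$t)
  expect_lt(abs(estimate(t1) - estimate(t2)), 1e-10)
  expect_lt(abs(stdError(t1) - stdError(t2)), 1e-10)
})

test_that("2SLS recovers the simulated causal effect", {
  # truth -0.25 at large single-cohort n
  co <- fixCohort(n = 100000, seed = 5, beta = -0.25)
  z <- fixZ(co)
  s <- weightedScore(co, "bmi_increasing")
  ts <- tsls(s, z$bmi, z$t, direction = "bmi_to_t")
  expect_equal(estimate(ts), -0.25, tolerance = 0.05 / 0.25)
  expect_lt(abs(estimate(ts) + 0.25), 0.05)
})

test_that("2SLS removes confounding that biases the observational slope", {
  # strong shared confounding, truth 0
  co <- fixCohort(n = 50000, seed = 35, beta = 0,
                  confAgeBmi = 0.35, confAgeT = -0.4,
                  confSmokeBmi = -0.2, confSmokeT = 0.2)
  ph <- phenotypes(co)
  zb <- standardizePhenotype(log(ph$bmi))      # unadjusted on purpose
  zt <- standardizePhenotype(ph$testosterone)
  obs <- associate(zValues(zb), zt)
  expect_gt(abs(estimate(obs)), 0.1)           # biased away from 0
  s <- weightedScore(co, "bmi_increasing")
  iv <- tsls(s, zb, zt, direction = "bmi_to_t")
  expect_lt(abs(estimate(iv)), 3 * stdError(iv))
})

test_that("weak instruments warn below the floor and refuse below F = 1", {
  set.seed(44)
  n <- 2000
  s <- rnorm(n)
  x <- 0.05 * s + rnorm(n)   # F ~ 5
  y <- rnorm(n)
  expect_warning(tsls(s, x, y), "weak instrument")
  # exposure orthogonalized against the instrument: first-stage F = 0
  xOrth <- qr.resid(qr(cbind(1, s)), rnorm(n))
  expect_error(suppressWarnings(tsls(s, xOrth, y)), "too weak")
})

test_that("SHBG adjustment attenuates a fully mediated effect", {
  co <- fixCohort(n = 50000, seed = 45, beta = -0.3,
                  mediatedBySHBG = TRUE)
  ph <- phenotypes(co)
  z <- fixZ(co)
  zshbg <- standardizePhenotype("shbg", ph,
                                c("age", "smoking", "samplingTime"))
  s <- weightedScore(co, "bmi_increasing")
  un <- tsls(s, z$bmi, z$t, direction = "bmi_to_t")
  ad <- adjustedIV(s, z$bmi, z$t, zshbg, adjustName = "shbg",
                   direction = "bmi_to_t")
  expect_lt(abs(estimate(ad)), abs(estimate(un)) * 0.5)
})

test_that("SHBG adjustment leaves an SHBG-independent effect intact", {
  co <- fixCohort(n = 50000, seed = 55, beta = -0.25, shbgBmiCoef = 0)
  ph <- phenotypes(co)
  z <- fixZ(co)
  zshbg <- standardizePhenotype("shbg", ph,
                                c("age", "smoking", "samplingTime"))
  s <- weightedScore(co, "bmi_increasing")
  un <- tsls(s, z$bmi, z$t, direction = "bmi_to_t")
  ad <- adjustedIV(s, z$bmi, z$t, zshbg, adjustName = "shbg",
                   direction = "bmi_to_t")
  expect_lt(abs(estimate(ad) - estimate(un)), stdError(un))
})

test_that("all-missing SHBG marks the adjusted analysis as skipped", {
  co <- fixCohort(n = 1000, seed = 65)
  z <- fixZ(co)
  s <- weightedScore(co, "bmi_increasing")
  expect_message(
    out <- adjustedIV(s, z$bmi, z$t, rep(NA_real_, 1000)),
    "skipped")
  expect_null(out)
})

test_that("the instrument split is consistent without pleiotropy", {
  # lead-locus (1) vs remaining-96 split at paper-like effect sizes:
  # under a homogeneous causal effect both sub-instruments should
  # bracket the truth and agree, up to the expected sampling rates
  specs <- fixSpecsFull()
  res <- vapply(1:8, function(i) {
    co <- fixCohort(n = 30000, seed = 70 + i, beta = -0.25,
                    specs = specs)
    z <- fixZ(co)
    rd <- variants(co)
    bmiIds <- rd$rsid[rd$trait == "bmi_increasing"]
    sp <- instrumentSplit(co, list(bmiIds[1], bmiIds[-1]),
                          z$bmi, z$t, direction = "bmi_to_t")
    c(consistent = sp$differenceP > 0.05,
      cover1 = confInt(sp$iv1)[1] < -0.25 && confInt(sp$iv1)[2] > -0.25,
      cover2 = confInt(sp$iv2)[1] < -0.25 && confInt(sp$iv2)[2] > -0.25)
  }, logical(3))
  expect_gte(mean(res["consistent", ]), 0.75)
  expect_gte(mean(res["cover1", ]), 0.75)
  expect_gte(mean(res["cover2", ]), 0.75)
  co <- fixCohort(n = 30000, seed = 71, beta = -0.25, specs = specs)
  z <- fixZ(co)
  bmiIds <- variants(co)$rsid[variants(co)$trait == "bmi_increasing"]
  expect_error(instrumentSplit(co, list(bmiIds, character(0)),
                               z$bmi, z$t), "non-empty")
  expect_error(instrumentSplit(co, list(bmiIds[1:10], bmiIds[10:97]),
                               z$bmi, z$t), "overlap")
})

test_that("a pleiotropic sub-instrument is detected by the split", {
  hits <- vapply(1:10, function(i) {
    co <- fixCohort(n = 30000, seed = 200 + i, beta = -0.25,
                    pleiotropyEffect = -0.08, specs = fixSpecsFull())
    z <- fixZ(co)
    rd <- variants(co)
    bmiIds <- rd$rsid[rd$trait == "bmi_increasing"]
    # variant 1 carries the direct path in the generator
    sp <- instrumentSplit(co, list(bmiIds[1], bmiIds[-1]),
                          z$bmi, z$t, direction = "bmi_to_t")
    sp$differenceP < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("split difference p is uniform under homogeneous effects", {
  ps <- vapply(1:60, function(i) {
    co <- fixCohort(n = 4000, seed = 300 + i, beta = -0.25,
                    specs = fixSpecsSmall())
    z <- fixZ(co)
    rd <- variants(co)
    bmiIds <- rd$rsid[rd$trait == "bmi_increasing"]
    sp <- suppressWarnings(
      instrumentSplit(co, list(bmiIds[1:2], bmiIds[-(1:2)]),
                      z$bmi, z$t, direction = "bmi_to_t"))
    sp$differenceP
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the Hausman-type observational-vs-IV comparison behaves", {
  obs <- assocOf(-0.30, 0.012)
  iv <- waldRatio(assocOf(-0.0066, 0.0022), assocOf(0.022, 0.0018))
  expect_equal(obsVsIV(assocOf(estimate(iv), 0.012), iv), 1)
  p <- obsVsIV(obs, iv)
  expect_true(p > 0 && p <= 1)
  # IV nominally more precise than OLS -> floored variance with warning
  ivTight <- waldRatio(assocOf(-0.0066, 1e-6), assocOf(0.022, 1e-7))
  expect_warning(obsVsIV(obs, ivTight), "floored")
})

test_that("discordant truth is detected when confounding is strong", {
  hits <- vapply(1:10, function(i) {
    co <- fixCohort(n = 50000, seed = 400 + i, beta = 0,
                    confAgeBmi = 0.35, confAgeT = -0.4,
                    confSmokeBmi = -0.2, confSmokeT = 0.2)
    ph <- phenotypes(co)
    zb <- standardizePhenotype(log(ph$bmi))
    zt <- standardizePhenotype(ph$testosterone)
    obs <- associate(zValues(zb), zt)
    s <- weightedScore(co, "bmi_increasing")
    iv <- tsls(s, zb, zt, direction = "bmi_to_t")
    obsVsIV(obs, iv) < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("percent-change translation chains the exact arithmetic", {
  tr <- translateToPercent(-0.25, sdT = 1.6, sdLogBmi = 0.148,
                           tPredAtFrom = 4.2)
  manual <- 100 * (-0.25) * (1.6 / 0.148) * (log(25) - log(30)) / 4.2
  expect_equal(tr@percentChange, manual, tolerance = 1e-12)
  expect_equal(tr@percentChange, 11.7, tolerance = 0.01)
  expect_gt(tr@percentChange, 0)  # BMI loss raises testosterone
  expect_equal(translateToPercent(0, 1.6, 0.148, 4.2)@percentChange, 0)
  expect_equal(translateToPercent(-0.25, 1.6, 0.148, 4.2,
                                  bmiFrom = 28,
                                  bmiTo = 28)@percentChange, 0)
  expect_error(translateToPercent(-0.25, -1, 0.148, 4.2), "> 0")
})

test_that("translation is antisymmetric in the BMI endpoints", {
  a <- translateToPercent(-0.25, 1.6, 0.148, 4.2, bmiFrom = 30,
                          bmiTo = 25)
  b <- translateToPercent(-0.25, 1.6, 0.148, 4.2, bmiFrom = 25,
                          bmiTo = 30)
  expect_equal(a@percentChange, -b@percentChange, tolerance = 1e-12)
})

test_that("predicted testosterone interpolates the pooled regression", {
  co <- fixCohort(n = 20000, seed = 85)
  ph <- as.data.frame(phenotypes(co))
  tp30 <- predictedTestosterone(ph, bmiAt = 30)
  tp25 <- predictedTestosterone(ph, bmiAt = 25)
  expect_gt(tp25, tp30)  # lower BMI, higher testosterone
  expect_gt(tp30, 1); expect_lt(tp30, 8)
  # closed-form equivalence with the fitted lm
  fit <- lm(testosterone ~ lnbmi + age + smoking + samplingTime,
            data = transform(ph, lnbmi = log(bmi)))
  expect_equal(tp30,
               mean(ph$testosterone) +
                 coef(fit)[["lnbmi"]] * (log(30) - mean(log(ph$bmi))),
               tolerance = 1e-10)
})
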