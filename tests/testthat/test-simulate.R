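# Synthetic multi-cohort generator: variant construction, the structural
# model's moments, genotype-confounder independence, determinism.

test_that("simulateVariants hits counts, X-linkage and R2 targets", {
  specs <- fixSpecsFull()
  expect_equal(nrow(specs), 100)
  expect_equal(sum(specs$trait == "bmi_increasing"), 97)
  expect_equal(sum(specs$trait == "t_decreasing"), 3)
  # exactly one X-linked variant among the three testosterone SNPs
  expect_equal(sum(specs$chromClass == "x_male"), 1)
  expect_true(all(specs$chromClass[specs$trait == "bmi_increasing"] ==
                    "autosomal"))
  # theoretical score variance equals the target exactly by construction
  for (tr in c("bmi_increasing", "t_decreasing")) {
    idx <- specs$trait == tr
    ploidy <- ifelse(specs$chromClass[idx] == "x_male", 1, 2)
    v <- sum(ploidy * specs$eaf[idx] * (1 - specs$eaf[idx]) *
               specs$weight[idx]^2)
    expect_equal(v, if (tr == "bmi_increasing") 0.019 else 0.025,
                 tolerance = 1e-12)
  }
  expect_true(all(specs$eaf > 0 & specs$eaf < 1))
  expect_true(all(specs$weight >= 0))
  expect_true(all(specs$effectAllele != specs$otherAllele))
})

test_that("single-variant score R2 equals its target by construction", {
  specs <- simulateVariants(1, 1, c(0.01, 0.01), seed = 7)
  expect_equal(nrow(specs), 2)
  v <- 2 * specs$eaf[1] * (1 - specs$eaf[1]) * specs$weight[1]^2
  expect_equal(v, 0.01, tolerance = 1e-12)
})

test_that("simulateVariants rejects invalid counts and targets", {
  expect_error(simulateVariants(0, 1, c(0.01, 0.01)), "nBmi")
  expect_error(simulateVariants(5, 2, c(0.3, 0.01)), "r2Targets")
  expect_error(simulateVariants(5, 2, c(0.01)), "r2Targets")
})

test_that("realized score R2 matches the variance-scaling algebra", {
  # Monte-Carlo check of sum(ploidy*eaf*(1-eaf)*w^2) at large n
  specs <- fixSpecsSmall()
  co <- fixCohort(n = 200000, seed = 21, specs = specs)
  for (tr in c("bmi_increasing", "t_decreasing")) {
    idx <- variants(co)$trait == tr
    g <- t(dosages(co))[, idx, drop = FALSE]
    s <- drop(g %*% variants(co)$weight[idx])
    expect_equal(var(s), 0.02, tolerance = 0.1)
  }
})

test_that("cohort moments track the requested profile", {
  specs <- fixSpecsSmall()
  pr <- defaultCohortProfiles()
  params <- structuralParams(seed = 11)
  co <- simulateCohort(specs, n = 50000, params = params, cohort = "MrOS")
  ph <- phenotypes(co)
  expect_gt(mean(ph$bmi), 25.0); expect_lt(mean(ph$bmi), 27.6)
  expect_equal(mean(ph$bmi), 26.3, tolerance = 0.05)
  expect_equal(sd(ph$bmi), 3.6, tolerance = 0.05)
  expect_equal(mean(ph$testosterone), 4.5, tolerance = 0.05)
  expect_equal(sd(ph$testosterone), 1.7, tolerance = 0.05)
  expect_equal(mean(ph$smoking), 0.09, tolerance = 0.05)
  expect_true(all(ph$bmi > 0) && all(ph$testosterone > 0) &&
                all(ph$age > 0))
})

test_that("unknown cohort name is a configuration error", {
  expect_error(simulateCohort(fixSpecsSmall(), n = 100,
                              params = structuralParams(),
                              cohort = "Framingham"),
               "unknown cohort")
})

test_that("null structural model decouples the T score from BMI", {
  specs <- fixSpecsSmall()
  params <- structuralParams(betaCausal = 0, confAgeBmi = 0,
                             confAgeT = 0, confSmokeBmi = 0,
                             confSmokeT = 0, confTimeT = 0, seed = 31)
  co <- simulateCohort(specs, n = 100000, params = params,
                       cohort = "SHIP")
  sT <- scoreValues(weightedScore(co, "t_decreasing"))
  expect_lt(abs(cor(sT, log(phenotypes(co)$bmi))), 0.01)
})

test_that("genotypes are independent of confounders", {
  co <- fixCohort(n = 100000, seed = 41)
  ph <- phenotypes(co)
  s <- scoreValues(weightedScore(co, "bmi_increasing"))
  expect_lt(abs(cor(s, ph$age)), 0.01)
  expect_lt(abs(cor(s, ph$smoking)), 0.01)
})

test_that("dosage bounds respect ploidy, X-linked never exceeding 1", {
  specs <- fixSpecsFull()
  params <- structuralParams(missingRate = 0.05, seed = 5)
  co <- simulateCohort(specs, n = 500, params = params, cohort = "GOOD")
  g <- dosages(co)
  xm <- variants(co)$chromClass == "x_male"
  expect_true(all(g[!xm, ] %in% c(0, 1, 2, NA)))
  expect_true(all(g[xm, ] %in% c(0, 1, NA)))
  expect_gt(sum(is.na(g)), 0)  # missingness was injected
})

test_that("ln-BMI variance decomposes into score + confounder + noise", {
  specs <- fixSpecsSmall()
  params <- structuralParams(seed = 17)
  co <- simulateCohort(specs, n = 200000, params = params,
                       cohort = "Inter99")
  lb <- log(phenotypes(co)$bmi)
  idx <- variants(co)$trait == "bmi_increasing"
  s <- drop(t(dosages(co))[, idx] %*% variants(co)$weight[idx])
  sdlog <- sqrt(log(1 + (4.0 / 26.8)^2))
  # components on the native ln scale: score, age, smoking, noise
  expect_equal(var(lb),
               sdlog^2 * (0.02 + 0.1^2 + 0.1^2 +
                            (1 - 0.02 - 0.1^2 - 0.1^2)),
               tolerance = 0.02)
  expect_equal(var(s) * sdlog^2 / var(lb), 0.02, tolerance = 0.05)
})

test_that("identical seed and params give bit-identical cohorts", {
  a <- fixCohort(n = 300, seed = 99)
  b <- fixCohort(n = 300, seed = 99)
  expect_identical(dosages(a), dosages(b))
  expect_identical(as.data.frame(phenotypes(a)),
                   as.data.frame(phenotypes(b)))
  c2 <- fixCohort(n = 300, seed = 100)
  expect_false(identical(dosages(a), dosages(c2)))
})

test_that("default study reproduces the five-cohort design", {
  study <- simulateStudy(structuralParams(seed = 2))
  expect_named(study, c("GOOD", "MrOS", "SHIP", "SHIP-Trend", "Inter99"))
  ns <- vapply(study, ncol, integer(1))
  expect_equal(unname(ns), c(929L, 1682L, 1912L, 427L, 2496L))
  expect_equal(sum(ns), 7446L)
})

test_that("dropVariantCohort removes one BMI variant from one cohort", {
  params <- structuralParams(seed = 2, dropVariantCohort = "Inter99",
                             nBmiVariants = 10L)
  study <- simulateStudy(params)
  expect_equal(sum(variants(study$Inter99)$trait == "bmi_increasing"), 9)
  expect_equal(sum(variants(study$GOOD)$trait == "bmi_increasing"), 10)
})

test_that("single-profile study degenerates to one cohort", {
  params <- structuralParams(cohortProfiles = defaultCohortProfiles()[1, ],
                             nBmiVariants = 5L, nTVariants = 2L, seed = 3)
  study <- simulateStudy(params)
  expect_length(study, 1)
  expect_equal(ncol(study$GOOD), 929L)
})

test_that("heterogeneitySd spreads the observational slope across cohorts", {
  # replicate small studies and compare the between-cohort slope variance
  # with and without heterogeneity
  specs <- fixSpecsSmall()
  slopeSpread <- function(het, seeds) {
    vapply(seeds, function(s) {
      pr <- defaultCohortProfiles()
      pr$n <- rep(1500L, 5)
      params <- structuralParams(heterogeneitySd = het, seed = s,
                                 cohortProfiles = pr)
      study <- simulateStudy(params, specs)
      slopes <- vapply(study, function(co) {
        z <- fixZ(co)
        estimate(associate(zValues(z$bmi), z$t))
      }, numeric(1))
      var(slopes)
    }, numeric(1))
  }
  v0 <- mean(slopeSpread(0, 1:12))
  v1 <- mean(slopeSpread(0.15, 1:12))
  # added between-cohort variance should be close to 0.15^2 = 0.0225
  expect_gt(v1 - v0, 0.0225 * 0.4)
  expect_lt(v1 - v0, 0.0225 * 2.5)
})

test_that("scrambleAlleles preserves information and flags orientation", {
  co <- fixCohort(n = 200, seed = 5)
  sc <- scrambleAlleles(co, prob = 0.5, seed = 8)
  rd <- variants(sc)
  flipped <- rd$countedAllele != rd$effectAllele
  expect_gt(sum(flipped), 0)
  lim <- ifelse(rd$chromClass == "x_male", 1, 2)
  expect_equal(dosages(sc)[flipped, ],
               lim[flipped] - dosages(co)[flipped, ])
  expect_identical(dosages(sc)[!flipped, ], dosages(co)[!flipped, ])
})

test_that("structuralParams validates its ranges", {
  expect_error(structuralParams(r2GrsBmi = 0.5), "r2")
  expect_error(structuralParams(missingRate = 1.2), "missingRate")
  pr <- defaultCohortProfiles(); pr$tSd[1] <- -1
  expect_error(structuralParams(cohortProfiles = pr), "SD")
})
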