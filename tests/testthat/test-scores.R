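# Risk-score construction: harmonization, weighted/unweighted scores,
# missing-data and absent-variant policies, scale conventions.

test_that("harmonization flips complementary dosages and is idempotent", {
  co <- fixTinyCohort()
  rd <- variants(co)
  rd$countedAllele[1] <- rd$otherAllele[1]   # rsA now counted on other
  g <- dosages(co)
  g[1, ] <- 2 - g[1, ]
  sc <- MRCohort(t(g), rd, as.data.frame(phenotypes(co)))
  h <- harmonizeDosages(sc)
  expect_equal(dosages(h), dosages(co))       # complement identity
  expect_identical(dosages(harmonizeDosages(h)), dosages(h)) # idempotent
  expect_true(all(variants(h)$countedAllele == variants(h)$effectAllele))
})

test_that("a counted allele matching neither spec allele names the variant", {
  co <- fixTinyCohort()
  rd <- variants(co)
  rd$countedAllele[2] <- "X"
  expect_error(MRCohort(t(dosages(co)), rd,
                        as.data.frame(phenotypes(co))),
               "rsB")
})

test_that("scramble/harmonize round-trip leaves scores unchanged", {
  co <- fixCohort(n = 500, seed = 13)
  h <- harmonizeDosages(scrambleAlleles(co, prob = 0.6, seed = 3))
  for (tr in c("bmi_increasing", "t_decreasing")) {
    expect_equal(scoreValues(weightedScore(h, tr)),
                 scoreValues(weightedScore(co, tr)))
    expect_equal(scoreValues(unweightedScore(h, tr)),
                 scoreValues(unweightedScore(co, tr)))
  }
})

test_that("unweighted score is the plain dosage sum", {
  co <- fixTinyCohort()
  s <- unweightedScore(co, "bmi_increasing")
  expect_equal(unname(scoreValues(s)),
               unname(colSums(dosages(co))))
  expect_equal(unname(scoreValues(s))[1], 3)  # dosages (2, 1, 0)
})

test_that("scores with zero dosages are zero regardless of weights", {
  co <- fixTinyCohort()
  g <- dosages(co) * 0
  z <- MRCohort(t(g), variants(co), as.data.frame(phenotypes(co)))
  expect_equal(unname(scoreValues(weightedScore(z, "bmi_increasing",
                                                rescale = FALSE))),
               rep(0, 4))
})

test_that("equal weights make the rescaled weighted score unweighted", {
  co <- fixCohort(n = 300, seed = 23)
  rd <- variants(co)
  rd$weight <- rep(0.05, nrow(rd))
  eq <- MRCohort(t(dosages(co)), rd, as.data.frame(phenotypes(co)))
  expect_equal(scoreValues(weightedScore(eq, "bmi_increasing",
                                         rescale = TRUE)),
               scoreValues(unweightedScore(eq, "bmi_increasing")))
})

test_that("97-variant scores sit on the allele-count scale", {
  # with mean effect-allele frequency ~0.47 the unweighted score mean is
  # ~2 * 0.47 * 97 ~ 91 and the rescaled weighted mean is close by
  set.seed(42)
  eaf <- pmin(pmax(rnorm(100, 0.47, 0.15), 0.1), 0.9)
  specs <- fixSpecsFull()
  specs$eaf <- eaf
  params <- structuralParams(seed = 12,
                             cohortProfiles = defaultCohortProfiles()[2, ])
  co <- simulateCohort(specs, n = 20000, params = params, cohort = "MrOS")
  su <- scoreValues(unweightedScore(co, "bmi_increasing"))
  sw <- scoreValues(weightedScore(co, "bmi_increasing"))
  expTotal <- sum(2 * specs$eaf[specs$trait == "bmi_increasing"])
  expect_equal(mean(su), expTotal, tolerance = 0.01)
  expect_equal(mean(su), 91, tolerance = 0.03)
  expect_gt(mean(sw), 85); expect_lt(mean(sw), 95)
  expect_gt(sd(sw), 4); expect_lt(sd(sw), 9)
})

test_that("impute_eaf contributes the Hardy-Weinberg expectation", {
  co <- fixTinyCohort()
  g <- dosages(co)
  g["rsA", "id1"] <- NA   # eaf 0.25, autosomal -> contributes 0.5
  m <- MRCohort(t(g), variants(co), as.data.frame(phenotypes(co)))
  s <- unweightedScore(m, "bmi_increasing", missingPolicy = "impute_eaf")
  expect_equal(unname(scoreValues(s)["id1"]), 1 + 0 + 0.5)
  so <- unweightedScore(m, "bmi_increasing", missingPolicy = "omit")
  expect_equal(unname(scoreValues(so)["id1"]), 1)
  expect_equal(so@nVariantsUsed[1], 2L)
})

test_that("impute_eaf leaves the large-sample score mean unchanged", {
  specs <- fixSpecsSmall()
  co <- fixCohort(n = 50000, seed = 77, specs = specs)
  full <- mean(scoreValues(unweightedScore(co, "bmi_increasing")))
  gm <- dosages(co)
  set.seed(5)
  gm[sample(length(gm), round(0.1 * length(gm)))] <- NA
  miss <- MRCohort(t(gm), variants(co), as.data.frame(phenotypes(co)))
  imp <- mean(scoreValues(unweightedScore(miss, "bmi_increasing",
                                          missingPolicy = "impute_eaf")))
  expect_equal(imp, full, tolerance = 0.005)
})

test_that("absent variants are omitted without rescaling by default", {
  co <- fixCohort(n = 400, seed = 31)
  specsAll <- variants(co)
  sub <- co[-1, ]   # drop the first variant from the matrix entirely
  sFull <- unweightedScore(co, "bmi_increasing")
  sSub <- unweightedScore(sub, "bmi_increasing", specs = specsAll)
  dropped <- dosages(co)[1, ]
  expect_equal(scoreValues(sFull) - scoreValues(sSub), dropped)
  # opt-in proportional rescale
  nB <- sum(specsAll$trait == "bmi_increasing")
  sRe <- unweightedScore(sub, "bmi_increasing", specs = specsAll,
                         absentPolicy = "rescale")
  expect_equal(scoreValues(sRe),
               scoreValues(sSub) * nB / (nB - 1))
})

test_that("x-linked dosage can be doubled for sensitivity analysis", {
  co <- fixCohort(n = 200, seed = 51, specs = fixSpecsFull())
  xm <- variants(co)$chromClass == "x_male"
  expect_true(any(xm & variants(co)$trait == "t_decreasing"))
  a <- scoreValues(unweightedScore(co, "t_decreasing"))
  b <- scoreValues(unweightedScore(co, "t_decreasing",
                                   xDoseScale = "doubled"))
  extra <- colSums(dosages(co)[xm & variants(co)$trait == "t_decreasing",
                               , drop = FALSE])
  expect_equal(b - a, extra)
})

test_that("scores have no cross-individual coupling", {
  co <- fixCohort(n = 100, seed = 61)
  s <- scoreValues(weightedScore(co, "bmi_increasing"))
  first <- co[, 1:40]
  s40 <- scoreValues(weightedScore(first, "bmi_increasing"))
  expect_equal(s[1:40], s40)
})

test_that("weighted and unweighted scores are strongly rank-correlated", {
  co <- fixCohort(n = 5000, seed = 71, specs = fixSpecsFull())
  w <- scoreValues(weightedScore(co, "bmi_increasing"))
  u <- scoreValues(unweightedScore(co, "bmi_increasing"))
  expect_gt(cor(w, u, method = "spearman"), 0.9)
})

test_that("degenerate score inputs are rejected", {
  co <- fixTinyCohort()
  rd <- variants(co)
  rd$weight <- 0
  z <- MRCohort(t(dosages(co)), rd, as.data.frame(phenotypes(co)))
  expect_error(weightedScore(z, "bmi_increasing"), "all-zero")
  expect_error(unweightedScore(co, "t_decreasing"), "no variants")
})
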