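# Shared fixtures: small simulated objects reused across test files.
# All are deterministic (fixed seeds) and built in code at test time.

fixSpecsSmall <- function(seed = 3) {
  simulateVariants(5, 2, c(0.02, 0.02), seed = seed)
}

fixSpecsFull <- function(seed = 1) {
  simulateVariants(97, 3, c(0.019, 0.025), seed = seed)
}

# single mid-sized cohort with the MrOS-like profile
fixCohort <- function(n = 2000, seed = 11, beta = -0.25, specs = NULL,
                      ...) {
  if (is.null(specs)) specs <- fixSpecsSmall()
  params <- structuralParams(betaCausal = beta,
                             cohortProfiles = defaultCohortProfiles()[2, ],
                             seed = seed, ...)
  simulateCohort(specs, n = n, params = params, cohort = "MrOS")
}

# per-cohort standardized traits with the standard adjustment sets
fixZ <- function(cohort) {
  ph <- phenotypes(cohort)
  list(bmi = standardizePhenotype("bmi", ph, c("age", "smoking"),
                                  logTransform = TRUE,
                                  phenotypeName = "lnBMI"),
       t = standardizePhenotype("testosterone", ph,
                                c("age", "smoking", "samplingTime")))
}

# tiny hand-built cohort for exact arithmetic checks
fixTinyCohort <- function() {
  specs <- variantSpecs(rsid = c("rsA", "rsB", "rsC"),
                        chromClass = c("autosomal", "autosomal", "x_male"),
                        effectAllele = c("A", "C", "G"),
                        otherAllele = c("G", "T", "A"),
                        weight = c(0.1, 0.2, 0.3),
                        eaf = c(0.25, 0.5, 0.4),
                        trait = "bmi_increasing")
  g <- matrix(c(2, 1, 0,
                1, 0, 1,
                0, 2, 1,
                2, 2, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("id", 1:4),
                              c("rsA", "rsB", "rsC")))
  ph <- data.frame(bmi = c(24, 28, 31, 26),
                   testosterone = c(5.2, 4.1, 3.3, 4.8),
                   age = c(45, 52, 61, 38), smoking = c(0, 1, 0, 1))
  MRCohort(g, specs, ph)
}
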