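#' @include AllClasses.R AllGenerics.R simulate.R scores.R standardize.R
#'   diagnostics.R mr.R meta.R power.R io.R
NULL

#' Assemble an analysis configuration
#'
#' Exactly one data source must be given: a simulation block (a
#' [StructuralParams-class], the default) or a `paths` list pointing at
#' on-disk TSV inputs (`variants` plus, per cohort, `dosages` and
#' `phenotypes`).
#'
#' @param simulation A [StructuralParams-class], or `NULL` when reading
#'   real inputs.
#' @param paths `NULL`, or a list with elements `variants` (one TSV) and
#'   `cohorts` (named list; each element a list with `dosages` and
#'   `phenotypes` paths).
#' @param alpha Two-sided significance level used throughout.
#' @param metaPolicy `"auto"` (Q-test-guided, default), `"fixed"` or
#'   `"random"`.
#' @param missingPolicy Risk-score missing-dosage policy.
#' @param bmiFrom,bmiTo Clinical BMI interval for the translation.
#' @param powerBeta Effect size for the power section; `NULL` uses the
#'   observed pooled observational slope magnitude.
#' @param seed Seed recorded in every output; defaults to the simulation
#'   block's seed.
#' @return A classed list (`"bidirmrConfig"`).
#' @export
analysisConfig <- function(simulation = structuralParams(), paths = NULL,
                           alpha = 0.05,
                           metaPolicy = c("auto", "fixed", "random"),
                           missingPolicy = c("impute_eaf", "omit"),
                           bmiFrom = 30, bmiTo = 25, powerBeta = NULL,
                           seed = NULL) {
  metaPolicy <- match.arg(metaPolicy)
  missingPolicy <- match.arg(missingPolicy)
  if (is.null(simulation) == is.null(paths))
    stop("exactly one of 'simulation' or 'paths' must be given")
  if (is.null(seed))
    seed <- if (!is.null(simulation)) simulation@seed else 1L
  structure(list(simulation = simulation, paths = paths, alpha = alpha,
                 metaPolicy = metaPolicy, missingPolicy = missingPolicy,
                 bmiFrom = bmiFrom, bmiTo = bmiTo, powerBeta = powerBeta,
                 seed = as.integer(seed)),
            class = "bidirmrConfig")
}

#' Read an analysis configuration from a YAML file
#'
#' Supports a `simulation:` block whose keys are
#' [structuralParams()] arguments (plus optional `cohortProfiles` as a
#' list of per-cohort records) or a `paths:` block, alongside any
#' top-level [analysisConfig()] options.
#'
#' @param path YAML file path.
#' @return An [analysisConfig()] list.
#' @export
readAnalysisConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    sb <- y$simulation
    if (!is.null(sb$cohortProfiles))
      sb$cohortProfiles <- do.call(rbind,
                                   lapply(sb$cohortProfiles, as.data.frame))
    sim <- do.call(structuralParams, sb)
  }
  opts <- y[setdiff(names(y), c("simulation", "paths"))]
  do.call(analysisConfig,
          c(list(simulation = sim, paths = y$paths), opts))
}

.configHash <- function(config) {
  raw <- serialize(unclass(config), NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * rep_len(c(1L, 3L, 7L, 31L),
                                                length(raw))) %%
            .Machine$integer.max)
}

.metaBy <- function(betas, ses, policy, alpha) {
  switch(policy,
         auto = modelSelect(betas, ses, alpha = alpha),
         fixed = fixedMeta(betas, ses),
         random = if (length(betas) >= 2) randomMeta(betas, ses)
                  else fixedMeta(betas, ses))
}

.loadStudy <- function(config) {
  if (!is.null(config$paths)) {
    p <- config$paths
    if (is.null(p$variants) || is.null(p$cohorts))
      stop("paths config must name 'variants' and 'cohorts'")
    need <- c(p$variants,
              unlist(lapply(p$cohorts, function(co)
                c(co$dosages, co$phenotypes))))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("input file(s) not found: ", paste(miss, collapse = ", "))
    out <- lapply(names(p$cohorts), function(nm)
      readCohort(p$variants, p$cohorts[[nm]]$dosages,
                 p$cohorts[[nm]]$phenotypes, cohort = nm))
    names(out) <- names(p$cohorts)
    out
  } else {
    simulateStudy(config$simulation)
  }
}

.cohortZ <- function(co) {
  ph <- phenotypes(co)
  list(
    bmi = standardizePhenotype("bmi", ph,
                               adjustmentSet = c("age", "smoking"),
                               logTransform = TRUE,
                               phenotypeName = "lnBMI"),
    t = standardizePhenotype("testosterone", ph,
                             adjustmentSet = c("age", "smoking",
                                               "samplingTime")))
}

.instrumentGrid <- function() {
  expand.grid(weighted = c(TRUE, FALSE),
              direction = c("bmi_to_t", "t_to_bmi"),
              stringsAsFactors = FALSE)
}

.instLabel <- function(weighted, direction) {
  paste0(if (weighted) "w" else "uw", "GRS_",
         if (direction == "bmi_to_t") "BMI" else "T")
}

#' Run the full bi-directional MR study
#'
#' Orchestrates every stage on simulated or on-disk data: harmonization;
#' per-cohort and pooled Z-score standardization; the four risk scores
#' (weighted/unweighted for each trait); instrument diagnostics;
#' observational estimates per cohort, meta-analyzed and pooled; IV
#' estimates in both directions per cohort, meta-analyzed and pooled;
#' SHBG-adjusted variants; the independent-instrument split; the
#' observational-versus-IV comparison; the percent-change translation
#' over the configured BMI interval; and the analytic power section.
#'
#' With `outputDir` set, every table is written as TSV alongside a
#' human-readable `report.txt`, forest plots, and a `manifest.json`
#' recording package version, seed and a configuration hash. On a stage
#' failure an `error_manifest.json` is written there before the error
#' propagates.
#'
#' @param config An [analysisConfig()] (default: the standard simulated
#'   five-cohort study).
#' @param outputDir Optional directory for the report bundle.
#' @param verbose Log stage progress with `message()`.
#' @return Invisibly, a list with elements `cohorts`, `diagnostics`,
#'   `observational`, `iv`, `table2`, `shbgAdjusted`, `split`,
#'   `obsVsIv`, `translation`, `power`, `manifest`.
#' @export
runFullStudy <- function(config = analysisConfig(), outputDir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  runStage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outputDir)) {
        dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
        jsonlite::write_json(
          list(status = "error", stage = name,
               message = conditionMessage(e)),
          file.path(outputDir, "error_manifest.json"), auto_unbox = TRUE)
      }
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  alpha <- config$alpha

  say("loading data")
  cohorts <- runStage("load", .loadStudy(config))
  cohorts <- runStage("harmonize", lapply(cohorts, harmonizeDosages))

  say("standardizing phenotypes per cohort")
  zs <- runStage("standardize", lapply(cohorts, .cohortZ))

  say("pooling cohorts")
  pooled <- runStage("pool", combineCohorts(cohorts))
  phP <- phenotypes(pooled)
  zP <- runStage("standardize_pooled", list(
    bmi = standardizePhenotype("bmi", phP,
                               adjustmentSet = c("age", "smoking",
                                                 "cohort"),
                               logTransform = TRUE,
                               phenotypeName = "lnBMI"),
    t = standardizePhenotype("testosterone", phP,
                             adjustmentSet = c("age", "smoking",
                                               "cohort",
                                               "samplingTime"))))
  hasShbg <- "shbg" %in% colnames(phP) && !all(is.na(phP$shbg))
  if (hasShbg)
    zP$shbg <- standardizePhenotype("shbg", phP,
                                    adjustmentSet = c("age", "smoking",
                                                      "cohort",
                                                      "samplingTime"))

  say("computing risk scores")
  scoreFor <- function(co, weighted, trait)
    if (weighted) weightedScore(co, trait,
                                missingPolicy = config$missingPolicy)
    else unweightedScore(co, trait, missingPolicy = config$missingPolicy)

  say("instrument diagnostics (pooled)")
  diagnostics <- runStage("diagnostics", {
    combos <- expand.grid(weighted = c(TRUE, FALSE),
                          trait = c("bmi_increasing", "t_decreasing"),
                          stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(combos)), function(i) {
      tr <- combos$trait[i]
      sc <- scoreFor(pooled, combos$weighted[i], tr)
      zTrait <- if (tr == "bmi_increasing") zP$bmi else zP$t
      diagnosticsReport(pooled, sc, zTrait, alpha = alpha)
    })
    names(out) <- vapply(seq_len(nrow(combos)), function(i)
      .instLabel(combos$weighted[i],
                 if (combos$trait[i] == "bmi_increasing") "bmi_to_t"
                 else "t_to_bmi"), character(1))
    out
  })

  say("observational estimates")
  observational <- runStage("observational", {
    perCohort <- lapply(names(cohorts), function(nm)
      associate(zValues(zs[[nm]]$bmi), zs[[nm]]$t,
                label = paste0(nm, ": T ~ lnBMI")))
    names(perCohort) <- names(cohorts)
    betas <- vapply(perCohort, estimate, numeric(1))
    ses <- vapply(perCohort, stdError, numeric(1))
    list(perCohort = perCohort,
         meta = .metaBy(betas, ses, config$metaPolicy, alpha),
         pooled = associate(zValues(zP$bmi), zP$t,
                            label = "pooled: T ~ lnBMI"))
  })

  say("IV estimation per cohort, meta, pooled")
  iv <- runStage("iv", {
    grid <- .instrumentGrid()
    out <- lapply(seq_len(nrow(grid)), function(i) {
      wtd <- grid$weighted[i]; dir <- grid$direction[i]
      tr <- if (dir == "bmi_to_t") "bmi_increasing" else "t_decreasing"
      inst <- .instLabel(wtd, dir)
      ## small cohorts can have an unusably weak first stage; they are
      ## dropped from the cohort-level meta-analysis (the pooled fit
      ## below always uses everyone)
      perCohort <- lapply(names(cohorts), function(nm) {
        sc <- scoreFor(cohorts[[nm]], wtd, tr)
        ex <- if (dir == "bmi_to_t") zs[[nm]]$bmi else zs[[nm]]$t
        ou <- if (dir == "bmi_to_t") zs[[nm]]$t else zs[[nm]]$bmi
        tryCatch(
          tsls(sc, ex, ou, direction = dir,
               instrument = paste0(inst, "@", nm)),
          error = function(e) {
            message(inst, ": cohort ", nm,
                    " dropped from the meta-analysis (",
                    conditionMessage(e), ")")
            NULL
          })
      })
      names(perCohort) <- names(cohorts)
      perCohort <- perCohort[!vapply(perCohort, is.null, logical(1))]
      if (!length(perCohort))
        stop("no cohort yielded a usable IV fit for ", inst)
      betas <- vapply(perCohort, estimate, numeric(1))
      ses <- vapply(perCohort, stdError, numeric(1))
      scP <- scoreFor(pooled, wtd, tr)
      ex <- if (dir == "bmi_to_t") zP$bmi else zP$t
      ou <- if (dir == "bmi_to_t") zP$t else zP$bmi
      assocExp <- associate(scP, ex)
      assocOut <- associate(scP, ou)
      list(instrument = inst, weighted = wtd, direction = dir,
           perCohort = perCohort,
           meta = .metaBy(betas, ses, config$metaPolicy, alpha),
           assocExposure = assocExp, assocOutcome = assocOut,
           wald = waldRatio(assocOut, assocExp, direction = dir,
                            instrument = inst),
           pooled = tsls(scP, ex, ou, direction = dir,
                         instrument = inst))
    })
    names(out) <- vapply(out, `[[`, "", "instrument")
    out
  })

  table2 <- runStage("table2", {
    do.call(rbind, lapply(iv, function(r) {
      ciE <- confInt(r$assocExposure); ciO <- confInt(r$assocOutcome)
      data.frame(
        instrument = r$instrument,
        coefIntermediate = estimate(r$assocExposure),
        coefIntermediateLow = ciE[1], coefIntermediateHigh = ciE[2],
        coefOutcome = estimate(r$assocOutcome),
        coefOutcomeLow = ciO[1], coefOutcomeHigh = ciO[2],
        ivRatio = estimate(r$pooled),
        ivLow = confInt(r$pooled)[1], ivHigh = confInt(r$pooled)[2],
        p = pValue(r$pooled),
        units = ivUnits(r$pooled),
        row.names = NULL)
    }))
  })

  say("SHBG-adjusted IV variants")
  shbgAdjusted <- runStage("shbg", {
    if (!hasShbg) {
      message("SHBG entirely missing; SHBG-adjusted analyses skipped")
      NULL
    } else {
      scP <- scoreFor(pooled, TRUE, "bmi_increasing")
      list(
        tAdjShbg = adjustedIV(scP, zP$bmi, zP$t, zP$shbg,
                              adjustName = "shbg",
                              direction = "bmi_to_t",
                              instrument = "wGRS_BMI"),
        shbgAdjT = adjustedIV(scP, zP$bmi, zP$shbg, zP$t,
                              adjustName = "testosterone",
                              direction = "bmi_to_t",
                              instrument = "wGRS_BMI"))
    }
  })

  say("independent-instrument split")
  split <- runStage("split", {
    rd <- rowData(pooled)
    bmi <- rd[rd$trait == "bmi_increasing", ]
    if (nrow(bmi) >= 2) {
      ## lead locus (largest weight) versus the remaining variants; a
      ## lead SNP too weak to serve as a lone instrument is reported as
      ## a skipped analysis rather than a failure
      leadId <- bmi$rsid[which.max(bmi$weight)]
      tryCatch(
        instrumentSplit(pooled,
                        partition = list(leadId,
                                         setdiff(bmi$rsid, leadId)),
                        exposure = zP$bmi, outcome = zP$t,
                        direction = "bmi_to_t"),
        error = function(e) {
          message("instrument split skipped: ", conditionMessage(e))
          NULL
        })
    } else NULL
  })

  obsVsIv <- runStage("obs_vs_iv", {
    vapply(c("wGRS_BMI", "uwGRS_BMI"), function(inst)
      obsVsIV(observational$pooled, iv[[inst]]$pooled), numeric(1))
  })

  say("clinical translation")
  translation <- runStage("translate", {
    cc <- !is.na(phP$testosterone) & !is.na(phP$bmi)
    sdT <- stats::sd(phP$testosterone[cc])
    sdLB <- stats::sd(log(phP$bmi[cc]))
    tPred <- predictedTestosterone(phP, bmiAt = config$bmiFrom)
    lst <- lapply(c("wGRS_BMI", "uwGRS_BMI"), function(inst)
      translateToPercent(iv[[inst]]$pooled, sdT, sdLB, tPred,
                         bmiFrom = config$bmiFrom,
                         bmiTo = config$bmiTo))
    names(lst) <- c("wGRS_BMI", "uwGRS_BMI")
    lst$observational <- translateToPercent(
      estimate(observational$pooled), sdT, sdLB, tPred,
      bmiFrom = config$bmiFrom, bmiTo = config$bmiTo)
    lst$moments <- c(sdT = sdT, sdLogBmi = sdLB, tPredAtFrom = tPred)
    lst
  })

  say("power section")
  power <- runStage("power", {
    n <- sum(vapply(cohorts, ncol, integer(1)))
    betaPw <- if (is.null(config$powerBeta))
      abs(estimate(observational$pooled)) else config$powerBeta
    r2B <- rSquared(diagnostics$wGRS_BMI$assoc)
    r2T <- rSquared(diagnostics$wGRS_T$assoc)
    list(bmiDirection = ivPower(n, r2B, betaPw, alpha),
         tDirection = ivPower(n, r2T, betaPw, alpha),
         halfEffectBmi = halfEffectPower(n, r2B, betaPw, alpha),
         halfEffectT = halfEffectPower(n, r2T, betaPw, alpha))
  })

  manifest <- list(
    package = "BiDirMR",
    version = as.character(utils::packageVersion("BiDirMR")),
    seed = config$seed,
    configHash = .configHash(config),
    nCohorts = length(cohorts),
    nIndividuals = sum(vapply(cohorts, ncol, integer(1))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  bundle <- list(cohorts = cohorts, diagnostics = diagnostics,
                 observational = observational, iv = iv,
                 table2 = table2, shbgAdjusted = shbgAdjusted,
                 split = split, obsVsIv = obsVsIv,
                 translation = translation, power = power,
                 manifest = manifest)
  if (!is.null(outputDir))
    runStage("write", .writeBundle(bundle, config, outputDir))
  invisible(bundle)
}

.writeBundle <- function(bundle, config, outputDir) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outputDir, f)
  utils::write.table(bundle$table2, p("table2.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  obs <- bundle$observational
  obsDf <- data.frame(
    study = names(obs$perCohort),
    beta = vapply(obs$perCohort, estimate, numeric(1)),
    se = vapply(obs$perCohort, stdError, numeric(1)),
    p = vapply(obs$perCohort, pValue, numeric(1)), row.names = NULL)
  utils::write.table(obsDf, p("observational.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  metaDf <- do.call(rbind, lapply(names(bundle$iv), function(nm) {
    m <- bundle$iv[[nm]]$meta
    data.frame(instrument = nm, pooledBeta = estimate(m),
               se = stdError(m), ciLow = confInt(m)[1],
               ciHigh = confInt(m)[2], p = pValue(m), model = m@model,
               qStat = m@qStat, qP = m@qP, iSquared = m@iSquared,
               tauSquared = m@tauSquared, row.names = NULL)
  }))
  utils::write.table(metaDf, p("iv_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  diagDf <- do.call(rbind, lapply(names(bundle$diagnostics),
                                  function(nm) {
    d <- bundle$diagnostics[[nm]]
    data.frame(instrument = nm, beta = estimate(d$assoc),
               se = stdError(d$assoc), p = pValue(d$assoc),
               r2 = rSquared(d$assoc), fStat = d$fStat,
               minConfounderP = if (length(d$confounderP))
                 min(d$confounderP) else NA_real_,
               quadraticP = d$quadraticP,
               nNominalSnps = sum(d$perSnp$nominal, na.rm = TRUE),
               nBonferroniSnps = sum(d$perSnp$bonferroni, na.rm = TRUE),
               row.names = NULL)
  }))
  utils::write.table(diagDf, p("diagnostics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  trDf <- do.call(rbind, lapply(
    setdiff(names(bundle$translation), "moments"), function(nm) {
      tr <- bundle$translation[[nm]]
      data.frame(estimator = nm, percentChange = tr@percentChange,
                 bmiFrom = tr@bmiFrom, bmiTo = tr@bmiTo,
                 ratio = tr@ratio, row.names = NULL)
    }))
  utils::write.table(trDf, p("translation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  pw <- bundle$power
  pwDf <- do.call(rbind, lapply(names(pw), function(nm)
    data.frame(scenario = nm, power = pw[[nm]]@power, n = pw[[nm]]@n,
               r2 = pw[[nm]]@r2Instrument, beta = pw[[nm]]@betaTrue,
               alpha = pw[[nm]]@alpha, row.names = NULL)))
  utils::write.table(pwDf, p("power.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  grDevices::png(p("forest_observational.png"), width = 800,
                 height = 500)
  forestPlot(obsDf, obs$meta,
             xlab = "SD testosterone per SD ln BMI",
             main = "Observational estimates")
  grDevices::dev.off()
  grDevices::png(p("forest_iv_bmi_to_t.png"), width = 800, height = 500)
  ivB <- bundle$iv$wGRS_BMI
  forestPlot(data.frame(study = names(ivB$perCohort),
                        beta = vapply(ivB$perCohort, estimate,
                                      numeric(1)),
                        se = vapply(ivB$perCohort, stdError,
                                    numeric(1))),
             ivB$meta, xlab = "SD testosterone per SD ln BMI",
             main = "IV estimates (wGRS_BMI)")
  grDevices::dev.off()
  grDevices::png(p("power_curve.png"), width = 700, height = 500)
  powerCurve(bundle$power$bmiDirection@n,
             c(bundle$power$bmiDirection@r2Instrument,
               bundle$power$tDirection@r2Instrument))
  grDevices::dev.off()

  rep <- c(
    "Bi-directional Mendelian randomization report",
    strrep("=", 46), "",
    sprintf("Cohorts: %d, individuals: %d, seed: %d",
            bundle$manifest$nCohorts, bundle$manifest$nIndividuals,
            config$seed), "",
    "Observational (pooled): ",
    sprintf("  %.3f SD T per SD lnBMI (p = %.2g)",
            estimate(obs$pooled), pValue(obs$pooled)), "",
    "IV estimates (pooled 2SLS):",
    vapply(bundle$iv, function(r)
      sprintf("  %-9s ratio %+ .3f (95%% CI %+.3f to %+.3f), p = %.2g [%s]",
              r$instrument, estimate(r$pooled), confInt(r$pooled)[1],
              confInt(r$pooled)[2], pValue(r$pooled),
              ivUnits(r$pooled)), character(1)), "",
    sprintf("BMI %g -> %g translation: %s", config$bmiFrom, config$bmiTo,
            paste(vapply(setdiff(names(bundle$translation), "moments"),
                         function(nm) sprintf("%s %+.1f%%", nm,
                           bundle$translation[[nm]]@percentChange),
                         character(1)), collapse = ", ")), "",
    sprintf("Power at observed effect: BMI-direction %.0f%%, T-direction %.0f%%",
            100 * pw$bmiDirection@power, 100 * pw$tDirection@power))
  writeLines(rep, p("report.txt"))
  jsonlite::write_json(c(bundle$manifest, list(status = "ok")),
                       p("manifest.json"), auto_unbox = TRUE)
  invisible(outputDir)
}
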