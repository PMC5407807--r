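#' @include AllClasses.R AllGenerics.R
NULL

## file-facing column names are snake_case (GWAS-summary convention);
## in-memory names are camelCase
.VARIANT_FILE_COLS <- c(rsid = "rsid", chromClass = "chrom_class",
                        effectAllele = "effect_allele",
                        otherAllele = "other_allele", weight = "weight",
                        eaf = "eaf", trait = "trait",
                        countedAllele = "counted_allele")

#' Read and write the plain-text interchange formats
#'
#' Variant weight tables are GWAS-summary-style TSV (`rsid`,
#' `chrom_class`, `effect_allele`, `other_allele`, `weight`, `eaf`,
#' `trait`, optional `counted_allele`); dosage matrices are TSV with
#' individuals in rows (first column `individual_id`, one column per
#' rsID, missing as `NA`); phenotype tables are TSV with named columns.
#' A minimal VCF dialect with a per-genotype `DS` (dosage) field is
#' supported for genotype exchange.
#'
#' @param specs,x,path,score,z See the individual functions.
#' @name io
NULL

#' @rdname io
#' @param specs A variant `DataFrame` ([variantSpecs()]).
#' @param path File path.
#' @export
writeVariantTable <- function(specs, path) {
  specs <- .asVariantSpecs(specs)
  df <- as.data.frame(specs)
  colnames(df) <- .VARIANT_FILE_COLS[colnames(df)]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  back <- stats::setNames(names(.VARIANT_FILE_COLS), .VARIANT_FILE_COLS)
  known <- colnames(df) %in% names(back)
  colnames(df)[known] <- back[colnames(df)[known]]
  .asVariantSpecs(df)
}

#' @rdname io
#' @param x An [MRCohort-class].
#' @export
writeDosageTable <- function(x, path) {
  g <- t(assay(x, "dosage"))
  df <- data.frame(individual_id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
readDosageTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "individual_id")
    stop("dosage TSV must start with an 'individual_id' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$individual_id
  m
}

#' @rdname io
#' @export
writePhenotypeTable <- function(x, path) {
  ph <- as.data.frame(if (is(x, "MRCohort")) phenotypes(x) else x)
  df <- data.frame(individual_id = rownames(ph), ph, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
readPhenotypeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("individual_id" %in% colnames(df)) {
    rownames(df) <- df$individual_id
    df$individual_id <- NULL
  }
  df
}

#' @rdname io
#' @param variantFile,dosageFile,phenotypeFile Paths to the three TSV
#'   components of one cohort.
#' @param cohort Optional cohort label override.
#' @export
readCohort <- function(variantFile, dosageFile, phenotypeFile,
                       cohort = NULL) {
  for (f in c(variantFile, dosageFile, phenotypeFile))
    if (!file.exists(f)) stop("input file not found: ", f)
  specs <- readVariantTable(variantFile)
  g <- readDosageTable(dosageFile)
  ph <- readPhenotypeTable(phenotypeFile)
  g <- g[rownames(ph), specs$rsid, drop = FALSE]
  MRCohort(g, specs, ph, cohort = cohort)
}

#' @rdname io
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the cohort name.
#' @export
writeCohort <- function(x, dir, prefix = cohortName(x)) {
  stopifnot(is(x, "MRCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(s) file.path(dir, paste0(prefix, "_", s, ".tsv"))
  writeVariantTable(rowData(x), p("variants"))
  writeDosageTable(x, p("dosages"))
  writePhenotypeTable(x, p("phenotypes"))
  invisible(dir)
}

#' @rdname io
#' @param score A [RiskScore-class].
#' @export
writeScoreTable <- function(score, path) {
  df <- data.frame(individual_id = names(scoreValues(score)),
                   score = unname(scoreValues(score)),
                   n_variants_used = score@nVariantsUsed)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param z A [StandardizedPhenotype-class].
#' @export
writeZScoreTable <- function(z, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s (transform: %s) adjusted for: %s",
                     z@phenotypeName, z@transform,
                     if (length(z@adjustmentSet))
                       paste(z@adjustmentSet, collapse = ", ")
                     else "(nothing)"), con)
  utils::write.table(
    data.frame(individual_id = names(zValues(z)),
               z = unname(zValues(z))),
    con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname io
#' @export
writeCohortVCF <- function(x, path) {
  stopifnot(is(x, "MRCohort"))
  rd <- rowData(x)
  g <- assay(x, "dosage")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (counted) allele\">",
    "##INFO=<ID=EAF,Number=1,Type=Float,Description=\"Effect allele frequency\">",
    "##INFO=<ID=WEIGHT,Number=1,Type=Float,Description=\"Per-allele weight\">",
    "##INFO=<ID=TRAIT,Number=1,Type=String,Description=\"Instrumented trait\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(x)), collapse = "\t")), con)
  chrom <- ifelse(rd$chromClass == "x_male", "X", "1")
  alt <- rd$countedAllele
  ref <- ifelse(alt == rd$effectAllele, rd$otherAllele, rd$effectAllele)
  for (i in seq_len(nrow(g))) {
    ds <- ifelse(is.na(g[i, ]), ".", format(g[i, ], trim = TRUE))
    writeLines(paste(c(
      chrom[i], i, rd$rsid[i], ref[i], alt[i], ".", "PASS",
      sprintf("EAF=%g;WEIGHT=%g;TRAIT=%s", rd$eaf[i], rd$weight[i],
              rd$trait[i]),
      "DS", ds), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname io
#' @export
readCohortVCF <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  ids <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  nv <- length(rows)
  info1 <- function(inf, key) {
    m <- regmatches(inf, regexpr(paste0(key, "=[^;]+"), inf))
    sub(paste0(key, "="), "", m)
  }
  rsid <- vapply(rows, `[`, "", 3)
  alt <- vapply(rows, `[`, "", 5)
  ref <- vapply(rows, `[`, "", 4)
  chrom <- vapply(rows, `[`, "", 1)
  inf <- vapply(rows, `[`, "", 8)
  eaf <- as.numeric(vapply(inf, info1, "", key = "EAF"))
  weight <- as.numeric(vapply(inf, info1, "", key = "WEIGHT"))
  trait <- vapply(inf, info1, "", key = "TRAIT")
  g <- t(vapply(rows, function(r) {
    v <- r[-(1:9)]
    suppressWarnings(as.numeric(ifelse(v == ".", NA, v)))
  }, numeric(length(ids))))
  dimnames(g) <- list(rsid, ids)
  ## DS counts ALT; the effect allele is ALT when the file was written
  ## from a harmonized object, but need not be -- record ALT as counted
  specs <- variantSpecs(
    rsid = rsid,
    chromClass = ifelse(chrom %in% c("X", "chrX"), "x_male", "autosomal"),
    effectAllele = alt, otherAllele = ref,
    weight = weight, eaf = eaf, trait = trait)
  list(dosages = t(g), variants = specs)
}
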