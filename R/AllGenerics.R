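#' Accessor generics for BiDirMR result and data classes
#'
#' Small generics shared by the result classes: point estimate, standard
#' error, two-sided p-value, confidence interval, explained variance and
#' sample size, plus accessors for the data containers.
#'
#' @param x An object of one of the BiDirMR S4 classes.
#' @param ... Passed to methods.
#' @return `estimate`, `stdError`, `pValue`, `rSquared`, `sampleSize` return
#'   a single numeric; `confInt` a length-2 numeric `c(lower, upper)`;
#'   `scoreValues` and `zValues` named numeric vectors; `dosages` the
#'   variant-by-individual dosage matrix; `variants` the variant-annotation
#'   `DataFrame`; `phenotypes` the per-individual `DataFrame`; `cohortName`
#'   a character scalar.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("estimate", function(x, ...) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(x, ...) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x, ...) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("rSquared", function(x, ...) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setGeneric("sampleSize", function(x, ...) standardGeneric("sampleSize"))

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x, ...) standardGeneric("scoreValues"))

#' @rdname accessors
#' @export
setGeneric("zValues", function(x, ...) standardGeneric("zValues"))

#' @rdname accessors
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setGeneric("variants", function(x, ...) standardGeneric("variants"))

#' @rdname accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname accessors
#' @export
setGeneric("cohortName", function(x, ...) standardGeneric("cohortName"))

#' @rdname harmonizeDosages
#' @export
setGeneric("harmonizeDosages", function(x, ...) standardGeneric("harmonizeDosages"))
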