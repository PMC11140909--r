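#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' `dosages()`, `variants()`, `populations()`, `nIndividuals()`,
#' `nVariants()` access a [GenotypePanel-class]; `prsWeights()` and
#' `scoreParams()` access a [PRSModel-class]; `setSize()` and
#' `credibleRows()` access a [CredibleSet-class].
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("alleleFrequencies", function(x) standardGeneric("alleleFrequencies"))
#' @rdname accessors
#' @export
setGeneric("prsWeights", function(x) standardGeneric("prsWeights"))
#' @rdname accessors
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))
#' @rdname accessors
#' @export
setGeneric("setSize", function(x) standardGeneric("setSize"))
#' @rdname accessors
#' @export
setGeneric("credibleRows", function(x) standardGeneric("credibleRows"))
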