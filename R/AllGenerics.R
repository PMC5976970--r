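#' Allele frequencies of a genotype tally
#'
#' @param x a [GenotypeCounts-class] object.
#' @return named numeric of length 2, `c(major = ..., minor = ...)`, summing
#'   to 1. Missing individuals are excluded from the denominator.
#' @export
setGeneric("alleleFrequencies", function(x) standardGeneric("alleleFrequencies"))

#' Minor allele frequency
#'
#' @param x a [GenotypeCounts-class] object.
#' @return numeric(1) in [0, 0.5]: the smaller of the two sample allele
#'   frequencies, computed from non-missing individuals.
#' @export
setGeneric("maf", function(x) standardGeneric("maf"))

#' @rdname accessors
#' @export
setGeneric("snpId", function(x) standardGeneric("snpId"))

#' @rdname accessors
#' @export
setGeneric("alleleMajor", function(x) standardGeneric("alleleMajor"))

#' @rdname accessors
#' @export
setGeneric("alleleMinor", function(x) standardGeneric("alleleMinor"))

#' @rdname accessors
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname accessors
#' @export
setGeneric("nMissing", function(x) standardGeneric("nMissing"))

#' @rdname accessors
#' @export
setGeneric("cases", function(x) standardGeneric("cases"))

#' @rdname accessors
#' @export
setGeneric("controls", function(x) standardGeneric("controls"))

#' @rdname accessors
#' @export
setGeneric("populationLabel", function(x) standardGeneric("populationLabel"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))
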