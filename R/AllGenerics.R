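#' Species ids of an object
#' @param x a TraitMatrix or EnvironmentMatrix.
#' @return character vector of species ids.
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' Trait ids of a TraitMatrix
#' @param x a TraitMatrix.
#' @return character vector of trait ids.
#' @export
setGeneric("traitIds", function(x) standardGeneric("traitIds"))

#' Environment ids of an EnvironmentMatrix
#' @param x an EnvironmentMatrix.
#' @return character vector of environment ids.
#' @export
setGeneric("environmentIds", function(x) standardGeneric("environmentIds"))

#' Coding of a TraitMatrix
#' @param x a TraitMatrix.
#' @return `"raw"` or `"binary"`.
#' @export
setGeneric("coding", function(x) standardGeneric("coding"))
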