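#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib TraitNet, .registration = TRUE
NULL

# Cell codes for raw trait matrices.  Internally a raw matrix is integer:
# 0 = absent, 1 = present, 2 = variable, NA = unavailable.  A binary matrix
# holds only 0, 1, NA; an imputed matrix has no NA left.
.CODE_ABSENT <- 0L
.CODE_PRESENT <- 1L
.CODE_VARIABLE <- 2L

#' Species-by-trait matrix
#'
#' Container for a species x trait growth-phenotype matrix.  Two codings are
#' used along the pipeline: `"raw"` cells are 0 (no growth), 1 (growth),
#' 2 (variable among strains) or `NA` (no data); `"binary"` cells are 0, 1 or
#' `NA`.  Rows are species, columns are traits; both carry unique ids as
#' dimnames.
#'
#' @slot data integer matrix with species as rownames and traits as colnames.
#' @slot coding either `"raw"` or `"binary"`.
#' @export
setClass("TraitMatrix",
  representation(data = "matrix", coding = "character"))

setValidity("TraitMatrix", function(object) {
  d <- object@data
  msg <- character()
  if (!is.integer(d))
    msg <- c(msg, "data must be an integer matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "data must carry species rownames and trait colnames")
  else {
    if (anyDuplicated(rownames(d)))
      msg <- c(msg, "duplicated species ids")
    if (anyDuplicated(colnames(d)))
      msg <- c(msg, "duplicated trait ids")
  }
  if (!object@coding %in% c("raw", "binary"))
    msg <- c(msg, "coding must be 'raw' or 'binary'")
  v <- d[!is.na(d)]
  allowed <- if (identical(object@coding, "raw")) c(0L, 1L, 2L) else c(0L, 1L)
  if (length(v) && !all(v %in% allowed))
    msg <- c(msg, sprintf("cells outside {%s}", paste(allowed, collapse = ",")))
  if (length(msg)) msg else TRUE
})

#' Construct a TraitMatrix
#'
#' @param data integer matrix (species x traits) with dimnames; values
#'   0/1/2/NA for `coding = "raw"`, 0/1/NA for `coding = "binary"`.
#' @param coding `"raw"` or `"binary"`.
#' @return A [TraitMatrix-class] object.
#' @export
TraitMatrix <- function(data, coding = c("binary", "raw")) {
  coding <- match.arg(coding)
  storage.mode(data) <- "integer"
  new("TraitMatrix", data = data, coding = coding)
}

#' Species-by-environment matrix
#'
#' Binary matrix recording which isolation environments (substrates,
#' habitats) each species has been recorded from.  A species may belong to
#' several environments; an `"unknown"` column is a legitimate label.
#' Environments may carry an optional broad parent category.
#'
#' @slot data binary integer matrix, species x environments, with dimnames.
#' @slot parent named character vector of broad parent labels per
#'   environment (`NA` where none).
#' @export
setClass("EnvironmentMatrix",
  representation(data = "matrix", parent = "character"))

setValidity("EnvironmentMatrix", function(object) {
  d <- object@data
  msg <- character()
  if (!is.integer(d))
    msg <- c(msg, "data must be an integer matrix")
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "data must carry species rownames and environment colnames")
  else if (anyDuplicated(colnames(d)))
    msg <- c(msg, "duplicated environment ids")
  if (anyNA(d) || (length(d) && !all(d %in% c(0L, 1L))))
    msg <- c(msg, "cells must be 0 or 1")
  if (length(object@parent) != ncol(d))
    msg <- c(msg, "parent must have one entry per environment")
  if (length(msg)) msg else TRUE
})

#' Construct an EnvironmentMatrix
#'
#' @param data binary matrix (species x environments) with dimnames.
#' @param parent optional character vector of broad parent categories,
#'   one per environment.
#' @return An [EnvironmentMatrix-class] object.
#' @export
EnvironmentMatrix <- function(data, parent = NULL) {
  storage.mode(data) <- "integer"
  if (is.null(parent)) parent <- rep(NA_character_, ncol(data))
  names(parent) <- colnames(data)
  new("EnvironmentMatrix", data = data, parent = parent)
}

#' Fixed-margin permutation ensemble summaries
#'
#' Streaming summaries of a checkerboard-swap null ensemble: per requested
#' pair, the null means of the co-occurrence count (1,1) and the
#' single-presence count (1,0)+(0,1), together with exceedance tallies of
#' replicates whose null count reached the observed count.  Full replicate
#' matrices are never stored.
#'
#' @slot pairs data.frame with columns `item_a`, `item_b`, and logical
#'   `b_fixed` (TRUE when item_b is a fixed, never-permuted column such as
#'   an environment).
#' @slot posObs,negObs integer observed counts per pair.
#' @slot posMean,negMean numeric null means per pair.
#' @slot posExceed,negExceed integer tallies of replicates with null count
#'   >= observed.
#' @slot nPerm,nSwaps integer ensemble parameters.
#' @slot swapMode `"attempts"` or `"successful"` swap counting.
#' @export
setClass("PermutationEnsemble",
  representation(pairs = "data.frame", posObs = "integer",
    negObs = "integer", posMean = "numeric", negMean = "numeric",
    posExceed = "integer", negExceed = "integer", nPerm = "integer",
    nSwaps = "integer", swapMode = "character"))

setValidity("PermutationEnsemble", function(object) {
  n <- nrow(object@pairs)
  lens <- c(length(object@posObs), length(object@negObs),
    length(object@posMean), length(object@negMean),
    length(object@posExceed), length(object@negExceed))
  if (!all(lens == n))
    return("summary vectors must cover every requested pair")
  if (object@nPerm < 1L)
    return("nPerm must be >= 1")
  TRUE
})

#' Three-set variance partition
#'
#' Unique and shared Ezekiel-adjusted R-squared fractions of a multivariate
#' response explained by three predictor sets (phylogeny, biological
#' properties, isolation environment), obtained by inclusion-exclusion over
#' the seven nonempty predictor-set unions.  Individual fractions may be
#' slightly negative, an adjusted-R-squared artifact, and are reported as
#' computed.
#'
#' @slot fractions named numeric: `phy`, `bio`, `env` (unique), `phy.bio`,
#'   `phy.env`, `bio.env` (pairwise shared), `phy.bio.env` (three-way),
#'   `residual`.
#' @slot r2 named numeric adjusted R-squared of the seven predictor unions.
#' @export
setClass("PartitionResult",
  representation(fractions = "numeric", r2 = "numeric"))

#' Signed trait association network
#'
#' Network whose nodes are traits with at least one significant association
#' of the given sign and whose edges are the significant pairs, weighted by
#' association strength.  Communities, when detected, partition the node
#' set.
#'
#' @slot graph an igraph object (undirected, weighted).
#' @slot sign `"positive"` or `"negative"`.
#' @slot communities named integer community membership (empty until
#'   [cnmCommunities()] is run).
#' @slot modularity modularity Q of the stored partition (NA until run).
#' @slot categories named character trait category labels (may be empty).
#' @export
setClass("TraitNetwork",
  representation(graph = "ANY", sign = "character",
    communities = "integer", modularity = "numeric",
    categories = "character"))
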