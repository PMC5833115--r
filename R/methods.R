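#' @describeIn TraitMatrix species ids (rownames).
#' @param x,object a `TraitMatrix`.
#' @export
setMethod("speciesIds", "TraitMatrix", function(x) rownames(x@data))

#' @describeIn TraitMatrix trait ids (colnames).
#' @export
setMethod("traitIds", "TraitMatrix", function(x) colnames(x@data))

#' @describeIn TraitMatrix coding, `"raw"` or `"binary"`.
#' @export
setMethod("coding", "TraitMatrix", function(x) x@coding)

#' @describeIn TraitMatrix dimensions (species, traits).
#' @export
setMethod("dim", "TraitMatrix", function(x) dim(x@data))

#' @describeIn TraitMatrix underlying integer matrix.
#' @export
setMethod("as.matrix", "TraitMatrix", function(x) x@data)

#' @describeIn TraitMatrix subset species (i) and traits (j); always keeps
#'   matrix structure.
#' @param i,j,drop row/column index; `drop` is ignored.
#' @param ... unused.
#' @export
setMethod("[", "TraitMatrix", function(x, i, j, ..., drop = FALSE) {
  d <- x@data
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) d <- d[, j, drop = FALSE]
  initialize(x, data = d)
})

setMethod("show", "TraitMatrix", function(object) {
  d <- object@data
  nmiss <- sum(is.na(d))
  cat(sprintf("TraitMatrix (%s): %d species x %d traits, %d missing cells (%.1f%%)\n",
    object@coding, nrow(d), ncol(d), nmiss, 100 * nmiss / max(1, length(d))))
  if (object@coding == "raw")
    cat(sprintf("  variable cells: %d\n", sum(d == .CODE_VARIABLE, na.rm = TRUE)))
})

#' @describeIn EnvironmentMatrix species ids (rownames).
#' @param x,object an `EnvironmentMatrix`.
#' @export
setMethod("speciesIds", "EnvironmentMatrix", function(x) rownames(x@data))

#' @describeIn EnvironmentMatrix environment ids (colnames).
#' @export
setMethod("environmentIds", "EnvironmentMatrix", function(x) colnames(x@data))

#' @describeIn EnvironmentMatrix dimensions (species, environments).
#' @export
setMethod("dim", "EnvironmentMatrix", function(x) dim(x@data))

#' @describeIn EnvironmentMatrix underlying binary matrix.
#' @export
setMethod("as.matrix", "EnvironmentMatrix", function(x) x@data)

setMethod("show", "EnvironmentMatrix", function(object) {
  d <- object@data
  cat(sprintf("EnvironmentMatrix: %d species x %d environments (%d eligible at >= 4 species)\n",
    nrow(d), ncol(d), sum(colSums(d) >= 4L)))
})

setMethod("show", "PermutationEnsemble", function(object) {
  cat(sprintf("PermutationEnsemble: %d pairs, %d permutations x %d swaps (%s counting)\n",
    nrow(object@pairs), object@nPerm, object@nSwaps, object@swapMode))
})

setMethod("show", "PartitionResult", function(object) {
  f <- object@fractions
  cat("Three-set variance partition (adjusted R-squared fractions)\n")
  cat(sprintf("  phylogeny alone      %+ .5f\n", f[["phy"]]))
  cat(sprintf("  biology alone        %+ .5f\n", f[["bio"]]))
  cat(sprintf("  environment alone    %+ .5f\n", f[["env"]]))
  cat(sprintf("  phy & bio            %+ .5f\n", f[["phy.bio"]]))
  cat(sprintf("  phy & env            %+ .5f\n", f[["phy.env"]]))
  cat(sprintf("  bio & env            %+ .5f\n", f[["bio.env"]]))
  cat(sprintf("  three-way            %+ .5f\n", f[["phy.bio.env"]]))
  cat(sprintf("  total explained      %+ .5f\n", object@r2[["phy.bio.env"]]))
  cat(sprintf("  residual             %+ .5f\n", f[["residual"]]))
})

setMethod("show", "TraitNetwork", function(object) {
  g <- object@graph
  cat(sprintf("TraitNetwork (%s): %d nodes, %d edges", object@sign,
    igraph::vcount(g), igraph::ecount(g)))
  if (length(object@communities))
    cat(sprintf(", %d communities (Q = %.3f)",
      length(unique(object@communities)), object@modularity))
  cat("\n")
})
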