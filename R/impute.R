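#' Zero-probability model for missing trait cells
#'
#' Collects the count statistics behind the probabilistic imputation rule:
#' per-species and per-trait zero counts over observed (non-missing) cells,
#' and the global zero fraction T(z) whose denominator is the full matrix
#' size n_r x n_c.
#'
#' @param x a binary [TraitMatrix-class] (0/1/NA).
#' @return list with `n0Species`, `nSpecies` (observed cells per species),
#'   `n0Trait`, `nTrait`, `n0Total`, `nRows`, `nCols`, `Tz`.
#' @export
imputationModel <- function(x) {
  stopifnot(is(x, "TraitMatrix"), coding(x) == "binary")
  d <- as.matrix(x)
  obs <- !is.na(d)
  zero <- !is.na(d) & d == 0L
  list(
    n0Species = rowSums(zero), nSpecies = rowSums(obs),
    n0Trait = colSums(zero), nTrait = colSums(obs),
    n0Total = sum(zero), nRows = nrow(d), nCols = ncol(d),
    Tz = sum(zero) / (nrow(d) * ncol(d)))
}

#' Probability that a missing cell is zero
#'
#' P(0) = T(z) * P(s) * P(t), where P(s) = n0/n_s is the zero fraction over
#' the species' observed cells, P(t) = n0/n_t the zero fraction over the
#' trait's observed cells, and T(z) = n0_total / (n_r * n_c) the global
#' zero fraction.  Being a product of three fractions, P(0) is bounded by
#' each factor and rarely exceeds 0.5 in practice, so most missing cells
#' impute to presence.
#'
#' @param model output of [imputationModel()].
#' @param species,trait species and trait id (or index).
#' @return P(0) for that cell.
#' @export
cellZeroProbability <- function(model, species, trait) {
  ns <- model$nSpecies[[species]]
  nt <- model$nTrait[[trait]]
  if (ns == 0L)
    stop("species '", species, "' has no observed cells; P(0) undefined")
  if (nt == 0L)
    stop("trait '", trait, "' has no observed cells; P(0) undefined")
  ps <- model$n0Species[[species]] / ns
  pt <- model$n0Trait[[trait]] / nt
  model$Tz * ps * pt
}

#' Impute missing trait cells
#'
#' Replaces every missing cell by 0 when P(0) > `threshold` and by 1 when
#' P(0) < `threshold`; an exact tie imputes 1 (the presence-side half-open
#' rule) and is logged.  All model statistics are frozen on the
#' pre-imputation matrix, so the result does not depend on fill order.
#' Observed cells are never modified.
#'
#' @param x a binary [TraitMatrix-class], typically after coverage
#'   filtering.
#' @param threshold decision threshold on P(0) (default 0.5).
#' @return A fully binary [TraitMatrix-class] with no missing cells; the
#'   attribute `audit` holds a data.frame of imputed cells (species, trait,
#'   p0, value).
#' @export
imputeTraits <- function(x, threshold = 0.5) {
  stopifnot(is(x, "TraitMatrix"), coding(x) == "binary")
  d <- as.matrix(x)
  miss <- which(is.na(d), arr.ind = TRUE)
  if (nrow(miss) == 0L) {
    attr(x, "audit") <- data.frame(species = character(), trait = character(),
      p0 = numeric(), value = integer())
    return(x)
  }
  model <- imputationModel(x)
  ns <- model$nSpecies[miss[, 1L]]
  nt <- model$nTrait[miss[, 2L]]
  if (any(ns == 0L))
    stop("species with no observed cells: ",
      paste(unique(rownames(d)[miss[ns == 0L, 1L]]), collapse = ", "))
  if (any(nt == 0L))
    stop("trait with no observed cells: ",
      paste(unique(colnames(d)[miss[nt == 0L, 2L]]), collapse = ", "))
  ps <- model$n0Species[miss[, 1L]] / ns
  pt <- model$n0Trait[miss[, 2L]] / nt
  p0 <- model$Tz * ps * pt
  val <- ifelse(p0 > threshold, 0L, 1L)
  ties <- p0 == threshold
  if (any(ties))
    message(sum(ties), " cell(s) at P(0) == threshold imputed to 1")
  d[miss] <- val
  out <- TraitMatrix(d, coding = "binary")
  attr(out, "audit") <- data.frame(
    species = rownames(d)[miss[, 1L]], trait = colnames(d)[miss[, 2L]],
    p0 = p0, value = val, stringsAsFactors = FALSE)
  out
}
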