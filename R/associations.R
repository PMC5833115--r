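#' Observed pair counts
#'
#' For a trait pair, the positive count is the number of species carrying
#' both traits (1,1); the negative count is the number carrying exactly one
#' of them, (1,0) + (0,1).
#'
#' @param m binary matrix or binary [TraitMatrix-class].
#' @param a,b column ids or indices; must differ.
#' @return named integer vector `c(positive_obs, negative_obs)`.
#' @export
pairCounts <- function(m, a, b) {
  m <- .asBinaryMatrix(m)
  ca <- if (is.numeric(a)) as.integer(a) else match(a, colnames(m))
  cb <- if (is.numeric(b)) as.integer(b) else match(b, colnames(m))
  if (is.na(ca) || is.na(cb)) stop("column not found")
  if (ca == cb) stop("a pair may not associate a trait with itself")
  x <- m[, ca]
  y <- m[, cb]
  c(positive_obs = sum(x & y), negative_obs = sum(xor(x, y)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving.  Wraps [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# Wilson score interval on a proportion x/n (no continuity correction)
.wilsonCI <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, ctr - hw), high = min(1, ctr + hw))
}

# Assemble an association table from ensemble summaries.  Empirical p per
# side uses the add-one form (1 + exceedance) / (nPerm + 1); BH is applied
# separately within the positive-test and negative-test families.
.associationTable <- function(ensemble, alpha = 0.05, bhFamily = c("per_side",
    "pooled")) {
  bhFamily <- match.arg(bhFamily)
  nP <- ensemble@nPerm
  pPos <- (1 + ensemble@posExceed) / (nP + 1)
  pNeg <- (1 + ensemble@negExceed) / (nP + 1)
  if (bhFamily == "per_side") {
    qPos <- bhAdjust(pPos)
    qNeg <- bhAdjust(pNeg)
  } else {
    q <- bhAdjust(c(pPos, pNeg))
    qPos <- q[seq_along(pPos)]
    qNeg <- q[-seq_along(pPos)]
  }
  strPos <- abs(ensemble@posObs - ensemble@posMean)
  strNeg <- abs(ensemble@negObs - ensemble@negMean)
  sigPos <- qPos < alpha
  sigNeg <- qNeg < alpha
  direction <- rep("none", length(pPos))
  direction[sigPos & !sigNeg] <- "positive"
  direction[sigNeg & !sigPos] <- "negative"
  both <- sigPos & sigNeg
  direction[both] <- ifelse(strPos[both] >= strNeg[both], "positive",
    "negative")
  # reported side: the significant direction, or for non-significant pairs
  # the side with the larger observed-minus-expected difference
  side <- ifelse(direction == "negative", "negative",
    ifelse(direction == "positive", "positive",
      ifelse(strPos >= strNeg, "positive", "negative")))
  pos <- side == "positive"
  ciPos <- t(vapply(ensemble@posExceed, .wilsonCI, numeric(2), n = nP))
  ciNeg <- t(vapply(ensemble@negExceed, .wilsonCI, numeric(2), n = nP))
  out <- data.frame(
    item_a = ensemble@pairs$item_a, item_b = ensemble@pairs$item_b,
    positive_obs = ensemble@posObs, negative_obs = ensemble@negObs,
    pos_exp = ensemble@posMean, neg_exp = ensemble@negMean,
    str_pos = strPos, str_neg = strNeg,
    p_pos = pPos, p_neg = pNeg, q_pos = qPos, q_neg = qNeg,
    direction = direction,
    observed = ifelse(pos, ensemble@posObs, ensemble@negObs),
    expected = ifelse(pos, ensemble@posMean, ensemble@negMean),
    strength = ifelse(pos, strPos, strNeg),
    q = ifelse(pos, qPos, qNeg),
    ci_low = ifelse(pos, ciPos[, 1L], ciNeg[, 1L]),
    ci_high = ifelse(pos, ciPos[, 2L], ciNeg[, 2L]),
    stringsAsFactors = FALSE)
  class(out) <- c("AssociationTable", "data.frame")
  out
}

#' Test all trait-trait associations
#'
#' Runs the fixed-margin permutation test for every unordered trait pair:
#' one-sided empirical p-values for the positive (co-occurrence above
#' expectation) and negative (single-presence above expectation) sides,
#' each Benjamini-Hochberg corrected across all pairs within its family.
#' A pair's direction is the significant side at `q < alpha` (the stronger
#' side if both reach significance); non-significant pairs report the side
#' with the larger observed-minus-expected difference.  Wilson confidence
#' intervals on the exceedance proportion accompany each call as a
#' stability diagnostic.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @param nPerm permutations (default 10000).
#' @param nSwaps swaps per permutation (default 1000).
#' @param alpha significance level on q (default 0.05).
#' @param swapMode see [checkerboardSwap()].
#' @param bhFamily `"per_side"` (default) corrects positive and negative
#'   tests separately; `"pooled"` corrects them as one family.
#' @return An association table (data.frame): one row per pair with
#'   observed/expected counts, strengths, p, q, direction and Wilson CI.
#' @export
associateAllTraits <- function(m, nPerm = 10000L, nSwaps = 1000L,
    alpha = 0.05, swapMode = c("attempts", "successful"),
    bhFamily = c("per_side", "pooled")) {
  ens <- buildEnsemble(m, pairs = NULL, nPerm = nPerm, nSwaps = nSwaps,
    swapMode = match.arg(swapMode))
  .associationTable(ens, alpha = alpha, bhFamily = match.arg(bhFamily))
}

#' Test trait-environment associations
#'
#' Same permutation machinery as [associateAllTraits()], but pairs every
#' trait with every eligible environment column.  Only the trait matrix is
#' permuted; environment columns are held fixed, so the null keeps each
#' environment's membership intact.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @param env an [EnvironmentMatrix-class] on the same species, same order.
#' @param nPerm,nSwaps,alpha,swapMode,bhFamily as in [associateAllTraits()].
#' @param minSpecies environments with fewer member species are excluded
#'   (default 4).
#' @param environments optional subset of environment ids to test; an
#'   ineligible id here is an error.
#' @return An association table with `item_a` = trait, `item_b` =
#'   environment.
#' @export
associateTraitEnvironment <- function(m, env, nPerm = 10000L,
    nSwaps = 1000L, alpha = 0.05, swapMode = c("attempts", "successful"),
    bhFamily = c("per_side", "pooled"), minSpecies = 4L,
    environments = NULL) {
  stopifnot(is(env, "EnvironmentMatrix"))
  mm <- .asBinaryMatrix(m)
  ed <- as.matrix(env)
  if (!identical(rownames(mm), rownames(ed)))
    stop("trait and environment matrices must cover the same species in ",
      "the same order")
  elig <- eligibleEnvironments(env, minSpecies)
  if (is.null(environments)) {
    environments <- environmentIds(env)[elig]
  } else if (any(!elig[environments])) {
    stop("ineligible environment(s) (< ", minSpecies, " species): ",
      paste(environments[!elig[environments]], collapse = ", "))
  }
  if (!length(environments))
    stop("no eligible environments to test")
  pairs <- expand.grid(item_a = colnames(mm), item_b = environments,
    stringsAsFactors = FALSE)
  pairs$b_fixed <- TRUE
  ens <- buildEnsemble(mm, pairs = pairs, fixed = ed, nPerm = nPerm,
    nSwaps = nSwaps, swapMode = match.arg(swapMode))
  .associationTable(ens, alpha = alpha, bhFamily = match.arg(bhFamily))
}

#' Significant pairs of an association table
#'
#' @param assoc an association table.
#' @param direction `"any"`, `"positive"` or `"negative"`.
#' @return The subset of rows called significant.
#' @export
significantPairs <- function(assoc, direction = c("any", "positive",
    "negative")) {
  direction <- match.arg(direction)
  keep <- assoc$direction != "none"
  if (direction != "any") keep <- assoc$direction == direction
  assoc[keep, , drop = FALSE]
}
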