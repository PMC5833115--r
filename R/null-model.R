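.asBinaryMatrix <- function(m) {
  if (is(m, "TraitMatrix")) {
    if (coding(m) != "binary")
      stop("matrix must be binary-coded")
    m <- as.matrix(m)
  }
  if (anyNA(m))
    stop("matrix must have no missing cells (impute first)")
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L)))
    stop("matrix must be strictly binary")
  m
}

#' Fixed-margin checkerboard randomization
#'
#' Randomizes a binary matrix by repeated checkerboard swaps: a random 2x2
#' submatrix equal to \code{[[1,0],[0,1]]} or \code{[[0,1],[1,0]]} is
#' flipped, which preserves all row and column sums exactly.  With the
#' default `swapMode = "attempts"` every draw counts toward `nSwaps`
#' whether or not it finds a checkerboard; this trial-swap chain has a
#' symmetric transition kernel and therefore samples the fixed-margin class
#' uniformly at stationarity.  `swapMode = "successful"` counts only
#' realized flips (redrawing failures up to `maxAttempts`), which mixes
#' faster on sparse matrices but weights matrices by their number of
#' checkerboard units.
#'
#' @param m binary matrix or binary [TraitMatrix-class].
#' @param nSwaps number of swaps (default 1000).
#' @param swapMode `"attempts"` (default) or `"successful"`.
#' @param maxAttempts draw cap for `"successful"` mode (default
#'   `10 * nSwaps`).
#' @return Randomized matrix with the margins of `m`; attributes
#'   `successes` and `attempts` record chain effort.  If `m` admits no
#'   checkerboard (e.g. perfectly nested), the input is returned with a
#'   warning.
#' @export
checkerboardSwap <- function(m, nSwaps = 1000L,
    swapMode = c("attempts", "successful"), maxAttempts = 10L * nSwaps) {
  swapMode <- match.arg(swapMode)
  m <- .asBinaryMatrix(m)
  if (nrow(m) < 2L || ncol(m) < 2L || !.hasCheckerboard(m)) {
    warning("matrix has no checkerboard unit; returned unchanged")
    attr(m, "successes") <- 0L
    attr(m, "attempts") <- 0L
    return(m)
  }
  res <- cpp_swap(m, as.integer(nSwaps), swapMode == "attempts",
    as.integer(maxAttempts))
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  attr(out, "successes") <- res$successes
  attr(out, "attempts") <- res$attempts
  out
}

.hasCheckerboard <- function(m) {
  # a checkerboard unit exists iff some column pair has both a (1,0) and a
  # (0,1) row; with x = crossprod (1,1)-counts and cs = column sums, the
  # (1,0) count of pair (i,j) is cs_i - x_ij and the (0,1) count cs_j - x_ij
  x <- crossprod(m)
  cs <- colSums(m)
  n10 <- outer(cs, rep(1, ncol(m))) - x
  n01 <- outer(rep(1, ncol(m)), cs) - x
  any(n10[upper.tri(x)] > 0 & n01[upper.tri(x)] > 0)
}

#' Build a fixed-margin permutation ensemble
#'
#' Draws `nPerm` independent randomizations of `m` (each re-started from
#' the observed matrix and swapped `nSwaps` times) and streams, for every
#' requested pair, the null mean of the co-occurrence count (1,1) and of
#' the single-presence count (1,0)+(0,1), plus tallies of replicates whose
#' null count reached the observed one.  Memory is O(pairs).
#'
#' Pairs may be trait-trait (two columns of `m`) or trait-fixed: when
#' `fixed` is supplied and `pairs$b_fixed` is TRUE, item_b indexes a column
#' of `fixed`, which is never permuted (environment columns are held
#' fixed; only the trait matrix is randomized).
#'
#' @param m binary matrix or binary [TraitMatrix-class].
#' @param pairs data.frame with columns `item_a`, `item_b` (ids or column
#'   indices) and optionally logical `b_fixed`; `NULL` means all unordered
#'   column pairs of `m`.
#' @param fixed optional binary matrix of fixed columns (same species
#'   order as `m`).
#' @param nPerm permutations (default 10000); fewer than 100 warns.
#' @param nSwaps swaps per permutation (default 1000).
#' @param swapMode see [checkerboardSwap()].
#' @param maxAttempts draw cap per replicate in `"successful"` mode.
#' @return A [PermutationEnsemble-class].
#' @export
buildEnsemble <- function(m, pairs = NULL, fixed = NULL, nPerm = 10000L,
    nSwaps = 1000L, swapMode = c("attempts", "successful"),
    maxAttempts = 10L * nSwaps) {
  swapMode <- match.arg(swapMode)
  m <- .asBinaryMatrix(m)
  if (nPerm < 100L)
    warning("nPerm < 100 gives unstable empirical p-values")
  if (is.null(pairs)) {
    idx <- utils::combn(ncol(m), 2L)
    pairs <- data.frame(item_a = idx[1L, ], item_b = idx[2L, ],
      b_fixed = FALSE)
  }
  if (is.null(pairs$b_fixed)) pairs$b_fixed <- FALSE
  toIdx <- function(v, mat) {
    if (is.numeric(v)) as.integer(v) else match(as.character(v), colnames(mat))
  }
  ia <- toIdx(pairs$item_a, m)
  ib <- integer(nrow(pairs))
  fb <- pairs$b_fixed
  if (any(fb)) {
    if (is.null(fixed))
      stop("pairs reference fixed columns but 'fixed' is NULL")
    fixed <- .asBinaryMatrix(fixed)
    stopifnot(nrow(fixed) == nrow(m))
    ib[fb] <- toIdx(pairs$item_b[fb], fixed)
  }
  ib[!fb] <- toIdx(pairs$item_b[!fb], m)
  if (anyNA(ia) || anyNA(ib))
    stop("pair item(s) not found among matrix columns")
  if (any(!fb & ia == ib))
    stop("a pair may not associate a trait with itself")
  # observed counts
  obsPos <- integer(nrow(pairs))
  obsNeg <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- m[, ia[k]]
    b <- if (fb[k]) fixed[, ib[k]] else m[, ib[k]]
    obsPos[k] <- sum(a & b)
    obsNeg[k] <- sum(xor(a, b))
  }
  if (is.null(fixed)) fixed <- matrix(0L, nrow(m), 0L)
  res <- cpp_ensemble(m, fixed, ia - 1L, ib - 1L, fb, obsPos, obsNeg,
    as.integer(nPerm), as.integer(nSwaps), swapMode == "attempts",
    as.integer(maxAttempts))
  cnM <- colnames(m)
  cnF <- colnames(fixed)
  lab <- function(i, isFixed) {
    isFixed <- rep_len(isFixed, length(i))
    nm <- character(length(i))
    nm[!isFixed] <- if (is.null(cnM)) as.character(i[!isFixed]) else
      cnM[i[!isFixed]]
    nm[isFixed] <- if (is.null(cnF)) as.character(i[isFixed]) else
      cnF[i[isFixed]]
    ifelse(is.na(nm) | !nzchar(nm), as.character(i), nm)
  }
  prs <- data.frame(
    item_a = lab(ia, FALSE), item_b = lab(ib, fb), b_fixed = fb,
    stringsAsFactors = FALSE)
  new("PermutationEnsemble", pairs = prs, posObs = obsPos, negObs = obsNeg,
    posMean = res$pos_sum / nPerm, negMean = res$neg_sum / nPerm,
    posExceed = res$pos_ge, negExceed = res$neg_ge,
    nPerm = as.integer(nPerm), nSwaps = as.integer(nSwaps),
    swapMode = swapMode)
}

#' Export ensemble summaries
#'
#' @param ensemble a [PermutationEnsemble-class].
#' @return data.frame with one row per pair: observed and null-mean counts
#'   for both association directions and the exceedance tallies.
#' @export
ensembleSummary <- function(ensemble) {
  cbind(ensemble@pairs[, c("item_a", "item_b")],
    data.frame(positive_obs = ensemble@posObs, negative_obs = ensemble@negObs,
      pos_exp = ensemble@posMean, neg_exp = ensemble@negMean,
      pos_exceed = ensemble@posExceed, neg_exceed = ensemble@negExceed))
}
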