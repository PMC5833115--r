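# Sum of sister-clade differences for one or many binary state vectors on
# the same tree.  Nodal values are estimated tips-to-root as the unweighted
# mean of daughter values (branch lengths are deliberately ignored here;
# they enter only the Brownian null).  Polytomy contribution is the mean
# over all daughter pairs of absolute differences, keeping balanced scaling.
.dMulti <- function(tree, S) {
  S <- as.matrix(S)
  nt <- length(tree$tip.label)
  stopifnot(nrow(S) == nt)
  po <- ape::reorder.phylo(tree, "postorder")
  V <- matrix(0, nt + tree$Nnode, ncol(S))
  V[seq_len(nt), ] <- S
  d <- numeric(ncol(S))
  parents <- unique(po$edge[, 1L])
  kidsOf <- split(po$edge[, 2L], factor(po$edge[, 1L], levels = parents))
  for (i in seq_along(parents)) {
    kids <- kidsOf[[i]]
    K <- V[kids, , drop = FALSE]
    V[parents[i], ] <- colMeans(K)
    if (length(kids) == 2L) {
      d <- d + abs(K[1L, ] - K[2L, ])
    } else {
      cmb <- utils::combn(length(kids), 2L)
      acc <- 0
      for (j in seq_len(ncol(cmb)))
        acc <- acc + abs(K[cmb[1L, j], ] - K[cmb[2L, j], ])
      d <- d + acc / ncol(cmb)
    }
  }
  d
}

#' Sum of sister-clade differences
#'
#' The raw dispersion measure behind the D statistic: binary tip states
#' are averaged up the tree (each internal node takes the unweighted mean
#' of its daughters), and the absolute differences between daughter values
#' are summed over internal nodes.
#'
#' @param tree a rooted `ape::phylo`.
#' @param tipStates binary vector named by tip label (or in tip order).
#' @return the scalar d.
#' @export
sumSisterDifferences <- function(tree, tipStates) {
  s <- .alignStates(tree, tipStates)
  .dMulti(tree, matrix(s, ncol = 1L))[1L]
}

.alignStates <- function(tree, tipStates) {
  if (!is.null(names(tipStates))) {
    miss <- setdiff(tree$tip.label, names(tipStates))
    if (length(miss))
      stop("tip(s) without a state: ", paste(miss, collapse = ", "))
    tipStates <- tipStates[tree$tip.label]
  } else if (length(tipStates) != length(tree$tip.label)) {
    stop("tipStates must cover every tip")
  }
  if (anyNA(tipStates)) stop("tip states may not be missing")
  as.numeric(tipStates)
}

# Brownian values at the tips: preorder walk adding N(0, branch length)
# increments; vectorized over k independent replicate traits.
.brownianTips <- function(tree, k) {
  nt <- length(tree$tip.label)
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  cw <- ape::reorder.phylo(tree, "cladewise")
  V <- matrix(0, nt + tree$Nnode, k)
  for (i in seq_len(nrow(cw$edge))) {
    p <- cw$edge[i, 1L]
    ch <- cw$edge[i, 2L]
    V[ch, ] <- V[p, ] + stats::rnorm(k, sd = sqrt(max(cw$edge.length[i], 0)))
  }
  V[seq_len(nt), , drop = FALSE]
}

#' Threshold-Brownian binary tip states
#'
#' Evolves a continuous trait along the phylogeny under Brownian motion
#' (increment variance proportional to branch length) and thresholds it at
#' the quantile that reproduces the requested prevalence exactly: the
#' `count` tips with the largest values are scored 1.
#'
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @param prevalence target fraction of present tips in (0, 1), or use
#'   `count` directly.
#' @param count integer number of present tips (overrides `prevalence`).
#' @param k number of independent replicate traits (default 1).
#' @return binary matrix, tips x k, rownames = tip labels.
#' @export
brownianThresholdStates <- function(tree, prevalence = NULL, count = NULL,
    k = 1L) {
  nt <- length(tree$tip.label)
  if (is.null(count)) {
    if (is.null(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop("prevalence must be strictly between 0 and 1")
    count <- round(prevalence * nt)
    count <- min(max(count, 1L), nt - 1L)
  }
  if (count <= 0L || count >= nt)
    stop("count must leave both states represented")
  X <- .brownianTips(tree, k)
  S <- apply(X, 2L, function(v) {
    out <- integer(nt)
    out[order(v, decreasing = TRUE)[seq_len(count)]] <- 1L
    out
  })
  S <- matrix(S, nrow = nt, dimnames = list(tree$tip.label, NULL))
  S
}

#' Fritz-Purvis D for a binary trait
#'
#' Scales the observed sum of sister-clade differences between its
#' expectations under two nulls: random shuffles of the tip states
#' (D about 1) and threshold-Brownian evolution at the observed prevalence
#' (D about 0).  D = (d_obs - mean d_Brownian) / (mean d_random - mean
#' d_Brownian).  Two-sided permutation p-values for departure from each
#' null are twice the smaller tail fraction, capped at 1.
#'
#' @param tree rooted `ape::phylo` with branch lengths, at least 4 tips.
#' @param tipStates binary vector named by tip label; must be
#'   non-constant.
#' @param nSim simulations per null (default 1000).
#' @param nulls optional precomputed list with numeric vectors `random`
#'   and `brownian` of null d values (shared across traits of equal
#'   prevalence).
#' @return one-row data.frame: `d_obs`, `mean_d_random`,
#'   `mean_d_brownian`, `D`, `p_vs_random` (departure from D = 1),
#'   `p_vs_brownian` (departure from D = 0), `n_sim`.
#' @export
dStatistic <- function(tree, tipStates, nSim = 1000L, nulls = NULL) {
  if (length(tree$tip.label) < 4L)
    stop("need at least 4 tips")
  s <- .alignStates(tree, tipStates)
  if (length(unique(s)) < 2L)
    stop("trait is constant on the tree's tips; D undefined")
  dObs <- .dMulti(tree, matrix(s, ncol = 1L))[1L]
  if (is.null(nulls))
    nulls <- dNullDistributions(tree, sum(s), nSim)
  mR <- mean(nulls$random)
  mB <- mean(nulls$brownian)
  twoSided <- function(null, obs) {
    lo <- mean(null <= obs)
    hi <- mean(null >= obs)
    min(1, 2 * min(lo, hi))
  }
  data.frame(
    d_obs = dObs, mean_d_random = mR, mean_d_brownian = mB,
    D = (dObs - mB) / (mR - mB),
    p_vs_random = twoSided(nulls$random, dObs),
    p_vs_brownian = twoSided(nulls$brownian, dObs),
    n_sim = length(nulls$random))
}

#' Null distributions of d for a given prevalence
#'
#' Both nulls depend on the states only through the tree and the number of
#' present tips, so they can be computed once and shared across traits of
#' equal prevalence.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param count number of present tips.
#' @param nSim simulations per null.
#' @return list with numeric vectors `random` and `brownian`.
#' @export
dNullDistributions <- function(tree, count, nSim = 1000L) {
  nt <- length(tree$tip.label)
  base <- c(rep(1, count), rep(0, nt - count))
  Srand <- vapply(seq_len(nSim), function(i) sample(base), numeric(nt))
  Sbro <- brownianThresholdStates(tree, count = count, k = nSim)
  list(random = .dMulti(tree, Srand), brownian = .dMulti(tree, Sbro))
}

#' D statistic for every trait of a matrix
#'
#' Species absent from the tree are dropped (with a message); constant
#' traits on the remaining tips are skipped with `NA` results.  Null
#' distributions are cached by prevalence, which is exact because both
#' nulls depend on the states only through the present-tip count.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param m binary matrix or imputed binary [TraitMatrix-class], species
#'   as rows.
#' @param nSim simulations per null (default 1000).
#' @return data.frame with one row per trait (columns as in
#'   [dStatistic()], plus `trait_id` and `n_tips`).
#' @export
dStatisticAll <- function(tree, m, nSim = 1000L) {
  mm <- .asBinaryMatrix(m)
  shared <- intersect(tree$tip.label, rownames(mm))
  if (length(shared) < 4L)
    stop("fewer than 4 species shared between tree and matrix")
  nd <- length(setdiff(rownames(mm), shared))
  if (nd > 0L)
    message(nd, " species absent from the tree were dropped")
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, shared))
  mm <- mm[tree$tip.label, , drop = FALSE]
  counts <- colSums(mm)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(ncol(mm)), function(j) {
    k <- counts[j]
    if (k == 0L || k == nrow(mm))
      return(data.frame(d_obs = NA_real_, mean_d_random = NA_real_,
        mean_d_brownian = NA_real_, D = NA_real_, p_vs_random = NA_real_,
        p_vs_brownian = NA_real_, n_sim = nSim))
    key <- as.character(k)
    if (is.null(cache[[key]]))
      cache[[key]] <- dNullDistributions(tree, k, nSim)
    dStatistic(tree, mm[, j], nSim = nSim, nulls = cache[[key]])
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(trait_id = colnames(mm),
    n_tips = nrow(mm), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}
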