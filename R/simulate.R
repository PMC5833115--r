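#' Simulate a coded species-by-trait matrix with planted structure
#'
#' Species trait vectors are drawn from a pairwise log-linear (Ising-type)
#' model: each trait has a baseline log-odds targeting its prevalence,
#' traits inside a planted module share a positive pairwise interaction
#' (co-occurrence odds boost), and planted exclusion pairs share a
#' negative one.  Sampling is by Gibbs sweeps over traits (vectorized over
#' species) from independent starts; baselines carry a mean-field
#' correction so realized prevalences stay near target.  A
#' missing-completely-at-random mask and a variable-code mask (drawn from
#' positive cells, since variable scores reflect growth in some strains)
#' are applied to the finished binary matrix.
#'
#' Defaults mirror the shape of the curated yeast compendium: 784 species,
#' 48 traits, 6% missing cells, 6% of positive cells coded variable.
#'
#' @param nSpecies,nTraits dimensions (defaults 784, 48).
#' @param modules list of integer/character vectors of trait indices/ids
#'   forming positive modules.
#' @param moduleBoost within-module pairwise log-odds (default 2, an e^2
#'   odds boost).
#' @param negativePairs 2-column matrix of trait pairs with exclusion
#'   interactions.
#' @param negativeStrength exclusion pairwise log-odds (default -2).
#' @param prevalence target trait prevalence, scalar or per-trait vector
#'   (default 0.5).
#' @param missingRate MCAR missingness fraction (default 0.06).
#' @param variableRate fraction of positive cells recoded as variable
#'   (default 0.06).
#' @param sweeps Gibbs burn-in sweeps (default 100).
#' @return list: `traits` (raw-coded [TraitMatrix-class]), `binary`
#'   (the unmasked binary matrix), `truth` (planted structure and
#'   parameters).
#' @export
simulateTraitMatrix <- function(nSpecies = 784L, nTraits = 48L,
    modules = list(), moduleBoost = 2, negativePairs = NULL,
    negativeStrength = -2, prevalence = 0.5, missingRate = 0.06,
    variableRate = 0.06, sweeps = 100L) {
  stopifnot(missingRate >= 0, missingRate < 1, variableRate >= 0,
    variableRate <= 1)
  prev <- rep_len(prevalence, nTraits)
  if (any(prev <= 0 | prev >= 1))
    stop("prevalences must be strictly between 0 and 1")
  traitIdx <- function(v) {
    if (is.character(v)) match(v, traitNames) else as.integer(v)
  }
  traitNames <- sprintf("trait%02d", seq_len(nTraits))
  spNames <- sprintf("sp%04d", seq_len(nSpecies))
  J <- matrix(0, nTraits, nTraits)
  for (md in modules) {
    md <- traitIdx(md)
    if (anyNA(md) || length(md) < 2L)
      stop("invalid module specification")
    J[t(utils::combn(md, 2L))] <- moduleBoost
  }
  if (!is.null(negativePairs)) {
    np <- negativePairs
    if (is.character(np))
      np <- matrix(match(np, traitNames), ncol = 2L)
    np <- matrix(as.integer(np), ncol = 2L)
    J[np] <- negativeStrength
  }
  J <- J + t(J)
  if (any(abs(diag(J)) > 0)) stop("self-interactions are not allowed")
  # mean-field corrected baselines
  alpha <- stats::qlogis(prev) - as.vector(J %*% prev)
  X <- matrix(stats::rbinom(nSpecies * nTraits, 1L,
    rep(prev, each = nSpecies)), nSpecies, nTraits)
  for (s in seq_len(sweeps)) {
    for (t in seq_len(nTraits)) {
      eta <- alpha[t] + X %*% J[, t]
      X[, t] <- stats::rbinom(nSpecies, 1L, stats::plogis(eta))
    }
  }
  dimnames(X) <- list(spNames, traitNames)
  storage.mode(X) <- "integer"
  coded <- X
  if (variableRate > 0) {
    ones <- which(coded == 1L)
    nv <- round(variableRate * length(ones))
    if (nv > 0)
      coded[sample(ones, nv)] <- .CODE_VARIABLE
  }
  if (missingRate > 0) {
    nm <- round(missingRate * length(coded))
    if (nm > 0)
      coded[sample(length(coded), nm)] <- NA_integer_
  }
  truth <- list(modules = lapply(modules, traitIdx),
    moduleBoost = moduleBoost,
    negativePairs = if (is.null(negativePairs)) NULL else
      matrix(as.integer(negativePairs), ncol = 2L),
    negativeStrength = negativeStrength, prevalence = prev,
    missingRate = missingRate, variableRate = variableRate,
    interaction = J)
  list(traits = TraitMatrix(coded, coding = "raw"),
    binary = TraitMatrix(X, coding = "binary"), truth = truth)
}

#' Simulate a Yule tree with threshold-Brownian and shuffled traits
#'
#' Grows a pure-birth (Yule) tree scaled to unit depth, then generates one
#' binary trait per entry of `modes`: `"brownian"` traits are
#' threshold-Brownian (phylogenetically clumped, D about 0), `"shuffled"`
#' traits are random permutations of such states across tips (no signal,
#' D about 1).
#'
#' @param nTips number of tips (>= 8).
#' @param prevalences per-trait target prevalence, recycled over `modes`.
#' @param modes character vector of `"brownian"` / `"shuffled"`.
#' @param birth Yule birth rate (default 1).
#' @return list: `tree` (`ape::phylo`, unit depth), `states` (tips x
#'   traits binary matrix), `modes`.
#' @export
simulateTreeAndTraits <- function(nTips, prevalences = 0.5,
    modes = c("brownian", "shuffled"), birth = 1) {
  stopifnot(nTips >= 8L)
  tree <- ape::rphylo(nTips, birth = birth, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  prev <- rep_len(prevalences, length(modes))
  S <- matrix(0L, nTips, length(modes),
    dimnames = list(tree$tip.label,
      sprintf("trait%03d", seq_along(modes))))
  for (j in seq_along(modes)) {
    cnt <- min(max(round(prev[j] * nTips), 1L), nTips - 1L)
    s <- brownianThresholdStates(tree, count = cnt)[, 1L]
    if (modes[j] == "shuffled") s <- sample(s)
    S[, j] <- s
  }
  list(tree = tree, states = S, modes = modes)
}

#' Simulate environments and gene tables tied to a trait matrix
#'
#' Environments select species enriched for a trait suite: each
#' environment's members are the top-scoring species under a logistic
#' perturbation of the suite score (number of suite traits present), so
#' environment sizes are exact and cover the control grid.  Genes are
#' causally linked to a mapped trait: present with probability
#' `1 - noise` when the trait is present and `noise` otherwise.
#'
#' @param x binary (imputed) [TraitMatrix-class] or binary matrix.
#' @param sizes environment sizes; the default recycles the control grid
#'   4, 11, 26, 47, 76, 147, 217 over `nEnvironments`.
#' @param nEnvironments number of environments (default 50).
#' @param suiteSize traits per environment suite (default 3).
#' @param suiteScale logistic scale of trait-suite selection (default 2;
#'   0 makes membership independent of traits).
#' @param geneMap named character vector gene id -> trait id; default
#'   maps two 5-gene groups onto the first 10 traits.
#' @param noise gene-presence flip probability (default 0.05).
#' @return list: `env` ([EnvironmentMatrix-class]), `genes` (binary
#'   matrix species x genes), `truth` (suites, geneMap, parameters).
#' @export
simulateEnvironmentsAndGenes <- function(x,
    sizes = NULL, nEnvironments = 50L, suiteSize = 3L, suiteScale = 2,
    geneMap = NULL, noise = 0.05) {
  m <- .asBinaryMatrix(x)
  grid <- c(4L, 11L, 26L, 47L, 76L, 147L, 217L)
  if (is.null(sizes))
    sizes <- rep_len(grid[grid <= nrow(m)], nEnvironments)
  stopifnot(all(sizes <= nrow(m)), all(sizes >= 1L))
  nEnv <- length(sizes)
  E <- matrix(0L, nrow(m), nEnv, dimnames = list(rownames(m),
    sprintf("env%02d", seq_len(nEnv))))
  suites <- vector("list", nEnv)
  for (e in seq_len(nEnv)) {
    suite <- sample(colnames(m), min(suiteSize, ncol(m)))
    score <- suiteScale * rowSums(m[, suite, drop = FALSE]) +
      stats::rlogis(nrow(m))
    members <- order(score, decreasing = TRUE)[seq_len(sizes[e])]
    E[members, e] <- 1L
    suites[[e]] <- suite
  }
  names(suites) <- colnames(E)
  if (is.null(geneMap)) {
    tr <- colnames(m)
    geneMap <- stats::setNames(tr[rep_len(seq_len(min(10L, ncol(m))), 10L)],
      sprintf("gene%02d", 1:10))
  }
  G <- vapply(names(geneMap), function(g) {
    tr <- m[, geneMap[[g]]]
    flip <- stats::rbinom(length(tr), 1L, noise)
    as.integer(ifelse(flip == 1L, 1L - tr, tr))
  }, integer(nrow(m)))
  G <- matrix(G, nrow = nrow(m),
    dimnames = list(rownames(m), names(geneMap)))
  list(env = EnvironmentMatrix(E), genes = G,
    truth = list(suites = suites, sizes = sizes, suiteScale = suiteScale,
      geneMap = geneMap, noise = noise))
}
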