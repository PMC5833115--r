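#' Species-by-pair response matrix
#'
#' One indicator column per unordered trait pair: 1 when the species
#' carries both traits, 0 when it carries one or neither (the both-absent
#' case is the only consistent binary completion of the pair coding).
#' Column sums therefore equal the observed positive pair counts.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @return integer matrix, species x C(T,2) pairs, columns named
#'   `"a:b"`.
#' @export
buildResponse <- function(m) {
  mm <- .asBinaryMatrix(m)
  idx <- utils::combn(ncol(mm), 2L)
  Y <- mm[, idx[1L, ], drop = FALSE] * mm[, idx[2L, ], drop = FALSE]
  colnames(Y) <- paste(colnames(mm)[idx[1L, ]], colnames(mm)[idx[2L, ]],
    sep = ":")
  Y
}

#' Ezekiel-adjusted multivariate redundancy R-squared
#'
#' Linear redundancy statistic of a multivariate response on a predictor
#' set: the ratio of the regression sum of squares (summed over response
#' columns) to the total sum of squares, adjusted as
#' R2a = 1 - (1 - R2)(n - 1)/(n - p - 1) with p the rank of the centered
#' predictor matrix.  Rank-deficient predictor sets are pruned implicitly
#' via the QR rank (with a warning).
#'
#' @param Y response matrix (columns are centered internally).
#' @param X predictor matrix.
#' @return adjusted R-squared (scalar).
#' @export
adjustedR2 <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  qrX <- qr(cbind(1, X))
  p <- qrX$rank - 1L
  if (p < ncol(X))
    warning("predictor matrix is rank deficient; effective p = ", p)
  if (n <= p + 1L)
    stop("need n > p + 1 for the adjustment")
  fit <- qr.fitted(qrX, Yc)
  r2 <- sum(fit^2) / sum(Yc^2)
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Three-set variance partition
#'
#' Partitions the adjusted explained variance of a multivariate response
#' among three predictor sets by inclusion-exclusion over the adjusted
#' R-squared of the seven nonempty unions: unique fractions (e.g.
#' unique(phy) = R2a(all) - R2a(bio U env)), pairwise-shared and three-way
#' fractions, and the residual 1 - R2a(all).  Fractions may be slightly
#' negative (adjusted-R-squared artifact) and are reported as computed;
#' they sum to R2a(all) exactly.
#'
#' @param Y response matrix (e.g. [buildResponse()] output).
#' @param Xphy,Xbio,Xenv predictor matrices over the same species in the
#'   same row order (phylogeny axes, biological-property counts, binary
#'   environments).
#' @return A [PartitionResult-class].
#' @export
partition3 <- function(Y, Xphy, Xbio, Xenv) {
  Xphy <- as.matrix(Xphy); Xbio <- as.matrix(Xbio); Xenv <- as.matrix(Xenv)
  n <- nrow(as.matrix(Y))
  if (nrow(Xphy) != n || nrow(Xbio) != n || nrow(Xenv) != n)
    stop("species sets differ across matrices: Y has ", n, " rows, ",
      "predictors have ", nrow(Xphy), "/", nrow(Xbio), "/", nrow(Xenv))
  rn <- rownames(as.matrix(Y))
  for (X in list(Xphy, Xbio, Xenv))
    if (!is.null(rn) && !is.null(rownames(X)) &&
        !identical(rn, rownames(X)))
      stop("species ordering differs between response and predictors")
  r2 <- c(
    phy = adjustedR2(Y, Xphy),
    bio = adjustedR2(Y, Xbio),
    env = adjustedR2(Y, Xenv),
    phy.bio = adjustedR2(Y, cbind(Xphy, Xbio)),
    phy.env = adjustedR2(Y, cbind(Xphy, Xenv)),
    bio.env = adjustedR2(Y, cbind(Xbio, Xenv)),
    phy.bio.env = adjustedR2(Y, cbind(Xphy, Xbio, Xenv)))
  all3 <- r2[["phy.bio.env"]]
  a <- all3 - r2[["bio.env"]]   # unique phylogeny
  b <- all3 - r2[["phy.env"]]   # unique biology
  c_ <- all3 - r2[["phy.bio"]]  # unique environment
  abTot <- r2[["phy"]] + r2[["bio"]] - r2[["phy.bio"]]   # ab + abc
  acTot <- r2[["phy"]] + r2[["env"]] - r2[["phy.env"]]
  bcTot <- r2[["bio"]] + r2[["env"]] - r2[["bio.env"]]
  abc <- abTot + acTot - (r2[["phy"]] - a)
  fractions <- c(phy = a, bio = b, env = c_,
    phy.bio = abTot - abc, phy.env = acTot - abc, bio.env = bcTot - abc,
    phy.bio.env = abc, residual = 1 - all3)
  new("PartitionResult", fractions = fractions, r2 = r2)
}

#' Fractions of a PartitionResult
#'
#' @param x a [PartitionResult-class].
#' @return named numeric vector of the seven fractions and the residual.
#' @export
partitionFractions <- function(x) {
  stopifnot(is(x, "PartitionResult"))
  x@fractions
}

#' Phylogeny predictor axes
#'
#' Principal-coordinate axes of the tree's cophenetic (patristic) distance
#' matrix.  Axes with positive eigenvalues are retained up to `cumMass`
#' cumulative eigenvalue mass (default 95%); feeding the raw n x n
#' distance matrix to a regression would make adjusted R-squared
#' degenerate.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param species species ids to keep, in the required row order.
#' @param cumMass cumulative positive-eigenvalue mass to retain.
#' @return numeric matrix, species x axes.
#' @export
phyloPredictors <- function(tree, species = NULL, cumMass = 0.95) {
  D <- ape::cophenetic.phylo(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(D))
    if (length(miss))
      stop("species absent from tree: ", paste(miss, collapse = ", "))
    D <- D[species, species]
  }
  pc <- stats::cmdscale(D, k = nrow(D) - 1L, eig = TRUE)
  eig <- pc$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(eig))
  cum <- cumsum(eig[pos]) / sum(eig[pos])
  keep <- seq_len(min(which(cum >= cumMass)))
  X <- pc$points[, pos[keep], drop = FALSE]
  colnames(X) <- paste0("PCo", seq_len(ncol(X)))
  X
}

#' Biological-property predictors
#'
#' Per-species counts of utilized carbon sources in each molecular
#' category: the number of hexoses, glucosides, sugar alcohols, etc. a
#' species can grow on.
#'
#' @param m binary matrix or imputed binary [TraitMatrix-class].
#' @param categoryMap named character vector mapping trait id to category
#'   label; traits absent from the map are ignored.
#' @return numeric matrix, species x categories.
#' @export
biologyPredictors <- function(m, categoryMap) {
  mm <- .asBinaryMatrix(m)
  traits <- intersect(colnames(mm), names(categoryMap))
  if (!length(traits))
    stop("no traits matched the category map")
  cats <- sort(unique(categoryMap[traits]))
  X <- vapply(cats, function(cat) {
    cols <- traits[categoryMap[traits] == cat]
    rowSums(mm[, cols, drop = FALSE])
  }, numeric(nrow(mm)))
  X <- matrix(X, nrow = nrow(mm), dimnames = list(rownames(mm), cats))
  X
}
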