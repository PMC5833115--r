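#' Signed association profiles
#'
#' Builds the trait x trait matrix of signed association strengths used
#' for clustering: +str_pos where a pair is significantly positive,
#' -str_neg where significantly negative, and 0 elsewhere (including the
#' diagonal).  The signed encoding keeps the positive/negative distinction
#' when profiles are compared.
#'
#' @param assoc an association table from [associateAllTraits()].
#' @param traits optional trait ordering; default is the sorted union of
#'   the table's items.
#' @return numeric matrix, traits x traits, symmetric with zero diagonal.
#' @export
associationProfiles <- function(assoc, traits = NULL) {
  if (is.null(traits))
    traits <- sort(unique(c(assoc$item_a, assoc$item_b)))
  S <- matrix(0, length(traits), length(traits),
    dimnames = list(traits, traits))
  sig <- assoc[assoc$direction != "none", , drop = FALSE]
  if (nrow(sig)) {
    val <- ifelse(sig$direction == "positive", sig$str_pos, -sig$str_neg)
    ia <- match(sig$item_a, traits)
    ib <- match(sig$item_b, traits)
    S[cbind(ia, ib)] <- val
    S[cbind(ib, ia)] <- val
  }
  S
}

#' Euclidean distance between association profiles
#'
#' @param profiles trait x trait signed strength matrix from
#'   [associationProfiles()]; rows must share one trait ordering with the
#'   columns.
#' @return a `dist` object (symmetric, zero diagonal, Euclidean).
#' @export
profileDistance <- function(profiles) {
  if (!identical(rownames(profiles), colnames(profiles)))
    stop("profile rows and columns must use the same trait ordering")
  stats::dist(profiles, method = "euclidean")
}

#' Ward clustering of traits
#'
#' Ward.D2 linkage (variance criterion on squared distances) by default;
#' `"ward.D"` is available since historical implementations differ.
#'
#' @param d a `dist` object over at least two traits.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return an `hclust` tree.
#' @export
wardCluster <- function(d, method = c("ward.D2", "ward.D")) {
  if (attr(d, "Size") < 2L)
    stop("need at least 2 items to cluster")
  stats::hclust(d, method = match.arg(method))
}

# tip-label sets of every internal node of an hclust tree
.hclustClusters <- function(h) {
  n <- length(h$labels)
  sets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    kids <- h$merge[i, ]
    mem <- unlist(lapply(kids, function(k)
      if (k < 0) h$labels[-k] else sets[[k]]))
    sets[[i]] <- sort(mem)
  }
  sets
}

#' Bootstrap support for trait clusters
#'
#' Resamples the profile coordinates (columns) with replacement, re-runs
#' the Ward clustering, and reports for every internal node of the
#' reference dendrogram the fraction of bootstrap trees that recover
#' exactly the same trait set (bootstrap probability, BP).  The root is
#' recovered by construction and reported with support 1.
#'
#' @param profiles trait x trait signed strength matrix.
#' @param nBoot bootstrap replicates (default 1000).
#' @param method Ward flavour, see [wardCluster()].
#' @param level support level at which a cluster is flagged significant
#'   (default 0.95).
#' @return list with `hclust` (reference tree) and `support`, a data.frame
#'   of node id, member traits, BP support and the significance flag.
#' @export
clusterSupport <- function(profiles, nBoot = 1000L,
    method = c("ward.D2", "ward.D"), level = 0.95) {
  method <- match.arg(method)
  if (nrow(profiles) < 3L)
    stop("need at least 3 traits for cluster support")
  ref <- wardCluster(profileDistance(profiles), method = method)
  refSets <- .hclustClusters(ref)
  keys <- vapply(refSets, paste, "", collapse = "\r")
  hits <- integer(length(keys))
  for (b in seq_len(nBoot)) {
    cols <- sample.int(ncol(profiles), replace = TRUE)
    hb <- wardCluster(stats::dist(profiles[, cols, drop = FALSE]),
      method = method)
    bk <- vapply(.hclustClusters(hb), paste, "", collapse = "\r")
    hits <- hits + (keys %in% bk)
  }
  support <- hits / nBoot
  support[length(support)] <- 1  # root: whole trait set, by convention
  list(hclust = ref, support = data.frame(
    node = seq_along(support),
    members = vapply(refSets, paste, "", collapse = ";"),
    bp = support, significant = support >= level,
    stringsAsFactors = FALSE))
}

#' Export a supported dendrogram as newick
#'
#' Converts the reference tree of [clusterSupport()] to a phylo object
#' with BP supports as internal node labels.
#'
#' @param cs result of [clusterSupport()].
#' @return an `ape::phylo` tree.
#' @export
supportedDendrogram <- function(cs) {
  phy <- ape::as.phylo(cs$hclust)
  # hclust merge order maps to phylo internal nodes by matching tip sets
  refSets <- .hclustClusters(cs$hclust)
  keys <- vapply(refSets, paste, "", collapse = "\r")
  nt <- length(cs$hclust$labels)
  lab <- rep("", phy$Nnode)
  for (nd in seq_len(phy$Nnode)) {
    tips <- sort(phy$tip.label[unlist(.phyloTips(nt + nd, phy))])
    k <- match(paste(tips, collapse = "\r"), keys)
    if (!is.na(k)) lab[nd] <- format(cs$support$bp[k], digits = 3)
  }
  phy$node.label <- lab
  phy
}

.phyloTips <- function(node, phy) {
  nt <- length(phy$tip.label)
  if (node <= nt) return(node)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .phyloTips, phy = phy))
}
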