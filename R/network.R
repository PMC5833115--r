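#' Build a signed trait association network
#'
#' Nodes are the (carbon) traits with at least one significant association
#' of the given sign; edges connect significantly associated pairs,
#' weighted by association strength.  Vertices are added in sorted id
#' order so downstream community detection is order-invariant.
#'
#' @param assoc association table from [associateAllTraits()].
#' @param sign `"positive"` or `"negative"`.
#' @param traits optional trait subset (e.g. carbon sources); pairs with
#'   either member outside it are dropped.
#' @param categories optional named character vector of node category
#'   labels (molecular structure classes).
#' @return A [TraitNetwork-class]; empty networks draw a warning.
#' @export
buildNetwork <- function(assoc, sign = c("positive", "negative"),
    traits = NULL, categories = NULL) {
  sign <- match.arg(sign)
  ed <- assoc[assoc$direction == sign, , drop = FALSE]
  if (!is.null(traits))
    ed <- ed[ed$item_a %in% traits & ed$item_b %in% traits, , drop = FALSE]
  if (!nrow(ed))
    warning("no significant ", sign, " associations; empty network")
  nodes <- sort(unique(c(ed$item_a, ed$item_b)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$item_a, to = ed$item_b,
      weight = ed$strength, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  cats <- character()
  if (!is.null(categories)) {
    cats <- categories[nodes]
    names(cats) <- nodes
  }
  new("TraitNetwork", graph = g, sign = sign, communities = integer(),
    modularity = NA_real_, categories = cats)
}

#' Greedy modularity communities (Clauset-Newman-Moore)
#'
#' Agglomerative modularity maximization on the strength-weighted graph
#' (fast-greedy); disconnected components are handled within the single
#' run.  Returns the partition at maximum modularity along the merge path
#' and its Q.
#'
#' @param net a [TraitNetwork-class] with at least one edge.
#' @param weighted use edge strengths as weights (default TRUE).
#' @return The network with `communities` (named membership) and
#'   `modularity` filled in.
#' @export
cnmCommunities <- function(net, weighted = TRUE) {
  stopifnot(is(net, "TraitNetwork"))
  g <- net@graph
  if (igraph::ecount(g) == 0L)
    stop("network has no edges")
  w <- if (weighted) igraph::E(g)$weight else NULL
  cl <- igraph::cluster_fast_greedy(g, weights = w)
  mem <- igraph::membership(cl)
  net@communities <- stats::setNames(as.integer(mem),
    igraph::V(g)$name)
  net@modularity <- igraph::modularity(g, mem, weights = w)
  net
}

#' Modularity of an explicit partition
#'
#' @param net a [TraitNetwork-class].
#' @param membership integer community id per node (named or in vertex
#'   order).
#' @param weighted use edge strengths as weights (default TRUE).
#' @return modularity Q.
#' @export
partitionModularity <- function(net, membership, weighted = TRUE) {
  g <- net@graph
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(g)$name]
  igraph::modularity(g, membership,
    weights = if (weighted) igraph::E(g)$weight else NULL)
}

#' Category enrichment within communities
#'
#' For every (community, category) combination present in the network, a
#' two-sided Fisher exact test on the 2x2 table of node membership in the
#' community against node membership in the category, computed over the
#' network's nodes.
#'
#' @param net a [TraitNetwork-class] with communities detected.
#' @param categoryMap named character vector, trait id -> category; every
#'   node must be categorized.
#' @return data.frame: community, category, counts of the 2x2 table, odds
#'   ratio and two-sided Fisher p.
#' @export
communityEnrichment <- function(net, categoryMap = NULL) {
  stopifnot(is(net, "TraitNetwork"))
  if (!length(net@communities))
    stop("run cnmCommunities() first")
  if (is.null(categoryMap)) categoryMap <- net@categories
  nodes <- names(net@communities)
  miss <- nodes[!nodes %in% names(categoryMap) |
    is.na(categoryMap[nodes])]
  if (length(miss))
    stop("uncategorized node(s): ", paste(miss, collapse = ", "))
  cats <- categoryMap[nodes]
  res <- list()
  for (comm in sort(unique(net@communities))) {
    inComm <- net@communities == comm
    for (cat in sort(unique(cats))) {
      inCat <- cats == cat
      if (!any(inCat)) next
      tab <- matrix(c(sum(inComm & inCat), sum(inComm & !inCat),
        sum(!inComm & inCat), sum(!inComm & !inCat)), 2L)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      res[[length(res) + 1L]] <- data.frame(
        community = comm, category = cat,
        in_comm_in_cat = tab[1L, 1L], in_comm_out_cat = tab[2L, 1L],
        out_comm_in_cat = tab[1L, 2L], out_comm_out_cat = tab[2L, 2L],
        odds_ratio = unname(ft$estimate), p = ft$p.value)
    }
  }
  do.call(rbind, res)
}

#' Enrichment of positive over negative associations among carbon traits
#'
#' Tests whether significant carbon-carbon trait pairs are biased toward
#' positive direction relative to the other significant pairs: a
#' two-sided Fisher exact test on {carbon-carbon, other} x {positive,
#' negative}.  `method = "binomial"` instead tests the carbon-carbon
#' positive/negative split against an even 50/50 expectation.
#'
#' @param assoc association table.
#' @param carbonTraits character vector of carbon-source trait ids.
#' @param method `"fisher"` (default) or `"binomial"`.
#' @return list with the 2x2 `table` (or counts) and the two-sided `p`.
#' @export
signEnrichment <- function(assoc, carbonTraits,
    method = c("fisher", "binomial")) {
  method <- match.arg(method)
  sig <- assoc[assoc$direction %in% c("positive", "negative"), ,
    drop = FALSE]
  carbon <- sig$item_a %in% carbonTraits & sig$item_b %in% carbonTraits
  if (method == "fisher") {
    tab <- table(factor(ifelse(carbon, "carbon", "other"),
      c("carbon", "other")),
      factor(sig$direction, c("positive", "negative")))
    ft <- stats::fisher.test(tab, alternative = "two.sided")
    list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
  } else {
    npos <- sum(carbon & sig$direction == "positive")
    n <- sum(carbon)
    bt <- stats::binom.test(npos, n, p = 0.5)
    list(table = c(positive = npos, negative = n - npos), p = bt$p.value)
  }
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net a [TraitNetwork-class].
#' @param edgePath path for the edge-list TSV (from, to, weight, sign).
#' @param graphmlPath optional path for a GraphML export.
#' @return `edgePath`, invisibly.
#' @export
exportNetwork <- function(net, edgePath, graphmlPath = NULL) {
  g <- net@graph
  el <- igraph::as_data_frame(g, what = "edges")
  el$sign <- net@sign
  if (length(net@communities)) {
    el$community_from <- net@communities[el$from]
    el$community_to <- net@communities[el$to]
  }
  utils::write.table(el, edgePath, sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(graphmlPath)) {
    if (length(net@communities))
      igraph::V(g)$community <- as.integer(net@communities[igraph::V(g)$name])
    if (length(net@categories))
      igraph::V(g)$category <- as.character(net@categories[igraph::V(g)$name])
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  invisible(edgePath)
}
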