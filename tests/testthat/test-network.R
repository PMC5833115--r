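edgeAssoc <- function(el, strength = 1) {
  data.frame(item_a = el[, 1], item_b = el[, 2], direction = "positive",
    strength = rep_len(strength, nrow(el)), stringsAsFactors = FALSE)
}

test_that("networks keep only significant same-sign pairs", {
  assoc <- data.frame(
    item_a = c("a", "a", "b"), item_b = c("b", "c", "c"),
    direction = c("positive", "negative", "none"),
    strength = c(5, 3, 1))
  net <- buildNetwork(assoc, "positive")
  expect_equal(igraph::ecount(net@graph), 1)
  expect_setequal(igraph::V(net@graph)$name, c("a", "b"))
  expect_warning(buildNetwork(assoc[assoc$direction == "none", ],
    "negative"), "empty")
})

test_that("node degree equals the count of significant same-sign partners", {
  set.seed(81)
  sim <- simulateTraitMatrix(nSpecies = 300, nTraits = 12,
    modules = list(1:4, 5:8), missingRate = 0, variableRate = 0)
  assoc <- associateAllTraits(as.matrix(sim$binary), nPerm = 300,
    nSwaps = 4000)
  net <- buildNetwork(assoc, "positive")
  sig <- significantPairs(assoc, "positive")
  for (v in igraph::V(net@graph)$name) {
    expect_equal(
      unname(igraph::degree(net@graph, v)),
      sum(sig$item_a == v | sig$item_b == v))
  }
})

test_that("greedy communities recover twin cliques and match brute force", {
  el <- rbind(t(combn(paste0("p", 1:4), 2)), t(combn(paste0("q", 1:4), 2)),
    c("p4", "q1"))
  w <- rep(1, nrow(el))
  net <- cnmCommunities(buildNetwork(edgeAssoc(el), "positive"))
  brute <- bruteForceBestPartition(el, w)
  expect_true(samePartition(net@communities, brute$membership))
  expect_equal(net@modularity, brute$Q, tolerance = 1e-10)
  split_ <- split(names(net@communities), net@communities)
  expect_setequal(vapply(split_, paste, "", collapse = ","),
    c("p1,p2,p3,p4", "q1,q2,q3,q4"))
})

test_that("a single edge has zero modularity in one community", {
  net <- cnmCommunities(buildNetwork(edgeAssoc(cbind("a", "b")), "positive"))
  one <- stats::setNames(c(1L, 1L), c("a", "b"))
  expect_equal(partitionModularity(net, one), 0)
})

test_that("greedy Q matches brute force on assorted small weighted graphs", {
  graphs <- list(
    # two triangles bridged
    list(el = rbind(c("a", "b"), c("b", "c"), c("a", "c"),
      c("d", "e"), c("e", "f"), c("d", "f"), c("c", "d")),
      w = c(2, 2, 2, 2, 2, 2, 0.5)),
    # disconnected pair of edges
    list(el = rbind(c("a", "b"), c("c", "d")), w = c(1, 2)),
    # path of five nodes
    list(el = cbind(paste0("m", 1:4), paste0("m", 2:5)), w = rep(1, 4)))
  for (g in graphs) {
    assoc <- edgeAssoc(g$el, g$w)
    net <- cnmCommunities(buildNetwork(assoc, "positive"))
    brute <- bruteForceBestPartition(g$el, g$w)
    expect_equal(net@modularity, brute$Q, tolerance = 1e-10)
    expect_true(samePartition(net@communities, brute$membership))
  }
})

test_that("detected Q dominates random partitions of the same graph", {
  set.seed(83)
  el <- rbind(t(combn(paste0("n", 1:5), 2))[sample(10, 7), ],
    c("n1", "n6"), c("n6", "n7"))
  w <- runif(nrow(el), 0.5, 2)
  net <- cnmCommunities(buildNetwork(edgeAssoc(el, w), "positive"))
  nodes <- igraph::V(net@graph)$name
  for (i in 1:1000) {
    mem <- stats::setNames(sample(3, length(nodes), replace = TRUE), nodes)
    expect_gte(net@modularity, partitionModularity(net, mem) - 1e-12)
  }
})

test_that("community detection ignores node input order", {
  el <- rbind(t(combn(paste0("p", 1:4), 2)), t(combn(paste0("q", 1:4), 2)),
    c("p4", "q1"))
  a <- cnmCommunities(buildNetwork(edgeAssoc(el), "positive"))
  rev_ <- el[rev(seq_len(nrow(el))), 2:1]
  b <- cnmCommunities(buildNetwork(edgeAssoc(rev_), "positive"))
  expect_true(samePartition(a@communities, b@communities))
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  # exact oracle over all 2x2 tables with n <= 10 (full sweep in the
  # acceptance suite)
  for (a in 0:3) for (b in 0:3) for (c in 0:2) for (d in 0:2) {
    if (a + b + c + d < 2 || a + b == 0 || c + d == 0) next
    tab <- matrix(c(a, c, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fisherOracle(a, b, c, d),
      tolerance = 1e-9)
  }
})

test_that("community-category enrichment flags a perfect overlap", {
  el <- rbind(t(combn(paste0("p", 1:4), 2)), t(combn(paste0("q", 1:4), 2)),
    c("p4", "q1"))
  cmap <- c(stats::setNames(rep("gluco", 4), paste0("p", 1:4)),
    stats::setNames(rep("galacto", 4), paste0("q", 1:4)))
  net <- cnmCommunities(buildNetwork(edgeAssoc(el), "positive",
    categories = cmap))
  enr <- communityEnrichment(net)
  perfect <- enr[enr$in_comm_in_cat == 4 & enr$out_comm_in_cat == 0, ]
  expect_equal(perfect$p, rep(fisherOracle(4, 0, 0, 4), nrow(perfect)))
  # minimal attainable p for these margins
  expect_equal(unique(round(perfect$p, 12)), round(2 / choose(8, 4), 12))
  expect_error(communityEnrichment(net, cmap[-1]), "uncategorized")
})

test_that("sign enrichment is null when strata split evenly", {
  assoc <- data.frame(
    item_a = c("c1", "c2", "x1", "x2"), item_b = c("c3", "c4", "x3", "x4"),
    direction = c("positive", "negative", "positive", "negative"))
  res <- signEnrichment(assoc, paste0("c", 1:4))
  expect_equal(res$p, 1)
  resB <- signEnrichment(assoc, paste0("c", 1:4), method = "binomial")
  expect_equal(resB$p, 1)
})

test_that("networks export as edge lists and GraphML", {
  el <- rbind(c("a", "b"), c("b", "c"))
  net <- cnmCommunities(buildNetwork(edgeAssoc(el, c(2, 3)), "positive"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, tsv, gml)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), 2L)
  expect_true(any(grepl("graphml", readLines(gml, n = 3))))
})
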