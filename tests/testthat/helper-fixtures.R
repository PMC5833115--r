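# Shared fixtures and independent oracles for the test suite.

# random coded trait matrix (raw codes 0/1/2/NA)
randomRawMatrix <- function(nSpecies, nTraits,
    probs = c(absent = 0.35, present = 0.45, variable = 0.1, missing = 0.1)) {
  codes <- sample(c(0L, 1L, 2L, NA_integer_), nSpecies * nTraits,
    replace = TRUE, prob = probs)
  m <- matrix(codes, nSpecies, nTraits,
    dimnames = list(sprintf("sp%03d", seq_len(nSpecies)),
      sprintf("tr%02d", seq_len(nTraits))))
  TraitMatrix(m, coding = "raw")
}

namedBinary <- function(m) {
  if (is.null(rownames(m)))
    dimnames(m) <- list(sprintf("s%03d", seq_len(nrow(m))),
      sprintf("t%02d", seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}

# exhaustive enumeration of the binary matrices with the margins of m
enumerateMarginClass <- function(m) {
  n <- length(m)
  grid <- expand.grid(rep(list(0:1), n))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    cand <- matrix(as.integer(grid[i, ]), nrow(m), ncol(m))
    if (all(rowSums(cand) == rowSums(m)) &&
        all(colSums(cand) == colSums(m)))
      out[[length(out) + 1L]] <- cand
  }
  out
}

# all set partitions of n items as membership vectors (restricted growth)
allPartitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxUsed) {
    k <- length(prefix)
    if (k == n) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (g in seq_len(maxUsed + 1L))
      rec(c(prefix, g), max(maxUsed, g))
  }
  rec(integer(), 0L)
  res
}

# hand-written weighted modularity, independent of igraph:
# Q = sum_c [ w_in(c)/W - (s(c)/(2W))^2 ], W = total edge weight,
# s(c) = sum of weighted degrees in c, w_in counts each within edge once
handModularity <- function(edges, weights, membership) {
  W <- sum(weights)
  deg <- tapply(c(weights, weights), c(edges[, 1L], edges[, 2L]), sum)
  comms <- unique(membership)
  Q <- 0
  for (cm in comms) {
    nodes <- names(membership)[membership == cm]
    within <- edges[, 1L] %in% nodes & edges[, 2L] %in% nodes
    win <- sum(weights[within])
    s <- sum(deg[nodes], na.rm = TRUE)
    Q <- Q + win / W - (s / (2 * W))^2
  }
  Q
}

bruteForceBestPartition <- function(edges, weights) {
  nodes <- sort(unique(c(edges[, 1L], edges[, 2L])))
  parts <- allPartitions(length(nodes))
  best <- NULL
  bestQ <- -Inf
  for (p in parts) {
    mem <- stats::setNames(p, nodes)
    q <- handModularity(edges, weights, mem)
    if (q > bestQ + 1e-12) {
      bestQ <- q
      best <- mem
    }
  }
  list(membership = best, Q = bestQ)
}

# two-sided Fisher exact p by hypergeometric enumeration for a 2x2 table
# with cells (a, b, c, d) = (x11, x12, x21, x22)
fisherOracle <- function(a, b, c, d) {
  m <- a + c   # first column total
  n <- b + d
  k <- a + b   # first row total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# membership vectors describe the same partition up to label renaming
samePartition <- function(a, b) {
  a <- a[sort(names(a))]
  b <- b[sort(names(b))]
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# quick association table row lookup (unordered pair)
assocRow <- function(assoc, a, b) {
  hit <- (assoc$item_a == a & assoc$item_b == b) |
    (assoc$item_a == b & assoc$item_b == a)
  assoc[hit, , drop = FALSE]
}
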