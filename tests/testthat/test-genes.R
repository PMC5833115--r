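test_that("same/different counts and the 2x2 chi-squared follow hand arithmetic", {
  # 2x2 [[20,5],[5,20]]: chi2 = n(ad-bc)^2/(r1 r2 c1 c2) = 50*375^2/25^4 = 18
  g <- c(rep(1L, 25), rep(0L, 25))
  w <- c(rep(1L, 20), rep(0L, 5), rep(1L, 5), rep(0L, 20))
  genes <- matrix(g, dimnames = list(sprintf("s%02d", 1:50), "G"))
  growth <- matrix(w, dimnames = list(sprintf("s%02d", 1:50), "C"))
  res <- geneGrowthChi2(genes, growth)
  expect_identical(res$same, 20L)
  expect_identical(res$different, 10L)  # 5 absent&growth + 5 present&no-growth
  expect_equal(res$chi2, 18)
  expect_equal(res$chi2, 50 * (20 * 20 - 5 * 5)^2 / (25^4))
})

test_that("a gene identical to its growth column has different = 0", {
  set.seed(91)
  w <- rbinom(40, 1, 0.5)
  genes <- matrix(as.integer(w), dimnames = list(sprintf("s%02d", 1:40), "G"))
  growth <- matrix(as.integer(w), dimnames = list(sprintf("s%02d", 1:40), "C"))
  res <- geneGrowthChi2(genes, growth)
  expect_identical(res$different, 0L)
  # maximal chi2 for these margins: n (perfect association)
  expect_equal(res$chi2, 40)
})

test_that("count identities hold and ordering does not matter", {
  set.seed(92)
  genes <- matrix(rbinom(120, 1, 0.6), 60, 2,
    dimnames = list(sprintf("s%02d", 1:60), c("G1", "G2")))
  growth <- matrix(rbinom(120, 1, 0.5), 60, 2,
    dimnames = list(sprintf("s%02d", 1:60), c("C1", "C2")))
  storage.mode(genes) <- "integer"; storage.mode(growth) <- "integer"
  res <- geneGrowthChi2(genes, growth)
  for (k in seq_len(nrow(res))) {
    g <- genes[, res$gene[k]]
    w <- growth[, res$carbon[k]]
    expect_identical(res$same[k] + res$different[k] +
      sum(g == 0L & w == 0L), 60L)
  }
  o <- sample(60)
  res2 <- geneGrowthChi2(genes[o, ], growth[o, ])
  expect_equal(res$chi2, res2$chi2)
  expect_equal(res$q, res2$q)
})

test_that("constant columns are skipped with NA statistics", {
  genes <- matrix(c(1L, 1L, 1L, 1L), dimnames = list(sprintf("s%d", 1:4), "G"))
  growth <- matrix(c(1L, 0L, 1L, 0L), dimnames = list(sprintf("s%d", 1:4), "C"))
  expect_message(res <- geneGrowthChi2(genes, growth), "not testable")
  expect_true(is.na(res$chi2))
  expect_identical(res$same, 2L)
})

test_that("identical gene groups show no co-occurrence contrast", {
  base <- rbinom(50, 1, 0.6)
  genes <- matrix(rep(as.integer(base), 4), 50, 4,
    dimnames = list(sprintf("s%02d", 1:50), c("a1", "a2", "b1", "b2")))
  res <- coOccurrenceTest(genes, c("a1", "a2"), c("b1", "b2"))
  expect_equal(res$within_freq, res$between_freq)
  expect_equal(res$p, 1)
})

test_that("group bookkeeping counts pairs within and across groups", {
  set.seed(93)
  genes <- matrix(rbinom(200, 1, 0.5), 20, 10,
    dimnames = list(sprintf("s%02d", 1:20), sprintf("g%02d", 1:10)))
  storage.mode(genes) <- "integer"
  g1 <- sprintf("g%02d", 1:5)
  g2 <- sprintf("g%02d", 6:10)
  res <- coOccurrenceTest(genes, g1, g2)
  expect_equal(res$within_total, 20 * (choose(5, 2) * 2))
  expect_equal(res$between_total, 20 * 25)
  expect_error(coOccurrenceTest(genes, g1, c("g05", "g06")), "disjoint")
  expect_error(coOccurrenceTest(genes, character(), g2), "non-empty")
})

test_that("co-inherited gene groups recover the planted frequency gap", {
  set.seed(94)
  n <- 500
  # group-1 genes ride one pathway trait, group-2 another; the traits are
  # independent, so between-group co-occurrence is the product of the
  # within-group rates
  t1 <- rbinom(n, 1, 0.7)
  t2 <- rbinom(n, 1, 0.7)
  mk <- function(t) as.integer(ifelse(rbinom(n, 1, 0.05) == 1, 1 - t, t))
  genes <- cbind(a1 = mk(t1), a2 = mk(t1), a3 = mk(t1),
    b1 = mk(t2), b2 = mk(t2), b3 = mk(t2))
  rownames(genes) <- sprintf("s%03d", 1:n)
  res <- coOccurrenceTest(genes, c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  gap <- res$within_freq - res$between_freq
  # analytic expectation: within ~ 0.7 * 0.905^2 + 0.3 * 0.05^2 ~ 0.574
  # minus between ~ (0.7 * 0.905 + 0.3 * 0.05)^2 ~ 0.419
  expect_lt(abs(gap - 0.155), 0.05)
  expect_lt(res$p, 0.001)
})

test_that("the equal-proportions test honors the continuity-correction switch", {
  genes <- cbind(a1 = rep(c(1L, 0L), c(30, 10)),
    a2 = rep(c(1L, 0L), c(28, 12)),
    b1 = rep(c(0L, 1L), c(20, 20)), b2 = rep(c(1L, 0L), c(15, 25)))
  rownames(genes) <- sprintf("s%02d", 1:40)
  yates <- coOccurrenceTest(genes, c("a1", "a2"), c("b1", "b2"))
  plain <- coOccurrenceTest(genes, c("a1", "a2"), c("b1", "b2"),
    correct = FALSE)
  ref <- stats::prop.test(c(yates$within_events, yates$between_events),
    c(yates$within_total, yates$between_total), correct = FALSE)
  expect_equal(plain$chi2, unname(ref$statistic))
  expect_gte(plain$chi2, yates$chi2)
})
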