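test_that("pair counts follow the (1,1) and (1,0)+(0,1) definitions", {
  m <- namedBinary(cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0)))
  colnames(m) <- c("a", "b")
  counts <- pairCounts(m, "a", "b")
  expect_identical(counts[["positive_obs"]], 1L)
  expect_identical(counts[["negative_obs"]], 2L)
  m2 <- cbind(m, c = m[, "a"])
  expect_identical(pairCounts(m2, "a", "c")[["negative_obs"]], 0L)
  expect_error(pairCounts(m, "a", "a"), "itself")
})

test_that("pair counts partition the species set", {
  set.seed(31)
  m <- namedBinary(matrix(rbinom(300, 1, 0.4), 50, 6))
  for (rep in 1:10) {
    ij <- sample(6, 2)
    counts <- pairCounts(m, ij[1], ij[2])
    both0 <- sum(m[, ij[1]] == 0 & m[, ij[2]] == 0)
    expect_identical(unname(counts[1] + counts[2]) + both0, 50L)
  }
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_identical(bhAdjust(numeric()), numeric())
  set.seed(32)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(q <= 1))
  # order preservation: adjusting a permuted copy permutes the q-values
  o <- sample(50)
  expect_equal(bhAdjust(p[o]), q[o])
})

test_that("empirical p hits the add-one floor for extreme observations", {
  set.seed(33)
  # a pair engineered so that observed co-occurrence is maximal
  m <- namedBinary(matrix(rbinom(600, 1, 0.5), 100, 6))
  m[, 1] <- c(rep(1L, 50), rep(0L, 50))
  m[, 2] <- m[, 1]
  assoc <- associateAllTraits(m, nPerm = 500, nSwaps = 3000)
  row <- assocRow(assoc, "t01", "t02")
  expect_equal(row$p_pos, 1 / 501)
})

test_that("empirical tail probabilities match enumeration on the 3x3 class", {
  start <- matrix(c(1L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L), 3, 3, byrow = TRUE)
  class3 <- enumerateMarginClass(start)
  posNull <- vapply(class3, function(x) sum(x[, 1] * x[, 2]), 0)
  obs <- sum(start[, 1] * start[, 2])
  exactTail <- mean(posNull >= obs)
  set.seed(34)
  ens <- buildEnsemble(start, pairs = data.frame(item_a = 1, item_b = 2),
    nPerm = 10000, nSwaps = 200)
  pHat <- ens@posExceed / ens@nPerm
  se <- sqrt(exactTail * (1 - exactTail) / 10000)
  expect_lt(abs(pHat - exactTail), 4 * se)
})

test_that("independent traits are almost never called significant", {
  set.seed(35)
  hits <- 0
  tot <- 0
  for (seed in 1:3) {
    m <- namedBinary(matrix(rbinom(200 * 10, 1, 0.4), 200, 10))
    assoc <- associateAllTraits(m, nPerm = 500, nSwaps = 4000)
    hits <- hits + sum(assoc$direction != "none")
    tot <- tot + nrow(assoc)
  }
  expect_lte(hits / tot, 0.08)
})

test_that("strength is invariant to species relabeling", {
  set.seed(36)
  m <- namedBinary(matrix(rbinom(400, 1, 0.4), 50, 8))
  o <- sample(50)
  set.seed(99)
  a <- associateAllTraits(m, nPerm = 300, nSwaps = 2000)
  set.seed(99)
  b <- associateAllTraits(m[o, ], nPerm = 300, nSwaps = 2000)
  expect_equal(a$positive_obs, b$positive_obs)
  expect_equal(a$negative_obs, b$negative_obs)
})

test_that("environment columns are fixed and tested against the trait null", {
  set.seed(37)
  m <- namedBinary(matrix(rbinom(400, 1, 0.5), 50, 8))
  E <- cbind(match_t01 = m[, 1], indep = rbinom(50, 1, 0.5))
  rownames(E) <- rownames(m)
  env <- EnvironmentMatrix(E)
  assoc <- associateTraitEnvironment(m, env, nPerm = 500, nSwaps = 3000)
  perfect <- assoc[assoc$item_a == "t01" & assoc$item_b == "match_t01", ]
  expect_identical(perfect$positive_obs, sum(m[, 1]))
  expect_equal(perfect$p_pos, 1 / 501)
  # an ineligible environment is refused
  E2 <- cbind(tiny = c(1L, 1L, 1L, rep(0L, 47)))
  rownames(E2) <- rownames(m)
  expect_error(
    associateTraitEnvironment(m, EnvironmentMatrix(E2), nPerm = 100,
      environments = "tiny"),
    "neligible")
})

test_that("environments independent of traits stay mostly non-significant", {
  set.seed(38)
  m <- namedBinary(matrix(rbinom(200 * 8, 1, 0.4), 200, 8))
  E <- matrix(rbinom(200 * 5, 1, 0.3), 200, 5,
    dimnames = list(rownames(m), sprintf("e%d", 1:5)))
  assoc <- associateTraitEnvironment(m, EnvironmentMatrix(E), nPerm = 500,
    nSwaps = 4000)
  expect_lte(mean(assoc$direction != "none"), 0.08)
})

test_that("non-significant pairs report the larger-difference side", {
  set.seed(39)
  m <- namedBinary(matrix(rbinom(300, 1, 0.5), 50, 6))
  assoc <- associateAllTraits(m, nPerm = 300, nSwaps = 2000)
  none <- assoc[assoc$direction == "none", ]
  expect_true(all(none$strength == pmax(none$str_pos, none$str_neg)))
  sig <- assoc[assoc$direction == "positive", ]
  if (nrow(sig))
    expect_true(all(sig$observed == sig$positive_obs))
})
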