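test_that("response coding marks only both-present species-pairs", {
  m <- namedBinary(rbind(c(1, 1, 1), c(1, 0, 0), c(0, 0, 0)))
  Y <- buildResponse(m)
  expect_identical(ncol(Y), 3L)
  expect_true(all(Y[1, ] == 1))  # all traits present
  expect_true(all(Y[2, ] == 0))  # exactly one trait present
  expect_true(all(Y[3, ] == 0))  # none present
})

test_that("response column sums equal the observed positive pair counts", {
  set.seed(61)
  m <- namedBinary(matrix(rbinom(200, 1, 0.5), 40, 5))
  Y <- buildResponse(m)
  idx <- utils::combn(5, 2)
  for (k in seq_len(ncol(idx))) {
    counts <- pairCounts(m, idx[1, k], idx[2, k])
    expect_identical(sum(Y[, k]), unname(counts["positive_obs"]))
  }
})

test_that("adjusted R2 is 1 for exact fits and centered on 0 for noise", {
  set.seed(62)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- X %*% matrix(rnorm(6), 3, 2)
  expect_equal(adjustedR2(Y, X), 1)
  r2 <- replicate(100, {
    Yn <- matrix(rnorm(200 * 2), 200, 2)
    Xn <- matrix(rnorm(200 * 5), 200, 5)
    adjustedR2(Yn, Xn)
  })
  expect_lt(abs(mean(r2)), 0.02)
})

test_that("multivariate R2 is the variance-weighted average of univariate R2", {
  set.seed(63)
  X <- matrix(rnorm(100), 100, 1)
  Y <- cbind(2 * X + rnorm(100), 0.5 * X + rnorm(100, sd = 3))
  n <- 100
  r2uni <- apply(Y, 2, function(y) summary(lm(y ~ X))$r.squared)
  ssy <- apply(scale(Y, scale = FALSE), 2, function(y) sum(y^2))
  expected <- sum(r2uni * ssy) / sum(ssy)
  adj <- adjustedR2(Y, X)
  raw <- 1 - (1 - adj) * (n - 1 - 1) / (n - 1)
  expect_equal(raw, expected)
})

test_that("rank-deficient predictors are pruned with a warning", {
  set.seed(64)
  X <- matrix(rnorm(60), 30, 2)
  X <- cbind(X, X[, 1] + X[, 2])
  Y <- matrix(rnorm(60), 30, 2)
  expect_warning(adjustedR2(Y, X), "rank deficient")
})

test_that("the seven fractions sum to the full-model adjusted R2 exactly", {
  set.seed(65)
  for (rep in 1:5) {
    Y <- matrix(rnorm(120 * 4), 120, 4)
    X1 <- matrix(rnorm(120 * 3), 120, 3)
    X2 <- matrix(rnorm(120 * 2), 120, 2)
    X3 <- matrix(rnorm(120 * 2), 120, 2)
    pr <- partition3(Y, X1, X2, X3)
    f <- partitionFractions(pr)
    expect_lt(abs(sum(f[1:7]) - pr@r2[["phy.bio.env"]]), 1e-10)
    expect_lt(abs(sum(f) - 1), 1e-10)
  }
})

test_that("orthogonal predictor sets share essentially nothing", {
  set.seed(66)
  Q <- qr.Q(qr(matrix(rnorm(300 * 9), 300, 9)))
  X1 <- Q[, 1:3]; X2 <- Q[, 4:6]; X3 <- Q[, 7:9]
  Y <- Q %*% matrix(rnorm(9 * 4), 9, 4) + matrix(rnorm(300 * 4, sd = 0.5),
    300, 4)
  f <- partitionFractions(partition3(Y, X1, X2, X3))
  expect_lt(abs(f[["phy.bio"]]), 0.01)
  expect_lt(abs(f[["phy.env"]]), 0.01)
  expect_lt(abs(f[["bio.env"]]), 0.01)
  expect_lt(abs(f[["phy.bio.env"]]), 0.01)
})

test_that("a response built from one predictor set loads on its unique fraction", {
  set.seed(67)
  Xphy <- matrix(rnorm(200 * 3), 200, 3)
  Xbio <- matrix(rnorm(200 * 3), 200, 3)
  Xenv <- matrix(rnorm(200 * 2), 200, 2)
  Y <- Xbio %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(600, sd = 0.2), 200, 3)
  pr <- partition3(Y, Xphy, Xbio, Xenv)
  f <- partitionFractions(pr)
  total <- pr@r2[["phy.bio.env"]]
  expect_gt(f[["bio"]], 0.9 * total)
  expect_lt(abs(f[["phy"]]), 0.02)
  expect_lt(abs(f[["env"]]), 0.02)
})

test_that("fractions agree with an independent redundancy implementation", {
  skip_if_not_installed("vegan")
  set.seed(68)
  Y <- matrix(rnorm(100 * 4), 100, 4)
  X1 <- matrix(rnorm(100 * 3), 100, 3)
  X2 <- matrix(rnorm(100 * 2), 100, 2)
  X3 <- matrix(rnorm(100 * 2), 100, 2)
  f <- partitionFractions(partition3(Y, X1, X2, X3))
  vp <- vegan::varpart(Y, X1, X2, X3)
  ind <- vp$part$indfract$Adj.R.square
  # vegan order: a, b, c, ab, bc, ac, abc, residual
  expect_equal(unname(f[c("phy", "bio", "env", "phy.bio", "bio.env",
    "phy.env", "phy.bio.env", "residual")]), ind, tolerance = 1e-8)
})

test_that("consistent row permutations leave every fraction unchanged", {
  set.seed(69)
  Y <- matrix(rnorm(80 * 3), 80, 3)
  X1 <- matrix(rnorm(80 * 2), 80, 2)
  X2 <- matrix(rnorm(80 * 2), 80, 2)
  X3 <- matrix(rnorm(80 * 2), 80, 2)
  f <- partitionFractions(partition3(Y, X1, X2, X3))
  o <- sample(80)
  f2 <- partitionFractions(partition3(Y[o, ], X1[o, ], X2[o, ], X3[o, ]))
  expect_equal(f, f2)
})

test_that("phylogeny axes reproduce cophenetic distances and cap at 95% mass", {
  set.seed(70)
  tree <- ape::rphylo(25, 1, 0)
  X <- phyloPredictors(tree, cumMass = 1)
  D <- ape::cophenetic.phylo(tree)[rownames(X), rownames(X)]
  expect_equal(as.matrix(dist(X)), unname(D) + 0 * D, tolerance = 1e-6,
    ignore_attr = TRUE)
  X95 <- phyloPredictors(tree, cumMass = 0.95)
  expect_lte(ncol(X95), ncol(X))
})

test_that("biology predictors count utilized sources per category", {
  m <- namedBinary(rbind(c(1, 1, 0, 1), c(0, 1, 1, 0)))
  cmap <- c(t01 = "hexose", t02 = "hexose", t03 = "glucoside",
    t04 = "glucoside")
  X <- biologyPredictors(m, cmap)
  expect_identical(X[1, ], c(glucoside = 1, hexose = 2))
  expect_identical(X[2, ], c(glucoside = 1, hexose = 1))
})
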