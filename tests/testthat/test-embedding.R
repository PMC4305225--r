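test_that("tetrahedron affinities are uniform and rows hit target perplexity", {
  Y <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  aff <- conditionalAffinities(Y, perplexity = 3)
  P <- as.matrix(aff@P)
  off <- P[row(P) != col(P)]
  expect_equal(off, rep(1 / 3, 12), tolerance = 1e-9)

  set.seed(31)
  X <- matrix(rnorm(60 * 8), 60)
  aff2 <- conditionalAffinities(X, perplexity = 12)
  P2 <- as.matrix(aff2@P)
  H <- apply(P2, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  expect_true(all(abs(2^H - 12) <= 1e-4 * 12))
  expect_equal(unname(rowSums(P2)), rep(1, 60), tolerance = 1e-9)
})

test_that("stored neighbors are the exact kNN of each point", {
  set.seed(32)
  X <- matrix(rnorm(50 * 10), 50)
  aff <- conditionalAffinities(X, perplexity = 10)
  u <- floor(3 * 10)
  D <- as.matrix(dist(X))
  P <- as.matrix(aff@P)
  for (i in 1:50) {
    got <- which(P[i, ] > 0)
    want <- setdiff(order(D[i, ]), i)[1:u]
    expect_setequal(got, want)
  }
})

test_that("symmetrization yields a normalized symmetric joint distribution", {
  set.seed(33)
  X <- matrix(rnorm(40 * 5), 40)
  aff <- conditionalAffinities(X, perplexity = 8)
  joint <- symmetrizeAffinities(aff)
  P <- joint@P
  expect_equal(sum(P), 1, tolerance = 1e-9)
  expect_true(Matrix::isSymmetric(P))
  # sparsity pattern is the union of kNN relations
  C <- as.matrix(aff@P) > 0
  expect_identical(unname(as.matrix(P) > 0), unname(C | t(C)))
})

test_that("exact gradient matches a literal double-loop transcription", {
  set.seed(34)
  n <- 100
  X <- matrix(rnorm(n * 6), n)
  P <- symmetrizeAffinities(conditionalAffinities(X, perplexity = 15))
  Y <- matrix(rnorm(n * 2), n)
  expect_lt(max(abs(exactGradient(P, Y) - oracleExactGradient(P@P, Y))),
            1e-10)

  # two points with symmetric P: equal and opposite forces
  P2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.5, 0.5))
  Y2 <- rbind(c(0, 0), c(1, 1))
  g2 <- exactGradient(P2, Y2)
  expect_equal(g2[1, ], -g2[2, ], tolerance = 1e-12)

  # single point: no pairs, zero gradient
  expect_equal(exactGradient(Matrix::sparseMatrix(i = 1, j = 1, x = 0,
                                                  dims = c(1, 1)),
                             matrix(0, 1, 2)),
               matrix(0, 1, 2))
})

test_that("KL divergence matches its double-loop oracle and is non-negative", {
  set.seed(35)
  X <- matrix(rnorm(50 * 4), 50)
  P <- symmetrizeAffinities(conditionalAffinities(X, perplexity = 10))
  Y <- matrix(rnorm(50 * 2), 50)
  expect_equal(klDivergence(P, Y), oracleKl(P@P, Y), tolerance = 1e-10)
  expect_gte(klDivergence(P, Y), 0)

  # 2-point system where q matches p exactly -> KL = 0
  P2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(0.5, 0.5))
  Y2 <- rbind(c(0, 0), c(1, 0)) # q_12 = q_21 = 1/2 by symmetry
  expect_equal(klDivergence(P2, Y2), 0, tolerance = 1e-12)
})

test_that("Barnes-Hut gradient degenerates to exact at theta 0 and errs monotonically", {
  set.seed(36)
  n <- 300
  X <- matrix(rnorm(n * 8), n)
  P <- symmetrizeAffinities(conditionalAffinities(X, perplexity = 25))
  Y <- matrix(rnorm(n * 2), n)
  ge <- exactGradient(P, Y)

  expect_lt(max(abs(bhGradient(P, Y, theta = 0) - ge)), 1e-9)

  relErr <- function(theta) {
    norm(bhGradient(P, Y, theta = theta) - ge, "F") / norm(ge, "F")
  }
  errs <- vapply(c(1.0, 0.5, 0.25, 0.1), relErr, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_true(all(diff(errs) <= 1e-12)) # error non-increasing as theta drops
})

test_that("quadtree conserves mass and center of mass", {
  set.seed(37)
  Y <- matrix(rnorm(500 * 2), 500)
  Y[1:10, ] <- Y[11, c(1, 2)] # duplicates share a leaf
  s <- binscape:::quadtree_summary_cpp(Y)
  expect_identical(s$rootMass, 500L)
  expect_identical(s$leafPoints, 500L)
  expect_equal(s$rootCom, unname(colMeans(Y)), tolerance = 1e-9)
})

test_that("embedding is deterministic for a fixed seed and its math permutation-equivariant", {
  set.seed(38)
  X <- matrix(rnorm(80 * 6), 80)
  params <- TsneParams(perplexity = 10, nIter = 150, seed = 99)
  e1 <- runBhSne(X, params)
  e2 <- runBhSne(X, params)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))

  # affinities and gradients are equivariant to a row permutation (the
  # full trajectory is not comparable bitwise: gradient descent amplifies
  # reordered floating-point sums)
  set.seed(99)
  perm <- sample(80)
  P0 <- symmetrizeAffinities(conditionalAffinities(X, 10))
  Pp <- symmetrizeAffinities(conditionalAffinities(X[perm, ], 10))
  expect_lt(max(abs(as.matrix(Pp@P) - as.matrix(P0@P)[perm, perm])), 1e-12)
  Y <- matrix(rnorm(80 * 2), 80)
  g0 <- exactGradient(P0, Y)
  gp <- exactGradient(Pp, Y[perm, ])
  expect_lt(max(abs(gp - g0[perm, ])), 1e-9)
  gb <- bhGradient(Pp, Y[perm, ], theta = 0)
  expect_lt(max(abs(gb - g0[perm, ])), 1e-9)
})

test_that("two well-separated clusters embed with pure neighborhoods and decreasing KL", {
  set.seed(39)
  X <- rbind(matrix(rnorm(50 * 10), 50), matrix(rnorm(50 * 10) + 8, 50))
  labels <- rep(c("a", "b"), each = 50)
  emb <- runBhSne(X, TsneParams(perplexity = 10, seed = 4))
  expect_gte(knnLabelPurity(emb, labels, k = 5), 0.95)
  tr <- klTrace(emb)
  expect_lte(tr$kl[tr$iteration == 1000], tr$kl[tr$iteration == 300])
  expect_true(all(tr$kl >= 0))
})

test_that("multithreaded gradient reproduces the single-thread embedding", {
  set.seed(40)
  X <- rbind(matrix(rnorm(40 * 5), 40), matrix(rnorm(40 * 5) + 6, 40))
  p1 <- TsneParams(perplexity = 8, nIter = 300, seed = 5, nThreads = 1)
  p4 <- TsneParams(perplexity = 8, nIter = 300, seed = 5, nThreads = 4)
  e1 <- runBhSne(X, p1)
  e4 <- runBhSne(X, p4)
  # per-point forces are computed independently and Z is reduced in a
  # fixed order, so thread count does not change the arithmetic at all
  expect_identical(unname(embeddingCoords(e1)), unname(embeddingCoords(e4)))
  k1 <- tail(klTrace(e1)$kl, 1)
  k4 <- tail(klTrace(e4)$kl, 1)
  expect_lt(abs(k1 - k4) / k1, 0.01)
})

test_that("degenerate and invalid embedding inputs are handled", {
  expect_error(conditionalAffinities(matrix(0, 3, 2), 1), "at least 4")
  expect_error(conditionalAffinities(matrix(rnorm(20), 10), 10),
               "perplexity")
  # all-coincident points fall back to uniform conditionals
  aff <- conditionalAffinities(matrix(1, 8, 3), perplexity = 2)
  P <- as.matrix(aff@P)
  expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-12)
  expect_equal(max(P), 1 / 6, tolerance = 1e-12)
})
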