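# t-SNE: perplexity-calibrated affinities, exact and Barnes-Hut gradients,
# KL divergence, and the gradient-descent driver.

.squaredDistances <- function(X) {
  s <- rowSums(X^2)
  D2 <- outer(s, s, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  D2
}

.asSignatureValues <- function(X) {
  if (is(X, "SignatureMatrix")) unname(as.matrix(X)) else as.matrix(X)
}

#' Perplexity-calibrated conditional neighbor affinities
#'
#' For each point i, the `floor(3 * perplexity)` exact nearest neighbors
#' (Euclidean; ties broken by row index) receive Gaussian conditional
#' probabilities `p(j|i) ∝ exp(-beta_i * d_ij^2)`, with `beta_i` found
#' by binary search so that the Shannon entropy H of `p(.|i)` satisfies
#' `|log2(perplexity) - H| <= tol` (or after `maxIter` bisections).
#' If all neighbor distances of a point are zero the conditional
#' distribution falls back to uniform.
#'
#' @param X numeric matrix (rows = points) or a [SignatureMatrix].
#' @param perplexity target perplexity; must not exceed `n - 1`, and the
#'   `3 * perplexity` neighbor rule is only fully satisfiable when
#'   `perplexity <= (n - 1) / 3` (with fewer points available the
#'   neighbor count is capped at `n - 1`).
#' @param tol entropy tolerance in bits, default `1e-5`.
#' @param maxIter maximum bisection iterations per point, default 200.
#' @return an [AffinityMatrix] with `type = "conditional"` (each row of
#'   `P` sums to 1 over the stored neighbors).
#' @export
conditionalAffinities <- function(X, perplexity, tol = 1e-5,
                                  maxIter = 200L) {
  X <- .asSignatureValues(X)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 points")
  if (perplexity > n - 1)
    stop(sprintf("perplexity must be <= n - 1 = %d", n - 1L))
  u <- min(floor(3 * perplexity), n - 1L)
  D2 <- .squaredDistances(X)
  logU <- log2(perplexity)

  iAll <- integer(n * u)
  jAll <- integer(n * u)
  pAll <- numeric(n * u)
  beta <- numeric(n)

  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    d <- D2[i, others]
    ord <- order(d, others)[seq_len(u)] # stable: ties by row index
    nn <- others[ord]
    dn <- d[ord]

    if (all(dn == 0)) {
      p <- rep(1 / u, u)
      beta[i] <- Inf
    } else {
      b <- 1
      bmin <- -Inf
      bmax <- Inf
      for (it in seq_len(maxIter)) {
        w <- exp(-b * dn)
        s <- sum(w)
        p <- w / s
        # H in bits
        H <- (log(s) + b * sum(dn * w) / s) / log(2)
        diff <- H - logU
        if (abs(diff) <= tol) break
        if (diff > 0) { # entropy too high -> narrow the kernel
          bmin <- b
          b <- if (is.finite(bmax)) (b + bmax) / 2 else b * 2
        } else {
          bmax <- b
          b <- if (is.finite(bmin)) (b + bmin) / 2 else b / 2
        }
      }
      beta[i] <- b
    }
    k <- ((i - 1) * u + 1):(i * u)
    iAll[k] <- i
    jAll[k] <- nn
    pAll[k] <- p
  }

  P <- Matrix::sparseMatrix(i = iAll, j = jAll, x = pAll, dims = c(n, n))
  new("AffinityMatrix", P = P, beta = beta,
      perplexity = as.numeric(perplexity), type = "conditional")
}

#' Symmetrize conditional affinities into joint probabilities
#'
#' `p_ij = (p(j|i) + p(i|j)) / (2n)`; the result is symmetric and sums
#' to 1 over all stored pairs.
#'
#' @param affinities an [AffinityMatrix] of type `"conditional"`.
#' @return an [AffinityMatrix] of type `"joint"`.
#' @export
symmetrizeAffinities <- function(affinities) {
  stopifnot(is(affinities, "AffinityMatrix"),
            affinities@type == "conditional")
  P <- affinities@P
  n <- nrow(P)
  Pj <- (P + Matrix::t(P)) / (2 * n)
  new("AffinityMatrix", P = methods::as(Pj, "CsparseMatrix"),
      beta = affinities@beta, perplexity = affinities@perplexity,
      type = "joint")
}

.jointSparse <- function(P) {
  if (is(P, "AffinityMatrix")) P <- P@P
  methods::as(Matrix::drop0(P), "CsparseMatrix")
}

#' Exact t-SNE gradient (O(n^2) reference)
#'
#' `4 * sum_j (p_ij - q_ij) (1 + ||y_i - y_j||^2)^-1 (y_i - y_j)` with the
#' Student-t kernel `q_ij` normalized over all pairs. Kept as the
#' quadratic-cost reference against which the Barnes-Hut approximation is
#' validated; `bhGradient(theta = 0)` must agree with it.
#'
#' @param P joint affinities (an [AffinityMatrix] of type `"joint"` or a
#'   sparse/dense matrix).
#' @param Y n x 2 coordinate matrix.
#' @return n x 2 gradient matrix.
#' @export
exactGradient <- function(P, Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 2L) return(matrix(0, n, 2))
  Pm <- as.matrix(.jointSparse(P))
  D2 <- .squaredDistances(Y)
  W <- 1 / (1 + D2)
  diag(W) <- 0
  Z <- sum(W)
  Q <- W / Z
  M <- 4 * (Pm - Q) * W
  rowSums(M) * Y - M %*% Y
}

#' Barnes-Hut approximated t-SNE gradient
#'
#' Attractive forces are summed over the sparse affinities; repulsive
#' forces are approximated with a quadtree in which a cell of width `w`
#' at distance `r` is summarized by its center of mass when
#' `w / r < theta`. `theta = 0` reproduces the exact repulsive sum.
#'
#' @inheritParams exactGradient
#' @param theta Barnes-Hut accuracy in \[0, 1\].
#' @param nThreads threads used over points.
#' @return n x 2 gradient matrix.
#' @export
bhGradient <- function(P, Y, theta = 0.5, nThreads = 1L) {
  stopifnot(theta >= 0, theta <= 1)
  Y <- as.matrix(Y)
  Ps <- .jointSparse(P)
  # CSC of a symmetric matrix doubles as CSR: column i holds p(., i)
  bh_gradient_cpp(Y, Ps@p, Ps@i, Ps@x, theta, as.integer(nThreads))
}

#' Kullback-Leibler divergence of an embedding
#'
#' `sum p_ij log(p_ij / q_ij)` over the stored affinity pairs, with the
#' Student-t `q_ij` normalized over all pairs; `p` and `q` are floored at
#' `1e-12` inside the logarithm only.
#'
#' @inheritParams exactGradient
#' @return non-negative scalar.
#' @export
klDivergence <- function(P, Y) {
  Y <- as.matrix(Y)
  Ps <- .jointSparse(P)
  tr <- Matrix::summary(Ps)
  D2 <- .squaredDistances(Y)
  W <- 1 / (1 + D2)
  diag(W) <- 0
  Z <- sum(W)
  q <- W[cbind(tr$i, tr$j)] / Z
  p <- tr$x
  sum(p * (log(pmax(p, 1e-12)) - log(pmax(q, 1e-12))))
}

#' Run Barnes-Hut t-SNE on a signature matrix
#'
#' Computes perplexity-calibrated joint affinities, initializes the
#' embedding from `Gaussian(0, 1e-4)` (RNG seeded from `params@seed`),
#' multiplies the affinities by `earlyExaggeration` for the first
#' `exaggerationIter` iterations, and runs gradient descent with the
#' momentum schedule and per-parameter adaptive gains of the reference
#' implementation. The KL divergence (against the unexaggerated
#' affinities) is recorded every 50 iterations. With `nThreads = 1` the
#' result is bit-reproducible for a fixed seed.
#'
#' @param X numeric matrix or [SignatureMatrix] (rows = points, n >= 4).
#' @param params a [TsneParams].
#' @param Y0 optional n x 2 initial configuration (overrides the random
#'   initialization; used e.g. to continue a run or to test permutation
#'   equivariance).
#' @param verbose print progress every 50 iterations?
#' @return an [EmbeddingResult].
#' @export
runBhSne <- function(X, params = TsneParams(), Y0 = NULL, verbose = FALSE) {
  ids <- if (is(X, "SignatureMatrix")) X@ids else rownames(X)
  Xm <- .asSignatureValues(X)
  n <- nrow(Xm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n < 4L) stop("need at least 4 points to embed")

  aff <- conditionalAffinities(Xm, params@perplexity)
  joint <- symmetrizeAffinities(aff)
  P <- .jointSparse(joint)

  if (is.null(Y0)) {
    set.seed(params@seed)
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  } else {
    Y <- as.matrix(Y0)
    stopifnot(nrow(Y) == n, ncol(Y) == 2)
  }

  Pex <- P * params@earlyExaggeration
  gains <- matrix(1, n, 2)
  update <- matrix(0, n, 2)
  klIter <- integer(0)
  klVal <- numeric(0)

  for (iter in seq_len(params@nIter)) {
    Pcur <- if (iter <= params@exaggerationIter) Pex else P
    G <- bhGradient(Pcur, Y, theta = params@theta,
                    nThreads = params@nThreads)
    if (any(!is.finite(G)))
      stop("non-finite gradient at iteration ", iter,
           "; try a lower learning rate or higher perplexity")
    gains <- ifelse(sign(G) != sign(update), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    momentum <- if (iter <= params@momentumSwitch) params@momentumStart
                else params@momentumFinal
    update <- momentum * update - params@learningRate * gains * G
    Y <- Y + update
    Y <- sweep(Y, 2, colMeans(Y))
    if (any(!is.finite(Y)))
      stop("non-finite coordinates at iteration ", iter,
           "; optimization diverged")
    if (iter %% 50L == 0L || iter == params@nIter) {
      if (!length(klIter) || klIter[length(klIter)] != iter) {
        kl <- klDivergence(P, Y)
        klIter <- c(klIter, iter)
        klVal <- c(klVal, kl)
        if (verbose)
          message(sprintf("iteration %d: KL = %.4f", iter, kl))
      }
    }
  }

  new("EmbeddingResult", ids = ids, coords = Y,
      klTrace = data.frame(iteration = klIter, kl = klVal),
      params = params)
}
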