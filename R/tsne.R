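# Exact t-SNE. Quadratic in n, which is fine at the scales this package
# projects (hundreds to a few thousand records).

# Conditional Gaussian affinities for one point at a given precision beta.
hBeta <- function(d2, beta) {
  p <- exp(-d2 * beta)
  sumP <- sum(p)
  if (sumP == 0) return(list(H = 0, p = rep(0, length(p))))
  H <- log(sumP) + beta * sum(d2 * p) / sumP
  list(H = H, p = p / sumP)
}

# Per-point bisection on beta until the conditional entropy matches
# log(perplexity), the standard calibration.
calibrateAffinities <- function(d2, perplexity, tol = 1e-5, maxTries = 50L) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    di <- d2[i, -i]
    hb <- hBeta(di, beta)
    tries <- 0L
    while (abs(hb$H - logU) > tol && tries < maxTries) {
      if (hb$H > logU) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
      hb <- hBeta(di, beta)
      tries <- tries + 1L
    }
    P[i, -i] <- hb$p
  }
  P
}

#' Exact t-SNE embedding
#'
#' Standard t-distributed stochastic neighbor embedding: Gaussian input
#' affinities calibrated per point to the target perplexity, symmetrized;
#' Student-t (1 df) output affinities; gradient descent with momentum (0.5
#' for the first 250 iterations, then 0.8), learning rate 200, and early
#' exaggeration (x4) for the first 100 iterations. Deterministic given
#' `seed`, which drives the small random initialization.
#'
#' @param x numeric matrix (rows are points).
#' @param outDim output dimensionality, 2 or 3.
#' @param perplexity target perplexity; must satisfy `n > 3 * perplexity`.
#' @param seed RNG seed.
#' @param maxIter iterations (default 500).
#' @return n x outDim coordinate matrix.
#' @export
tsne <- function(x, outDim = 2L, perplexity = 30, seed = 1L,
                 maxIter = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n - 1 < 3 * perplexity)
    stop("perplexity too large for the number of points")
  d2 <- as.matrix(dist(x))^2
  P <- calibrateAffinities(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  set.seed(seed)
  Y <- matrix(rnorm(n * outDim, sd = 1e-4), n, outDim)
  dY <- matrix(0, n, outDim)
  gains <- matrix(1, n, outDim)
  eta <- 200
  for (iter in seq_len(maxIter)) {
    exaggeration <- if (iter <= 100) 4 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (exaggeration * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
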