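# Independent brute-force oracles. These deliberately use naive scalar
# loops and textbook formulas, sharing no code with the package internals.

# scalar RBF via the closed form, one pair at a time
oracleRbf <- function(x, x2, sigma) {
  exp(-sum((x - x2)^2) / (2 * sigma^2))
}

# kernel matrix by double loop over rows
oracleKernelMatrix <- function(A, B, sigma) {
  K <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    K[i, j] <- oracleRbf(A[i, ], B[j, ], sigma)
  K
}

# projection by scalar loop
oracleProjection <- function(comp, probs, sigma, x) {
  s <- 0
  for (i in seq_len(nrow(comp)))
    s <- s + probs[i] * oracleRbf(x, comp[i, ], sigma)^2
  s
}

# posterior weights by naive double loop over the inference formula
oracleInfer <- function(xComp, xProbs, protoComp, protoProbs, sigma,
                        eps = 1e-10) {
  mPrime <- nrow(protoComp)
  pp <- numeric(mPrime)
  for (i in seq_len(mPrime)) {
    acc <- 0
    for (l in seq_len(nrow(xComp))) {
      den <- 0
      for (j in seq_len(mPrime))
        den <- den + protoProbs[j] * oracleRbf(xComp[l, ], protoComp[j, ],
                                               sigma)^2
      acc <- acc + xProbs[l] * protoProbs[i] *
        oracleRbf(xComp[l, ], protoComp[i, ], sigma)^2 / (den + eps)
    }
    pp[i] <- acc
  }
  pp
}

# squared-normalized-label class probability readout by scalar loop
oracleClassProbs <- function(values, probs) {
  probs <- probs / sum(probs)
  cC <- ncol(values)
  out <- numeric(cC)
  for (j in seq_len(nrow(values))) {
    yhat <- values[j, ] / sqrt(sum(values[j, ]^2))
    for (cc in seq_len(cC)) out[cc] <- out[cc] + probs[j] * yhat[cc]^2
  }
  out
}

# two-pass variance formula: sum p (y - E)^2
oracleMoments <- function(probs, values) {
  probs <- probs / sum(probs)
  e <- sum(probs * values)
  list(expected = e, variance = sum(probs * (values - e)^2))
}

# quadratic-weighted kappa from an explicit confusion-matrix double loop
oracleQwk <- function(yTrue, yPred, nClasses) {
  n <- length(yTrue)
  O <- matrix(0, nClasses, nClasses)
  for (k in seq_len(n)) O[yTrue[k] + 1, yPred[k] + 1] <-
      O[yTrue[k] + 1, yPred[k] + 1] + 1
  E <- outer(rowSums(O), colSums(O)) / n
  num <- 0; den <- 0
  for (i in seq_len(nClasses)) for (j in seq_len(nClasses)) {
    w <- (i - j)^2 / (nClasses - 1)^2
    num <- num + w * O[i, j]
    den <- den + w * E[i, j]
  }
  1 - num / den
}

# hand-unrolled local-global attention forward for given parameters
oracleAttention <- function(Z, W1, b1, W2, b2, w3, b3) {
  k <- nrow(Z)
  L <- matrix(0, k, length(b1))
  for (j in seq_len(k)) L[j, ] <- pmax(W1 %*% Z[j, ] + b1, 0)
  g <- colSums(L) / k
  scores <- numeric(k)
  for (j in seq_len(k)) {
    h <- pmax(W2 %*% c(L[j, ], g) + b2, 0)
    scores[j] <- sum(w3 * h) + b3
  }
  e <- exp(scores - max(scores))
  e / sum(e)
}

# random KDM pieces for property batteries
randomKdm <- function(m, d, sigma = NULL) {
  comp <- matrix(rnorm(m * d), m)
  probs <- runif(m) + 0.05
  if (is.null(sigma)) sigma <- runif(1, 0.5, 2)
  list(comp = comp, probs = probs / sum(probs), sigma = sigma,
       kdm = KernelDensityMatrix(comp, probs, KernelParams(sigma, d)))
}

randomJoint <- function(m, d, cC, sigma = NULL) {
  if (is.null(sigma)) sigma <- runif(1, 0.5, 2)
  xc <- matrix(rnorm(m * d), m)
  yc <- matrix(abs(rnorm(m * cC)) + 0.1, m)
  probs <- runif(m) + 0.05
  list(xc = xc, yc = yc, probs = probs / sum(probs), sigma = sigma,
       joint = JointKDM(xc, yc, probs, KernelParams(sigma, d)))
}
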