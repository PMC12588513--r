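# Local-global attention pooling over bags of patch embeddings. Per-patch
# weights become the mixture probabilities of the input KDM in the
# weakly supervised path.

#' Initialize local-global attention parameters
#'
#' Two MLPs with 64 hidden units and ReLU activations: MLP1 maps each patch
#' embedding to a local context vector; the global context is the mean of
#' the local contexts; MLP2 scores the concatenated (local, global) pair
#' (width 128 -> 64 -> 1), and a softmax over the bag turns the scores into
#' weights. Weights use fan-in-scaled (He) random initialization.
#'
#' @param d input embedding dimension.
#' @param hidden hidden width of both MLPs (64 by default).
#' @param seed integer seed for the random initialization.
#' @return list of parameter matrices/vectors
#'   (\code{W1, b1, W2, b2, w3, b3}) plus \code{d} and \code{hidden}.
#' @export
initAttention <- function(d, hidden = 64L, seed = 1L) {
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  he <- function(nout, nin) matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)),
                                   nrow = nout)
  list(type = "localGlobal", d = as.integer(d), hidden = as.integer(hidden),
       W1 = he(hidden, d), b1 = numeric(hidden),
       W2 = he(hidden, 2L * hidden), b2 = numeric(hidden),
       w3 = stats::rnorm(hidden, sd = sqrt(2 / hidden)), b3 = 0)
}

# Forward pass; returns intermediates needed for backprop.
.attentionForward <- function(Z, params) {
  k <- nrow(Z)
  Lpre <- Z %*% t(params$W1) + rep(params$b1, each = k)
  L <- pmax(Lpre, 0)
  g <- colMeans(L)
  LG <- cbind(L, matrix(g, nrow = k, ncol = length(g), byrow = TRUE))
  Hpre <- LG %*% t(params$W2) + rep(params$b2, each = k)
  H <- pmax(Hpre, 0)
  scores <- as.numeric(H %*% params$w3) + params$b3
  sm <- exp(scores - max(scores))
  a <- sm / sum(sm)
  list(a = a, scores = scores, H = H, Hpre = Hpre, LG = LG, L = L,
       Lpre = Lpre)
}

#' Attention weights for a bag of patch embeddings
#'
#' @param bagFeatures k x d matrix of patch embeddings (one row per patch).
#' @param params attention parameters from [initAttention()].
#' @return numeric(k) softmax weights summing to one.
#' @export
computeAttention <- function(bagFeatures, params) {
  if (is.null(dim(bagFeatures))) bagFeatures <- matrix(bagFeatures, nrow = 1L)
  bagFeatures <- as.matrix(bagFeatures)
  if (nrow(bagFeatures) < 1L) stop("bag must contain at least one patch")
  if (ncol(bagFeatures) != params$d)
    stop("embedding dimension does not match attention parameters")
  .attentionForward(bagFeatures, params)$a
}

# Backward pass: given dL/da (k) and the forward cache, returns gradients for
# all attention parameters and dL/dZ.
.attentionBackward <- function(Z, fwd, da, params) {
  k <- nrow(Z); a <- fwd$a
  dt <- a * (da - sum(a * da))            # softmax backward
  dw3 <- as.numeric(crossprod(fwd$H, dt))
  db3 <- sum(dt)
  dH <- outer(dt, params$w3)
  dH[fwd$Hpre <= 0] <- 0
  dW2 <- crossprod(dH, fwd$LG)
  db2 <- colSums(dH)
  dLG <- dH %*% params$W2
  hid <- params$hidden
  dL <- dLG[, seq_len(hid), drop = FALSE]
  dg <- colSums(dLG[, hid + seq_len(hid), drop = FALSE])
  dL <- dL + matrix(dg / k, nrow = k, ncol = hid, byrow = TRUE)
  dL[fwd$Lpre <= 0] <- 0
  dW1 <- crossprod(dL, Z)
  db1 <- colSums(dL)
  dZ <- dL %*% params$W1
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, w3 = dw3, b3 = db3,
       dZ = dZ)
}
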