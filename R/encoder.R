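# Encoders mapping patches to 128-dimensional embeddings.
#
# The desk-scale convolutional encoder uses three stride-2 convolution
# blocks (16/32/64 channels, ReLU) with *fixed* random (He-initialized)
# filters, global average pooling, and a trainable affine projection to the
# embedding dimension. Random convolutional features are a strong texture
# summary at this scale, and freezing them lets a whole dataset be featurized
# once so end-to-end training only backpropagates through the projection.
# The identity encoder passes pre-encoded vectors through untouched, so all
# KDM/attention machinery is testable without images.
#
# Images are H x W x 3 arrays in [0, 1]; internally they are flattened
# row-major with channel fastest (index ((h-1)W + (w-1))C + c).

.flattenImage <- function(img) {
  # plane-major (CHW) with column fastest within a row: index
  # (c-1)HW + (h-1)W + w
  as.numeric(aperm(img, c(2L, 1L, 3L)))
}

# Gather indices for a kernel x kernel, stride-s, valid convolution over an
# H x W x C input in plane-major layout. For each kernel offset (kh, kw)
# the index vector picks, channel-block by channel-block, the strided input
# positions feeding each output position; the gathered B x (P * C) slab
# reshapes for free (column-major) into a (B * P) x C matrix, so each layer
# is kernel^2 gathers plus kernel^2 small matrix products with no array
# transposition.
.im2colIndex <- function(H, W, C, kernel, stride) {
  outH <- (H - kernel) %/% stride + 1L
  outW <- (W - kernel) %/% stride + 1L
  P <- outH * outW
  hBase <- rep((seq_len(outH) - 1L) * stride, each = outW)
  wBase <- rep((seq_len(outW) - 1L) * stride, times = outH)
  offsets <- vector("list", kernel * kernel)
  oi <- 0L
  for (kh in seq_len(kernel)) for (kw in seq_len(kernel)) {
    oi <- oi + 1L
    posFlat <- (hBase + kh - 1L) * W + (wBase + kw)
    offsets[[oi]] <- as.integer(outer(posFlat, (seq_len(C) - 1L) * H * W,
                                      "+"))
  }
  list(offsets = offsets, outH = outH, outW = outW, C = C,
       K = kernel * kernel * C, P = P)
}

#' Desk-scale convolutional encoder
#'
#' Three stride-2 valid convolutions (3x3 kernels; 16, 32, 64 channels;
#' ReLU) with fixed He-initialized random filters, global average pooling to
#' a 64-dimensional texture summary, and a trainable affine projection to
#' \code{dOut} dimensions. Deterministic given its seed; the convolutional
#' part never changes after construction, only the projection is updated
#' during training.
#'
#' @param inputSize side length of the square input patches (>= 16).
#' @param channels integer(3) channel widths of the convolution blocks.
#' @param dOut embedding dimension (128 by default).
#' @param seed integer seed for filter and projection initialization.
#' @return encoder list with \code{type = "conv"}.
#' @seealso [identityEncoder()], [encodeFeatures()]
#' @export
convEncoder <- function(inputSize = 64L, channels = c(16L, 32L, 64L),
                        dOut = 128L, seed = 1L) {
  if (inputSize < 16L) stop("'inputSize' must be at least 16")
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  kernel <- 3L; stride <- 2L
  H <- as.integer(inputSize); W <- H; Cin <- 3L
  layers <- vector("list", length(channels))
  for (li in seq_along(channels)) {
    cfg <- .im2colIndex(H, W, Cin, kernel, stride)
    Cout <- as.integer(channels[li])
    cfg$Cout <- Cout
    cfg$W <- lapply(seq_along(cfg$offsets), function(o)
      matrix(stats::rnorm(Cin * Cout, sd = sqrt(2 / cfg$K)), nrow = Cin))
    layers[[li]] <- cfg
    H <- cfg$outH; W <- cfg$outW; Cin <- Cout
  }
  dFixed <- Cin
  list(type = "conv", inputSize = as.integer(inputSize), layers = layers,
       dFixed = dFixed, dOut = as.integer(dOut),
       We = matrix(stats::rnorm(dOut * dFixed, sd = sqrt(1 / dFixed)),
                   nrow = dOut),
       be = numeric(dOut))
}

#' Identity encoder for pre-encoded feature vectors
#'
#' @param d feature dimension.
#' @return encoder list with \code{type = "identity"} and no trainable
#'   parameters.
#' @export
identityEncoder <- function(d) {
  list(type = "identity", d = as.integer(d), dFixed = as.integer(d),
       dOut = as.integer(d))
}

# Fixed (non-trainable) part of the encoder applied to a batch.
# X: B x (inputSize^2 * 3) matrix of flattened images (conv) or B x d
# feature matrix (identity). Returns B x dFixed.
.encFixed <- function(encoder, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (encoder$type == "identity") return(as.matrix(X))
  B <- nrow(X)
  for (cfg in encoder$layers) {
    Y <- matrix(0, B * cfg$P, cfg$Cout)
    for (o in seq_along(cfg$offsets)) {
      slab <- X[, cfg$offsets[[o]], drop = FALSE]
      dim(slab) <- c(B * cfg$P, cfg$C)
      Y <- Y + slab %*% cfg$W[[o]]
    }
    Y <- pmax(Y, 0)
    dim(Y) <- c(B, cfg$P * cfg$Cout)   # plane-major layout for next layer
    X <- Y
  }
  lastP <- encoder$layers[[length(encoder$layers)]]$P
  G <- matrix(0, B, encoder$dFixed)
  for (c in seq_len(encoder$dFixed))
    G[, c] <- rowMeans(matrix(X[, (c - 1L) * lastP + seq_len(lastP)],
                              nrow = B))
  G
}

# Trainable projection: fixed features -> embeddings.
.encProject <- function(encoder, F) {
  if (encoder$type == "identity") return(F)
  F %*% t(encoder$We) + rep(encoder$be, each = nrow(F))
}

# Normalize heterogeneous patch input into a flattened batch matrix.
.asBatchMatrix <- function(encoder, x) {
  if (is.list(x)) {
    do.call(rbind, lapply(x, .flattenImage))
  } else if (is.array(x) && length(dim(x)) == 3L) {
    matrix(.flattenImage(x), nrow = 1L)
  } else if (is.null(dim(x))) {
    matrix(x, nrow = 1L)
  } else as.matrix(x)
}

#' Encode patches into embedding vectors
#'
#' Runs the full encoder (fixed convolutional features, then the trainable
#' projection; or the identity on vector input).
#'
#' @param encoder an encoder from [convEncoder()] or [identityEncoder()].
#' @param x a single image (H x W x 3 array), a list of images, or a matrix
#'   of pre-encoded row vectors.
#' @return numeric matrix, one embedding row per input.
#' @export
encodeFeatures <- function(encoder, x) {
  X <- .asBatchMatrix(encoder, x)
  .encProject(encoder, .encFixed(encoder, X))
}
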