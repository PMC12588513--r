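# Model assembly: training configuration, joint-KDM prototype
# initialization, the two prediction paths (patch and bag), losses, and the
# parameter / kernel-evaluation accounting.

#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 1e-4 (beta1 = 0.9, beta2 = 0.999), a gradual warm-up with factor 10 over
#' the first epoch followed by cosine annealing, mini-batches of 4 bags,
#' at most 50 epochs with early stopping after 5 epochs without validation
#' improvement, a 2-epoch encoder warm-up, and a joint KDM of
#' \code{perClass * nClasses} components (36 x 6 = 216 by default).
#'
#' @param task "classification" or "ordinal".
#' @param nClasses number of label classes (6 grade groups by default).
#' @param perClass prototypes initialized per class (36 by default).
#' @param alpha nonnegative variance-penalty weight in the ordinal loss.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param warmupEpochs epochs of linear learning-rate ramp from lr/10 to lr.
#' @param batchBags bags per mini-batch in weak training.
#' @param batchPatches patches per mini-batch in supervised training.
#' @param maxEpochs maximum training epochs.
#' @param patience early-stopping patience (epochs without val improvement).
#' @param encoderWarmupEpochs epochs of encoder warm-up with a throwaway
#'   linear classification head before KDM initialization.
#' @param seed integer seed governing every stochastic step of training.
#' @return validated configuration list with derived \code{mPrototypes}.
#' @export
trainingConfig <- function(task = c("classification", "ordinal"),
                           nClasses = 6L, perClass = 36L, alpha = 0.1,
                           lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                           warmupEpochs = 1L, batchBags = 4L,
                           batchPatches = 64L, maxEpochs = 50L,
                           patience = 5L, encoderWarmupEpochs = 2L,
                           seed = 1L) {
  task <- match.arg(task)
  if (alpha < 0) stop("'alpha' must be nonnegative")
  if (lr <= 0) stop("'lr' must be positive")
  cfg <- list(task = task, nClasses = as.integer(nClasses),
              perClass = as.integer(perClass),
              mPrototypes = as.integer(perClass) * as.integer(nClasses),
              alpha = alpha, lr = lr, beta1 = beta1, beta2 = beta2,
              warmupEpochs = as.integer(warmupEpochs),
              batchBags = as.integer(batchBags),
              batchPatches = as.integer(batchPatches),
              maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience),
              encoderWarmupEpochs = as.integer(encoderWarmupEpochs),
              seed = as.integer(seed))
  cfg
}

#' Initialize the joint KDM by stratified prototype sampling
#'
#' Randomly selects \code{perClass} examples from each class (stratified
#' sampling), encodes them, and uses the embeddings as the initial prototype
#' positions. Label encodings are one-hot rows for classification or
#' normalized ordinal scalars for regression; mixture weights start uniform
#' at 1/m. The kernel bandwidth is initialized to the mean pairwise
#' Euclidean distance among the prototypes divided by sqrt(2), a
#' scale-adaptive start that avoids saturated kernels. The returned registry
#' records which source example seeded each component, enabling prototype
#' retrieval later.
#'
#' @param features n x dFixed matrix of fixed encoder features (or raw
#'   vectors for the identity encoder).
#' @param labels integer vector of 0-based class labels, length n.
#' @param config a [trainingConfig()].
#' @param encoder encoder whose projection maps features to embeddings.
#' @param ids optional character vector of example identifiers.
#' @return list with \code{joint} (a \linkS4class{JointKDM}) and
#'   \code{registry} (data.frame component/id/label).
#' @export
initJointKdm <- function(features, labels, config, encoder,
                         ids = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (is.null(ids)) ids <- sprintf("ex_%06d", seq_len(nrow(features)))
  rng <- .localRNG(childSeed(config$seed, 7L))
  on.exit(rng$restore())
  classes <- seq_len(config$nClasses) - 1L
  sel <- integer(0)
  for (cl in classes) {
    pool <- which(labels == cl)
    if (length(pool) < config$perClass)
      stop(sprintf("class %d has %d example(s); %d required", cl,
                   length(pool), config$perClass))
    sel <- c(sel, pool[sample.int(length(pool), config$perClass)])
  }
  X <- .encProject(encoder, features[sel, , drop = FALSE])
  m <- nrow(X)
  Y <- if (config$task == "classification") {
    Yc <- matrix(0, m, config$nClasses)
    Yc[cbind(seq_len(m), labels[sel] + 1L)] <- 1
    Yc
  } else matrix(toOrdinal(labels[sel], config$nClasses), ncol = 1L)
  pd <- .sqDist(X, X)
  sigma <- mean(sqrt(pd[upper.tri(pd)])) / sqrt(2)
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  joint <- JointKDM(X, Y, rep(1 / m, m), KernelParams(sigma, ncol(X)))
  registry <- data.frame(component = seq_len(m), id = ids[sel],
                         label = labels[sel], sourceIndex = sel,
                         stringsAsFactors = FALSE)
  list(joint = joint, registry = registry)
}

#' Predict a single patch
#'
#' Encodes the patch, wraps the embedding as a one-component KDM with unit
#' weight, and runs [infer()] against the model's joint KDM (the fully
#' supervised path; attention is bypassed since a single patch has weight 1).
#'
#' @param model a \linkS4class{KdmModel} (or a list with \code{encoder} and
#'   \code{joint} for untrained use).
#' @param x an image array or a pre-encoded feature vector.
#' @return A \linkS4class{LabelDistribution}.
#' @export
predictPatch <- function(model, x) {
  enc <- if (is(model, "KdmModel")) model@encoder else model$encoder
  joint <- if (is(model, "KdmModel")) model@joint else model$joint
  z <- encodeFeatures(enc, x)
  rhoX <- KernelDensityMatrix(z, 1, joint@kernel)
  infer(rhoX, joint)
}

#' Predict a bag (slide) of patches
#'
#' Encodes every patch, computes local-global attention weights, builds the
#' input KDM with the attention weights as mixture probabilities, and runs
#' [infer()]. With identical patches the attention weights are uniform and
#' the result equals [predictPatch()] on any one of them.
#'
#' @param model a \linkS4class{KdmModel} with attention parameters.
#' @param bag list with \code{features} (k x dFixed fixed-feature matrix) or
#'   \code{patches} (list of image arrays); alternatively a bare matrix or
#'   list of images.
#' @return A \linkS4class{LabelDistribution}.
#' @export
predictSlide <- function(model, bag) {
  enc <- if (is(model, "KdmModel")) model@encoder else model$encoder
  joint <- if (is(model, "KdmModel")) model@joint else model$joint
  attn <- if (is(model, "KdmModel")) model@attention else model$attention
  f <- .bagFixedFeatures(enc, bag)
  if (nrow(f) < 1L) stop("bag must contain at least one patch")
  Z <- .encProject(enc, f)
  a <- if (length(attn)) computeAttention(Z, attn) else
    rep(1 / nrow(Z), nrow(Z))
  rhoX <- KernelDensityMatrix(Z, a, joint@kernel)
  infer(rhoX, joint)
}

# Accepts the several bag representations and returns fixed features.
.bagFixedFeatures <- function(encoder, bag) {
  if (is.list(bag) && !is.null(bag$features)) return(as.matrix(bag$features))
  if (is.list(bag) && !is.null(bag$patches))
    return(.encFixed(encoder, .asBatchMatrix(encoder, bag$patches)))
  .encFixed(encoder, .asBatchMatrix(encoder, bag))
}

#' Categorical cross-entropy loss
#'
#' \eqn{-\sum_c y_c \log(\hat p_c)} with a 1e-12 probability floor inside
#' the logarithm.
#'
#' @param probs predicted class probabilities (vector) or matrix with one
#'   row per sample.
#' @param yTrue 0-based true class index vector.
#' @return nonnegative mean loss.
#' @export
classificationLoss <- function(probs, yTrue) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  -mean(log(probs[cbind(seq_len(nrow(probs)), as.integer(yTrue) + 1L)] +
            1e-12))
}

#' Ordinal loss: squared error plus variance penalty
#'
#' Mean over the batch of \eqn{(E[\hat y] - y)^2 + \alpha Var[\hat y]}.
#'
#' @param expected,variance numeric vectors of posterior moments.
#' @param yTrueOrdinal true labels on the [0, 1] ordinal scale.
#' @param alpha nonnegative variance penalty.
#' @return nonnegative mean loss.
#' @export
ordinalLoss <- function(expected, variance, yTrueOrdinal, alpha) {
  if (alpha < 0) stop("'alpha' must be nonnegative")
  mean((expected - yTrueOrdinal)^2 + alpha * variance)
}

#' KDM parameter count
#'
#' Prototype positions (m x d), label encodings (m x c) and one mixture
#' weight per component: \eqn{m(d + c + 1)}. With m = 216, d = 128, c = 6
#' this gives 29,160.
#'
#' @param m number of components.
#' @param d feature dimension.
#' @param c label dimension.
#' @return integer parameter count.
#' @export
countKdmParameters <- function(m, d, c) {
  as.integer(m) * (as.integer(d) + as.integer(c) + 1L)
}

#' Kernel evaluations per inference
#'
#' Inference scales as O(n x m): every input patch is compared against every
#' prototype once.
#'
#' @param nPatches number of input patches.
#' @param m number of prototypes.
#' @return integer count.
#' @export
countKernelEvaluations <- function(nPatches, m) {
  as.integer(nPatches) * as.integer(m)
}
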