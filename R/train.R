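# End-to-end gradient training. The forward pass composes the encoder
# projection, (optionally) local-global attention, and KDM inference; the
# backward pass is derived analytically for every trainable tensor:
# projection (We, be), attention MLPs (W1, b1, W2, b2, w3, b3), prototype
# positions (Xp), label encodings (Y), mixture-weight logits (u, with
# probs = softmax(u) keeping the simplex exact), and log-bandwidth (s).
# The gradients are verified against finite differences in the test suite.

# ---- parameter plumbing -----------------------------------------------------

.trainableParams <- function(encoder, attention, joint) {
  params <- list()
  if (encoder$type == "conv") {
    params$We <- encoder$We
    params$be <- encoder$be
  }
  if (length(attention)) {
    params$W1 <- attention$W1; params$b1 <- attention$b1
    params$W2 <- attention$W2; params$b2 <- attention$b2
    params$w3 <- attention$w3; params$b3 <- attention$b3
    params$hidden <- attention$hidden   # geometry, not trained
  }
  params$Xp <- joint@xComponents
  params$Y <- joint@yComponents
  params$u <- log(joint@probs + 1e-12)
  params$s <- joint@kernel@logBandwidth
  params
}

.softmaxVec <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

# ---- shared forward core ----------------------------------------------------

# Given embeddings Z (rows) and KDM params, returns kernel responsibilities.
.kdmForward <- function(Z, params) {
  pprime <- .softmaxVec(params$u)
  s2 <- exp(2 * params$s)
  D <- .sqDist(Z, params$Xp)
  G <- exp(-D / s2)
  W <- sweep(G, 2L, pprime, "*")
  Srow <- rowSums(W) + .KDMIL_EPS
  R <- W / Srow
  list(pprime = pprime, s2 = s2, D = D, G = G, Srow = Srow, R = R)
}

# ---- per-bag gradient (weak path) ------------------------------------------

# f: k x dFixed fixed features of one bag; yTrue: class index (0-based).
# Returns loss, prediction summary and gradients for all names in `params`.
.bagGrad <- function(f, yTrue, params, hyper, wantGrad = TRUE) {
  conv <- !is.null(params$We)
  Z <- if (conv) f %*% t(params$We) + rep(params$be, each = nrow(f)) else f
  useAttn <- !is.null(params$W1)
  if (useAttn) {
    afwd <- .attentionForward(Z, params)
    a <- afwd$a
  } else a <- rep(1 / nrow(Z), nrow(Z))
  kf <- .kdmForward(Z, params)
  ppRaw <- as.numeric(crossprod(kf$R, a))
  Tn <- sum(ppRaw)
  pp <- ppRaw / Tn

  Y <- params$Y
  if (hyper$task == "classification") {
    n2 <- rowSums(Y^2)
    Q <- Y^2 / n2
    q <- as.numeric(crossprod(Q, pp))
    loss <- -log(q[yTrue + 1L] + 1e-12)
    pred <- list(classProbs = q)
  } else {
    v <- Y[, 1L]
    E <- sum(pp * v); M2 <- sum(pp * v^2)
    Var <- M2 - E^2
    yOrd <- toOrdinal(yTrue, hyper$nClasses)
    loss <- (E - yOrd)^2 + hyper$alpha * Var
    pred <- list(expected = E, variance = max(Var, 0))
  }
  if (!wantGrad) return(list(loss = loss, pred = pred))

  if (hyper$task == "classification") {
    dq <- numeric(length(q)); dq[yTrue + 1L] <- -1 / (q[yTrue + 1L] + 1e-12)
    gpp <- as.numeric(Q %*% dq)
    dY <- (2 * Y / n2) * (pp * (rep(dq, each = nrow(Y)) -
                                as.numeric(Q %*% dq)))
  } else {
    dE <- 2 * (E - yOrd) - 2 * hyper$alpha * E
    gpp <- dE * v + hyper$alpha * v^2
    dY <- matrix(pp * (2 * (E - yOrd) + 2 * hyper$alpha * (v - E)),
                 ncol = 1L)
  }

  gRaw <- (gpp - sum(pp * gpp)) / Tn
  rv <- as.numeric(kf$R %*% gRaw)          # dL/da before softmax, and r_l
  B <- outer(a / kf$Srow, gRaw) - (a * rv / kf$Srow)
  dpprime <- colSums(B * kf$G)
  dG <- sweep(B, 2L, kf$pprime, "*")
  dD <- -dG * kf$G / kf$s2
  ds <- 2 * sum(dG * kf$G * kf$D) / kf$s2
  dZ <- 2 * (rowSums(dD) * Z - dD %*% params$Xp)
  dXp <- 2 * (colSums(dD) * params$Xp - crossprod(dD, Z))
  du <- kf$pprime * (dpprime - sum(kf$pprime * dpprime))

  grads <- list(Xp = dXp, Y = dY, u = du, s = ds)
  if (useAttn) {
    ab <- .attentionBackward(Z, afwd, rv, params)
    grads$W1 <- ab$W1; grads$b1 <- ab$b1
    grads$W2 <- ab$W2; grads$b2 <- ab$b2
    grads$w3 <- ab$w3; grads$b3 <- ab$b3
    dZ <- dZ + ab$dZ
  }
  if (conv) {
    grads$We <- crossprod(dZ, f)
    grads$be <- colSums(dZ)
  }
  list(loss = loss, pred = pred, grads = grads)
}

# ---- vectorized patch-batch gradient (supervised path) ---------------------

# F: B x dFixed; yTrue: integer vector of 0-based labels. Each patch is its
# own one-component bag with unit weight; no attention.
.patchBatchGrad <- function(F, yTrue, params, hyper, wantGrad = TRUE) {
  conv <- !is.null(params$We)
  Z <- if (conv) F %*% t(params$We) + rep(params$be, each = nrow(F)) else F
  B <- nrow(Z)
  kf <- .kdmForward(Z, params)
  Tn <- rowSums(kf$R)
  P <- kf$R / Tn                              # B x m normalized posteriors

  Y <- params$Y
  if (hyper$task == "classification") {
    n2 <- rowSums(Y^2)
    Q <- Y^2 / n2
    q <- P %*% Q                              # B x c
    pick <- cbind(seq_len(B), yTrue + 1L)
    loss <- -mean(log(q[pick] + 1e-12))
    pred <- list(classProbs = q)
  } else {
    v <- Y[, 1L]
    E <- as.numeric(P %*% v)
    M2 <- as.numeric(P %*% v^2)
    Var <- M2 - E^2
    yOrd <- toOrdinal(yTrue, hyper$nClasses)
    loss <- mean((E - yOrd)^2 + hyper$alpha * Var)
    pred <- list(expected = E, variance = pmax(Var, 0))
  }
  if (!wantGrad) return(list(loss = loss, pred = pred))

  if (hyper$task == "classification") {
    dq <- matrix(0, B, ncol(Q))
    dq[pick] <- -1 / ((q[pick] + 1e-12) * B)
    gpp <- dq %*% t(Q)                        # B x m
    dY <- (2 * Y / n2) * (crossprod(P, dq) -
                          matrix(colSums(P * gpp), nrow(Y),
                                 ncol(Y)))
  } else {
    dE <- (2 * (E - yOrd) - 2 * hyper$alpha * E) / B
    dM2 <- rep(hyper$alpha / B, B)
    gpp <- outer(dE, v) + outer(dM2, v^2)
    dY <- matrix(as.numeric(crossprod(P, dE)) +
                 2 * v * as.numeric(crossprod(P, dM2)), ncol = 1L)
  }

  gRaw <- (gpp - rowSums(P * gpp)) / Tn
  rv <- rowSums(kf$R * gRaw)
  Bm <- (gRaw - rv) / kf$Srow
  dpprime <- colSums(Bm * kf$G)
  dG <- sweep(Bm, 2L, kf$pprime, "*")
  dD <- -dG * kf$G / kf$s2
  ds <- 2 * sum(dG * kf$G * kf$D) / kf$s2
  dZ <- 2 * (rowSums(dD) * Z - dD %*% params$Xp)
  dXp <- 2 * (colSums(dD) * params$Xp - crossprod(dD, Z))
  du <- kf$pprime * (dpprime - sum(kf$pprime * dpprime))

  grads <- list(Xp = dXp, Y = dY, u = du, s = ds)
  if (conv) {
    grads$We <- crossprod(dZ, F)
    grads$be <- colSums(dZ)
  }
  list(loss = loss, pred = pred, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# Learning rate at a given (epoch, step): linear ramp from lr/10 to lr over
# the warm-up epoch(s), then cosine annealing to 0 at maxEpochs.
.lrAt <- function(config, epoch, step, stepsPerEpoch) {
  lr <- config$lr; w <- config$warmupEpochs
  if (epoch <= w) {
    frac <- ((epoch - 1) * stepsPerEpoch + step) / (w * stepsPerEpoch)
    return(lr / 10 + frac * (lr - lr / 10))
  }
  rest <- max(config$maxEpochs - w, 1L)
  lr * 0.5 * (1 + cos(pi * (epoch - w - 1) / rest))
}

# ---- encoder warm-up -------------------------------------------------------

# Trains the encoder projection plus a throwaway linear softmax head on
# (fixed features, labels) for config$encoderWarmupEpochs; the head is
# discarded, the projection is kept.
.encoderWarmup <- function(encoder, F, labels, config) {
  if (encoder$type != "conv" || config$encoderWarmupEpochs < 1L)
    return(encoder)
  rng <- .localRNG(childSeed(config$seed, 11L))
  on.exit(rng$restore())
  nC <- config$nClasses
  params <- list(We = encoder$We, be = encoder$be,
                 Wh = matrix(stats::rnorm(nC * encoder$dOut, sd = 0.01),
                             nrow = nC),
                 bh = numeric(nC))
  state <- .adamInit(params)
  n <- nrow(F)
  for (ep in seq_len(config$encoderWarmupEpochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batchPatches)
    for (st in starts) {
      ix <- ord[st:min(st + config$batchPatches - 1L, n)]
      Fb <- F[ix, , drop = FALSE]; yb <- labels[ix]
      Z <- Fb %*% t(params$We) + rep(params$be, each = length(ix))
      logits <- Z %*% t(params$Wh) + rep(params$bh, each = length(ix))
      sm <- exp(logits - apply(logits, 1L, max))
      p <- sm / rowSums(sm)
      Bn <- length(ix)
      dlogits <- p
      dlogits[cbind(seq_len(Bn), yb + 1L)] <-
        dlogits[cbind(seq_len(Bn), yb + 1L)] - 1
      dlogits <- dlogits / Bn
      grads <- list(Wh = crossprod(dlogits, Z), bh = colSums(dlogits))
      dZ <- dlogits %*% params$Wh
      grads$We <- crossprod(dZ, Fb); grads$be <- colSums(dZ)
      upd <- .adamStep(params, grads, state, config$lr, config$beta1,
                       config$beta2)
      params <- upd$params; state <- upd$state
    }
  }
  encoder$We <- params$We; encoder$be <- params$be
  encoder
}

# ---- shared training loop --------------------------------------------------

# stepFun(params, batchIndex) -> list(loss, grads); evalFun(params) ->
# list(loss = ..., metrics = named numeric). Runs the Adam + schedule +
# early-stopping loop and returns the best parameters and the log.
.trainLoop <- function(params, config, nItems, batchSize, stepFun, evalFun) {
  state <- .adamInit(params)
  rng <- .localRNG(childSeed(config$seed, 23L))
  on.exit(rng$restore())
  bestLoss <- Inf; bestParams <- params; bestEpoch <- 0L; wait <- 0L
  log <- list()
  stepsPerEpoch <- max(1L, ceiling(nItems / batchSize))
  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(nItems)
    starts <- seq(1L, nItems, by = batchSize)
    epochLoss <- 0
    for (bi in seq_along(starts)) {
      ix <- ord[starts[bi]:min(starts[bi] + batchSize - 1L, nItems)]
      res <- stepFun(params, ix)
      lr <- .lrAt(config, epoch, bi, stepsPerEpoch)
      upd <- .adamStep(params, res$grads, state, lr, config$beta1,
                       config$beta2)
      params <- upd$params; state <- upd$state
      epochLoss <- epochLoss + res$loss * length(ix)
    }
    epochLoss <- epochLoss / nItems
    ev <- evalFun(params)
    row <- data.frame(epoch = epoch, trainLoss = epochLoss,
                      valLoss = ev$loss)
    if (length(ev$metrics)) row <- cbind(row, as.list(ev$metrics))
    log[[length(log) + 1L]] <- row
    monitored <- if (is.finite(ev$loss)) ev$loss else epochLoss
    if (monitored < bestLoss - 1e-12) {
      bestLoss <- monitored; bestParams <- params
      bestEpoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = bestParams, log = do.call(rbind, log),
       bestEpoch = bestEpoch)
}

.rebuildModel <- function(encoder, attention, params, config, registry,
                          log) {
  if (!is.null(params$We)) {
    encoder$We <- params$We; encoder$be <- params$be
  }
  if (length(attention)) {
    attention$W1 <- params$W1; attention$b1 <- params$b1
    attention$W2 <- params$W2; attention$b2 <- params$b2
    attention$w3 <- params$w3; attention$b3 <- params$b3
  }
  joint <- JointKDM(params$Xp, params$Y, .softmaxVec(params$u),
                    KernelParams(exp(params$s), ncol(params$Xp)))
  new("KdmModel", encoder = encoder, attention = attention, joint = joint,
      config = config, registry = registry, task = config$task,
      trainingLog = if (is.null(log)) data.frame() else log)
}

# ---- fully supervised training --------------------------------------------

#' Train a fully supervised patch model
#'
#' Encoder warm-up (a throwaway linear head trains the projection for
#' \code{encoderWarmupEpochs}), stratified joint-KDM initialization, then
#' end-to-end Adam training of the projection and all KDM parameters with
#' warm-up + cosine learning-rate schedule and early stopping on validation
#' loss (best parameters restored).
#'
#' @param data list with \code{labels} (0-based integers) and either
#'   \code{features} (n x d matrix; identity encoder) or \code{images}
#'   (list of arrays; convolutional encoder), optionally \code{ids}.
#' @param config a [trainingConfig()].
#' @param encoder optional encoder; defaults to [identityEncoder()] for
#'   feature input or [convEncoder()] for image input.
#' @param valData optional validation list of the same shape; without it the
#'   training loss is monitored.
#' @return a trained \linkS4class{KdmModel}.
#' @export
trainSupervised <- function(data, config, encoder = NULL, valData = NULL) {
  prep <- .prepPatchData(data, encoder)
  encoder <- prep$encoder
  F <- prep$F; labels <- prep$labels
  if (length(labels) < config$nClasses)
    stop("training data is degenerate: fewer examples than classes")
  encoder <- .encoderWarmup(encoder, F, labels, config)
  ini <- initJointKdm(F, labels, config, encoder, ids = prep$ids)
  params <- .trainableParams(encoder, list(), ini$joint)
  hyper <- list(task = config$task, alpha = config$alpha,
                nClasses = config$nClasses)
  valPrep <- if (!is.null(valData)) .prepPatchData(valData, encoder) else NULL

  stepFun <- function(p, ix)
    .patchBatchGrad(F[ix, , drop = FALSE], labels[ix], p, hyper)
  evalFun <- function(p) {
    if (is.null(valPrep)) return(list(loss = NA_real_, metrics = c()))
    fw <- .patchBatchGrad(valPrep$F, valPrep$labels, p, hyper,
                          wantGrad = FALSE)
    yhat <- .predToClass(fw$pred, hyper)
    list(loss = fw$loss,
         metrics = c(valAccuracy = mean(yhat == valPrep$labels)))
  }
  fit <- .trainLoop(params, config, nrow(F), config$batchPatches, stepFun,
                    evalFun)
  .rebuildModel(encoder, list(), fit$params, config, ini$registry, fit$log)
}

.prepPatchData <- function(data, encoder) {
  if (!is.null(data$features)) {
    F0 <- as.matrix(data$features)
    if (is.null(encoder)) encoder <- identityEncoder(ncol(F0))
    F <- if (encoder$type == "conv") F0 else F0
  } else if (!is.null(data$images)) {
    if (is.null(encoder)) {
      sz <- dim(data$images[[1L]])[1L]
      encoder <- convEncoder(inputSize = sz)
    }
    F <- .encFixedBatched(encoder, data$images)
  } else stop("'data' must contain $features or $images")
  ids <- if (!is.null(data$ids)) data$ids else
    sprintf("ex_%06d", seq_along(data$labels))
  list(encoder = encoder, F = F, labels = as.integer(data$labels), ids = ids)
}

# featurize images through the fixed conv stack in moderate batches
.encFixedBatched <- function(encoder, images, batch = 64L) {
  n <- length(images)
  out <- matrix(0, n, encoder$dFixed)
  for (st in seq(1L, n, by = batch)) {
    ix <- st:min(st + batch - 1L, n)
    out[ix, ] <- .encFixed(encoder, .asBatchMatrix(encoder, images[ix]))
  }
  out
}

.predToClass <- function(pred, hyper) {
  if (hyper$task == "classification") {
    max.col(pred$classProbs, ties.method = "first") - 1L
  } else ordinalToClass(pred$expected, hyper$nClasses)
}

# ---- weakly supervised training -------------------------------------------

#' Train a weakly supervised bag (slide) model
#'
#' Same procedure as [trainSupervised()] but with the bag forward path:
#' patches are encoded, local-global attention weights become the input
#' KDM's mixture probabilities, and the loss is computed from the bag-level
#' posterior against the weak (slide-level) label. Encoder warm-up uses the
#' bag label broadcast to its patches; prototype initialization samples
#' patches stratified by bag label. Mini-batches contain
#' \code{config$batchBags} bags.
#'
#' @param bags list of bags; each bag is a list with \code{label}
#'   (0-based grade group), \code{id}, and \code{features} (k x d matrix)
#'   or \code{patches} (list of image arrays).
#' @param config a [trainingConfig()].
#' @param encoder optional encoder (defaults as in [trainSupervised()]).
#' @param valBags optional validation bags for early stopping.
#' @return a trained \linkS4class{KdmModel} with attention parameters.
#' @export
trainWeak <- function(bags, config, encoder = NULL, valBags = NULL) {
  prep <- .prepBags(bags, encoder)
  encoder <- prep$encoder
  feats <- prep$features; labels <- prep$labels
  if (length(feats) < 1L) stop("'bags' must be a nonempty list")

  pooled <- do.call(rbind, feats)
  pooledLabels <- rep(labels, vapply(feats, nrow, integer(1)))
  encoder <- .encoderWarmup(encoder, pooled, pooledLabels, config)
  pooledIds <- unlist(lapply(seq_along(feats), function(i)
    sprintf("%s_p%02d", prep$ids[i], seq_len(nrow(feats[[i]])))))
  ini <- initJointKdm(pooled, pooledLabels, config, encoder, ids = pooledIds)
  attention <- initAttention(encoder$dOut, seed = childSeed(config$seed, 3L))
  params <- .trainableParams(encoder, attention, ini$joint)
  hyper <- list(task = config$task, alpha = config$alpha,
                nClasses = config$nClasses)
  valPrep <- if (!is.null(valBags)) .prepBags(valBags, encoder) else NULL

  stepFun <- function(p, ix) {
    acc <- NULL; loss <- 0
    for (i in ix) {
      res <- .bagGrad(feats[[i]], labels[i], p, hyper)
      loss <- loss + res$loss
      acc <- if (is.null(acc)) res$grads else
        Map(`+`, acc, res$grads)
    }
    list(loss = loss / length(ix),
         grads = lapply(acc, function(g) g / length(ix)))
  }
  evalFun <- function(p) {
    if (is.null(valPrep)) return(list(loss = NA_real_, metrics = c()))
    ev <- .evalBags(valPrep, p, hyper)
    list(loss = ev$loss, metrics = c(valKappa = ev$kappa))
  }
  fit <- .trainLoop(params, config, length(feats), config$batchBags,
                    stepFun, evalFun)
  .rebuildModel(encoder, attention, fit$params, config, ini$registry,
                fit$log)
}

.prepBags <- function(bags, encoder) {
  if (is.null(encoder)) {
    b1 <- bags[[1L]]
    if (!is.null(b1$features)) {
      encoder <- identityEncoder(ncol(as.matrix(b1$features)))
    } else {
      sz <- dim(b1$patches[[1L]])[1L]
      encoder <- convEncoder(inputSize = sz)
    }
  }
  feats <- lapply(bags, function(b) {
    if (!is.null(b$features)) as.matrix(b$features)
    else .encFixed(encoder, .asBatchMatrix(encoder, b$patches))
  })
  labels <- vapply(bags, function(b) as.integer(b$label), integer(1))
  ids <- vapply(seq_along(bags), function(i)
    if (!is.null(bags[[i]]$id)) bags[[i]]$id else sprintf("bag_%04d", i),
    character(1))
  list(encoder = encoder, features = feats, labels = labels, ids = ids)
}

.evalBags <- function(prep, params, hyper) {
  n <- length(prep$features)
  loss <- 0; yhat <- integer(n)
  for (i in seq_len(n)) {
    fw <- .bagGrad(prep$features[[i]], prep$labels[i], params, hyper,
                   wantGrad = FALSE)
    loss <- loss + fw$loss
    yhat[i] <- if (hyper$task == "classification")
      which.max(fw$pred$classProbs) - 1L
    else ordinalToClass(fw$pred$expected, hyper$nClasses)
  }
  kappa <- tryCatch(
    quadraticWeightedKappa(prep$labels, yhat, hyper$nClasses),
    error = function(e) NA_real_)
  list(loss = loss / n, kappa = kappa, yhat = yhat)
}

#' Convert synthetic slides to training bags
#'
#' Renders each slide's patches and featurizes them through the encoder's
#' fixed convolutional stack once, so training touches images only here.
#'
#' @param slides list of \code{SyntheticSlide} objects.
#' @param encoder a [convEncoder()] matching the slide patch size.
#' @return list of bags (\code{features}, \code{label}, \code{id}, plus the
#'   slide's ground-truth \code{patterns} and \code{proportions}).
#' @export
bagsFromSlides <- function(slides, encoder) {
  lapply(slides, function(sl) {
    imgs <- renderSlidePatches(sl)
    list(features = .encFixed(encoder, .asBatchMatrix(encoder, imgs)),
         label = sl$isupGroup, id = sl$id, patterns = sl$patterns,
         proportions = sl$proportions)
  })
}

#' Predict a set of bags into a prediction table
#'
#' @param model a trained \linkS4class{KdmModel}.
#' @param bags list of bags as in [trainWeak()].
#' @return data.frame with id, trueLabel, classIndex, expected, variance.
#' @export
predictBags <- function(model, bags) {
  rows <- lapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    dist <- predictSlide(model, b)
    if (model@task == "ordinal") {
      mom <- posteriorMoments(dist)
      data.frame(id = if (!is.null(b$id)) b$id else sprintf("bag_%04d", i),
                 trueLabel = if (!is.null(b$label)) as.integer(b$label)
                             else NA_integer_,
                 classIndex = ordinalToClass(mom$expected,
                                             model@config$nClasses),
                 expected = mom$expected, variance = mom$variance,
                 stringsAsFactors = FALSE)
    } else {
      q <- classProbabilities(dist)
      mom <- posteriorMoments(q, toOrdinal(seq_along(q) - 1L, length(q)))
      data.frame(id = if (!is.null(b$id)) b$id else sprintf("bag_%04d", i),
                 trueLabel = if (!is.null(b$label)) as.integer(b$label)
                             else NA_integer_,
                 classIndex = which.max(q) - 1L,
                 expected = mom$expected, variance = mom$variance,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
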