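test_that("full-model gradients match finite differences (both tasks)", {
  ns <- asNamespace("kdmil")
  set.seed(42)
  k <- 4; dfix <- 3; dOut <- 4; m <- 5; cC <- 3
  f <- matrix(rnorm(k * dfix), k)
  base <- list(
    We = matrix(rnorm(dOut * dfix, sd = 0.5), dOut),
    be = rnorm(dOut, sd = 0.1),
    W1 = matrix(rnorm(4 * dOut, sd = 0.5), 4), b1 = rnorm(4, sd = 0.1),
    W2 = matrix(rnorm(4 * 8, sd = 0.5), 4), b2 = rnorm(4, sd = 0.1),
    w3 = rnorm(4, sd = 0.5), b3 = 0.2, hidden = 4L,
    Xp = matrix(rnorm(m * dOut), m),
    u = rnorm(m, sd = 0.5), s = 0.1)
  for (task in c("classification", "ordinal")) {
    params <- base
    params$Y <- if (task == "classification")
      abs(matrix(rnorm(m * cC), m)) + 0.2 else matrix(runif(m), ncol = 1)
    hyper <- list(task = task, alpha = 0.1, nClasses = cC)
    res <- ns$.bagGrad(f, 1L, params, hyper)
    eps <- 1e-6
    for (nm in setdiff(names(res$grads), "hidden")) {
      num <- res$grads[[nm]] * 0
      for (i in seq_along(params[[nm]])) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- ns$.bagGrad(f, 1L, p2, hyper, wantGrad = FALSE)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- ns$.bagGrad(f, 1L, p2, hyper, wantGrad = FALSE)$loss
        num[i] <- (lp - lm) / (2 * eps)
      }
      expect_equal(as.numeric(res$grads[[nm]]), as.numeric(num),
                   tolerance = 1e-5, label = paste(task, nm))
    }
  }
})

test_that("vectorized patch-batch gradients match finite differences", {
  ns <- asNamespace("kdmil")
  set.seed(43)
  B <- 5; dfix <- 3; dOut <- 3; m <- 4; cC <- 3
  F <- matrix(rnorm(B * dfix), B)
  y <- sample(0:(cC - 1), B, replace = TRUE)
  base <- list(We = matrix(rnorm(dOut * dfix, sd = 0.5), dOut),
               be = rnorm(dOut, sd = 0.1),
               Xp = matrix(rnorm(m * dOut), m),
               u = rnorm(m, sd = 0.5), s = 0.05)
  for (task in c("classification", "ordinal")) {
    params <- base
    params$Y <- if (task == "classification")
      abs(matrix(rnorm(m * cC), m)) + 0.2 else matrix(runif(m), ncol = 1)
    hyper <- list(task = task, alpha = 0.2, nClasses = cC)
    res <- ns$.patchBatchGrad(F, y, params, hyper)
    eps <- 1e-6
    for (nm in names(res$grads)) {
      num <- res$grads[[nm]] * 0
      for (i in seq_along(params[[nm]])) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        lp <- ns$.patchBatchGrad(F, y, p2, hyper, wantGrad = FALSE)$loss
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
        lm <- ns$.patchBatchGrad(F, y, p2, hyper, wantGrad = FALSE)$loss
        num[i] <- (lp - lm) / (2 * eps)
      }
      expect_equal(as.numeric(res$grads[[nm]]), as.numeric(num),
                   tolerance = 1e-5, label = paste(task, nm))
    }
  }
})

test_that("the learning-rate schedule ramps then anneals", {
  cfg <- trainingConfig(lr = 1e-4, warmupEpochs = 1L, maxEpochs = 50L)
  ns <- asNamespace("kdmil")
  lr0 <- ns$.lrAt(cfg, 1L, 0L, 10L)
  expect_equal(lr0, 1e-5, tolerance = 1e-12)          # factor-10 warm-up
  expect_equal(ns$.lrAt(cfg, 1L, 10L, 10L), 1e-4, tolerance = 1e-12)
  expect_equal(ns$.lrAt(cfg, 2L, 1L, 10L), 1e-4, tolerance = 1e-12)
  lrMid <- ns$.lrAt(cfg, 26L, 1L, 10L)
  expect_lt(lrMid, 1e-4)
  expect_gt(lrMid, 0)
  expect_lt(ns$.lrAt(cfg, 50L, 1L, 10L), lrMid)       # monotone decay
})

test_that("supervised training recovers a separable two-class problem", {
  set.seed(13)
  n <- 60
  X <- rbind(matrix(rnorm(n * 2, -2, 0.4), ncol = 2),
             matrix(rnorm(n * 2, 2, 0.4), ncol = 2))
  labels <- rep(0:1, each = n)
  tr <- list(features = X, labels = labels)
  cfg <- trainingConfig(task = "classification", nClasses = 2L,
                        perClass = 10L, maxEpochs = 50L, seed = 13L)
  m <- trainSupervised(tr, cfg)
  pred <- vapply(seq_len(nrow(X)), function(i)
    mapClass(predictPatch(m, X[i, ])), integer(1))
  expect_gte(mean(pred == labels), 0.99)
})

test_that("an untrained model predicts purely from initialization prototypes", {
  tr <- toyFeatureData(20, seed = 301)
  cfg <- trainingConfig(task = "classification", nClasses = 3L,
                        perClass = 5L, maxEpochs = 1L, seed = 4L)
  enc <- identityEncoder(2)
  ini <- initJointKdm(tr$features, tr$labels, cfg, enc)
  fake <- list(encoder = enc, joint = ini$joint)
  # the posterior is the plain kernel responsibility of the prototypes
  x <- c(0.3, 0.4)
  got <- mixtureProbs(predictPatch(fake, x))
  want <- oracleInfer(matrix(x, 1), 1, components(ini$joint),
                      mixtureProbs(ini$joint), bandwidth(ini$joint))
  expect_equal(got, want / sum(want), tolerance = 1e-10)
})

test_that("training is reproducible from its seed", {
  tr <- toyFeatureData(15, seed = 401)
  cfg <- trainingConfig(task = "classification", nClasses = 3L,
                        perClass = 5L, maxEpochs = 4L, seed = 77L)
  m1 <- trainSupervised(tr, cfg)
  m2 <- trainSupervised(tr, cfg)
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(components(jointKdm(m1)), components(jointKdm(m2)))
})

test_that("KDM parameters stay valid after optimizer steps", {
  m <- toyTrainedModel()
  jt <- jointKdm(m)
  expect_true(all(mixtureProbs(jt) >= 0))
  expect_equal(sum(mixtureProbs(jt)), 1, tolerance = 1e-9)
  expect_gt(bandwidth(jt), 0)
})

test_that("weak training recovers labels driven by a diagnostic pattern", {
  bags <- diagnosticBags(60, seed = 14)
  val <- diagnosticBags(15, seed = 15)
  test <- diagnosticBags(30, seed = 16)
  cfg <- trainingConfig(task = "classification", nClasses = 3L,
                        perClass = 12L, maxEpochs = 40L, seed = 14L)
  m <- trainWeak(bags, cfg, valBags = val)
  pr <- suppressWarnings(predictBags(m, test))
  truth <- vapply(test, function(b) b$label, integer(1))
  expect_gte(mean(pr$classIndex == truth), 0.9)
  # attention concentrates on the diagnostic patches
  ratios <- vapply(test, function(b) {
    w <- computeAttention(encodeFeatures(m@encoder, b$features),
                          m@attention)
    mean(w[b$isDiagnostic]) / mean(w[!b$isDiagnostic])
  }, numeric(1))
  expect_gt(mean(ratios), 1)
})

test_that("single-class weak data converges to that class", {
  bags <- lapply(1:10, function(i) {
    list(features = matrix(rnorm(6 * 3), 6), label = 0L,
         id = sprintf("b%d", i))
  })
  cfg <- trainingConfig(task = "classification", nClasses = 1L,
                        perClass = 4L, maxEpochs = 3L, seed = 6L)
  m <- trainWeak(bags, cfg)
  pr <- suppressWarnings(predictBags(m, bags))
  expect_true(all(pr$classIndex == 0L))
})

test_that("a one-patch bag with attention equals the supervised patch path", {
  bags <- diagnosticBags(12, seed = 18)
  cfg <- trainingConfig(task = "classification", nClasses = 3L,
                        perClass = 4L, maxEpochs = 2L, seed = 18L)
  m <- trainWeak(bags, cfg)
  x <- rnorm(8)
  one <- predictSlide(m, list(features = matrix(x, 1)))
  patch <- predictPatch(m, x)
  expect_equal(mixtureProbs(one), mixtureProbs(patch), tolerance = 1e-12)
})
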