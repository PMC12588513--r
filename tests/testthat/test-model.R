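test_that("prototype counts and kernel evaluations reproduce the printed table", {
  expect_identical(countKdmParameters(216, 128, 6), 29160L)
  expect_identical(countKdmParameters(108, 128, 6), 14580L)
  expect_identical(countKdmParameters(432, 128, 6), 58320L)
  expect_identical(countKdmParameters(648, 128, 6), 87480L)
  expect_identical(countKdmParameters(1, 1, 1), 3L)
  expect_identical(countKernelEvaluations(36, 216), 7776L)
  expect_identical(countKernelEvaluations(36, 108), 3888L)
  expect_identical(countKernelEvaluations(36, 432), 15552L)
  expect_identical(countKernelEvaluations(36, 648), 23328L)
  expect_identical(countKernelEvaluations(1, 1), 1L)
})

test_that("joint KDM initialization is stratified, uniform and registered", {
  set.seed(20)
  d <- 4
  X <- matrix(rnorm(300 * d), 300)
  labels <- rep(0:5, each = 50)
  enc <- identityEncoder(d)
  cfg <- trainingConfig(nClasses = 6L, perClass = 36L, seed = 9L)
  ini <- initJointKdm(X, labels, cfg, enc)
  expect_equal(nrow(components(ini$joint)), 216)
  expect_equal(mixtureProbs(ini$joint), rep(1 / 216, 216))
  expect_equal(unname(table(ini$registry$label)), rep(36L, 6),
               ignore_attr = TRUE)
  # label encodings are one-hot matching the registry labels
  Y <- labelValues(ini$joint)
  expect_true(all(Y %in% c(0, 1)))
  expect_equal(max.col(Y) - 1L, ini$registry$label)
  # bandwidth init: mean pairwise distance among prototypes / sqrt(2)
  pd <- as.matrix(dist(components(ini$joint)))
  expect_equal(bandwidth(ini$joint),
               mean(pd[upper.tri(pd)]) / sqrt(2), tolerance = 1e-10)
  # deterministic given the config seed
  ini2 <- initJointKdm(X, labels, cfg, enc)
  expect_identical(ini$registry, ini2$registry)
  expect_equal(components(ini$joint), components(ini2$joint))
  # insufficient class size names the class
  expect_error(initJointKdm(X[1:60, ], labels[1:60], cfg, enc), "class 1")
})

test_that("tiny stratified init works and ordinal labels are normalized", {
  X <- rbind(c(0, 0), c(1, 1))
  cfg <- trainingConfig(task = "ordinal", nClasses = 2L, perClass = 1L,
                        seed = 2L)
  ini <- initJointKdm(X, c(0, 1), cfg, identityEncoder(2))
  expect_equal(mixtureProbs(ini$joint), c(0.5, 0.5))
  expect_equal(sort(as.numeric(labelValues(ini$joint))), c(0, 0.5))
})

test_that("predictPatch composes encode, wrap and infer", {
  m <- toyTrainedModel()
  set.seed(21)
  x <- rnorm(2)
  got <- predictPatch(m, x)
  manual <- infer(KernelDensityMatrix(encodeFeatures(m@encoder, x), 1,
                                      jointKdm(m)@kernel), jointKdm(m))
  expect_equal(mixtureProbs(got), mixtureProbs(manual), tolerance = 1e-12)
  # single-prototype joint gives the trivial posterior
  jt1 <- JointKDM(matrix(c(0, 0), 1), matrix(c(1, 0, 0), 1), 1,
                  jointKdm(m)@kernel)
  fake <- list(encoder = m@encoder, joint = jt1)
  expect_equal(mixtureProbs(predictPatch(fake, x)), 1)
})

test_that("bag prediction is permutation invariant and collapses on identical patches", {
  m <- toyTrainedModel()
  att <- initAttention(2, seed = 12)
  model <- list(encoder = m@encoder, joint = m@joint, attention = att)
  set.seed(22)
  feats <- matrix(rnorm(12 * 2), 12)
  d1 <- predictSlide(model, list(features = feats))
  perm <- sample(12)
  d2 <- predictSlide(model, list(features = feats[perm, ]))
  expect_equal(mixtureProbs(d1), mixtureProbs(d2), tolerance = 1e-12)
  # identical patches: equals the supervised patch path
  x <- rnorm(2)
  same <- matrix(rep(x, each = 7), 7)
  dBag <- predictSlide(model, list(features = same))
  dPatch <- predictPatch(m, x)
  expect_equal(mixtureProbs(dBag), mixtureProbs(dPatch), tolerance = 1e-10)
  # manual composition oracle
  Z <- encodeFeatures(m@encoder, feats)
  a <- computeAttention(Z, att)
  manual <- infer(KernelDensityMatrix(Z, a, jointKdm(m)@kernel), jointKdm(m))
  expect_equal(mixtureProbs(d1), mixtureProbs(manual), tolerance = 1e-12)
})

test_that("losses match their closed forms and scalar loops", {
  expect_equal(classificationLoss(c(1, 0, 0), 0), 0, tolerance = 1e-10)
  expect_equal(classificationLoss(rep(1 / 6, 6), 3), log(6),
               tolerance = 1e-10)
  set.seed(23)
  P <- matrix(runif(5 * 4), 5); P <- P / rowSums(P)
  y <- sample(0:3, 5, replace = TRUE)
  manual <- -mean(sapply(1:5, function(i) log(P[i, y[i] + 1] + 1e-12)))
  expect_equal(classificationLoss(P, y), manual, tolerance = 1e-12)

  expect_equal(ordinalLoss(0.5, 0, 0.5, 0.1), 0)
  expect_equal(ordinalLoss(0.5, 0.25, 0.5, 0.1), 0.025)
  set.seed(24)
  e <- runif(8); v <- runif(8, 0, 0.2); yt <- runif(8)
  manual <- mean((e - yt)^2 + 0.3 * v)
  expect_equal(ordinalLoss(e, v, yt, 0.3), manual, tolerance = 1e-12)
  expect_error(ordinalLoss(0.1, 0.1, 0.1, -1), "nonnegative")
})

test_that("the conv encoder is deterministic and respects its contract", {
  enc <- convEncoder(32, seed = 31)
  img <- genPatch(patternSpec(2), 32, seed = 77)
  z1 <- encodeFeatures(enc, img)
  z2 <- encodeFeatures(enc, img)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(1L, 128L))
  enc2 <- convEncoder(32, seed = 31)
  expect_equal(encodeFeatures(enc2, img), z1)
  expect_error(convEncoder(8), "at least 16")
})
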