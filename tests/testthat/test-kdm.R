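test_that("KDM construction normalizes weights and rejects degenerate input", {
  kp <- KernelParams(1, 2)
  rho <- KernelDensityMatrix(rbind(c(0, 0), c(1, 1)), c(2, 2), kp)
  expect_equal(mixtureProbs(rho), c(0.5, 0.5))
  one <- KernelDensityMatrix(matrix(c(1, 2), 1), 1, kp)
  expect_equal(mixtureProbs(one), 1)
  expect_error(KernelDensityMatrix(rbind(c(0, 0)), c(0), kp), "mass")
  expect_error(KernelDensityMatrix(rbind(c(0, 0), c(1, 1)), c(-1, 2), kp),
               "nonnegative")
  expect_error(KernelDensityMatrix(matrix(0, 0, 2), numeric(0), kp))
})

test_that("projection matches the scalar-loop oracle and its limits", {
  kp <- KernelParams(1, 2)
  single <- KernelDensityMatrix(matrix(c(0.4, -0.1), 1), 1, kp)
  expect_equal(projection(single, c(0.4, -0.1)), 1, tolerance = 1e-14)
  # far-apart components with a tight kernel: cross-term vanishes
  tight <- KernelDensityMatrix(rbind(c(0, 0), c(100, 100)), c(0.5, 0.5),
                               KernelParams(0.05, 2))
  expect_equal(projection(tight, c(0, 0)), 0.5, tolerance = 1e-12)
  set.seed(3)
  r <- randomKdm(4, 3)
  x <- rnorm(3)
  expect_equal(projection(r$kdm, x),
               oracleProjection(r$comp, r$probs, r$sigma, x),
               tolerance = 1e-12)
  expect_error(projection(r$kdm, c(1, 2)), "dimension")
})

test_that("density is nonnegative and normalizer-scaled", {
  rho <- KernelDensityMatrix(matrix(0), 1, KernelParams(1 / sqrt(pi), 1))
  expect_equal(kdmDensity(rho, 0), 1, tolerance = 1e-12)
  set.seed(4)
  r <- randomKdm(5, 2)
  for (i in 1:100) {
    x <- rnorm(2, sd = 3)
    d <- kdmDensity(r$kdm, x)
    expect_gte(d, 0)
    expect_equal(d, pdfNormalizer(r$kdm@kernel) * projection(r$kdm, x),
                 tolerance = 1e-14)
  }
})

test_that("inference matches the double-loop oracle over a random battery", {
  set.seed(4)
  for (rep in 1:100) {
    m <- sample(1:20, 1); mp <- sample(1:20, 1); d <- sample(1:8, 1)
    sigma <- runif(1, 0.4, 2)
    rho <- randomKdm(m, d, sigma)
    jt <- randomJoint(mp, d, 3, sigma)
    got <- infer(rho$kdm, jt$joint)
    want <- oracleInfer(rho$comp, rho$probs, jt$xc, jt$probs, sigma)
    expect_equal(mixtureProbs(got), want / sum(want), tolerance = 1e-10)
    expect_equal(sum(mixtureProbs(got)), 1, tolerance = 1e-6)
  }
})

test_that("inference limit cases behave as required", {
  kp <- KernelParams(1, 2)
  # single prototype: posterior forced to 1
  jt1 <- JointKDM(matrix(c(0, 0), 1), matrix(c(1, 0), 1), 1, kp)
  rho <- KernelDensityMatrix(rbind(c(3, 1), c(-2, 0)), c(0.3, 0.7), kp)
  expect_equal(mixtureProbs(infer(rho, jt1)), 1)
  # tight kernel concentrates the posterior on the matching prototype
  tightK <- KernelParams(0.02, 2)
  jt2 <- JointKDM(rbind(c(0, 0), c(10, 10)), diag(2), c(0.5, 0.5), tightK)
  rhoPt <- KernelDensityMatrix(matrix(c(0, 0), 1), 1, tightK)
  pp <- mixtureProbs(infer(rhoPt, jt2))
  expect_equal(pp, c(1, 0), tolerance = 1e-10)
  expect_error(infer(KernelDensityMatrix(matrix(0), 1, KernelParams(1, 1)),
                     jt2), "dimension")
})

test_that("class probabilities follow the squared-encoding readout", {
  # one-hot rows: class probability equals summed posterior of its class
  kp <- KernelParams(1, 2)
  Y <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0))
  dist <- LabelDistribution(Y, c(0.2, 0.5, 0.3))
  expect_equal(classProbabilities(dist), c(0.5, 0.5, 0))
  # single one-hot component
  expect_equal(classProbabilities(LabelDistribution(rbind(c(0, 1)), 1)),
               c(0, 1))
  set.seed(5)
  V <- matrix(abs(rnorm(15)) + 0.1, 5)
  p <- runif(5); p <- p / sum(p)
  dist <- LabelDistribution(V, p)
  got <- classProbabilities(dist)
  expect_equal(got, oracleClassProbs(V, p), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  expect_error(classProbabilities(LabelDistribution(rbind(c(0, 0)), 1)),
               "norm")
})

test_that("posterior weight respects kernel locality", {
  # moving input mass onto the component nearest prototype 1 cannot
  # decrease prototype 1's posterior weight
  kp <- KernelParams(0.8, 1)
  jt <- JointKDM(matrix(c(0, 5)), matrix(c(1, 0), 2), c(0.5, 0.5), kp)
  comp <- matrix(c(0.2, 4.8))
  w1 <- sapply(seq(0.1, 0.9, by = 0.1), function(p) {
    rho <- KernelDensityMatrix(comp, c(p, 1 - p), kp)
    mixtureProbs(infer(rho, jt))[1]
  })
  expect_true(all(diff(w1) > 0))
})

test_that("mapClass breaks ties toward the lowest class index", {
  dist <- LabelDistribution(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_identical(mapClass(dist), 0L)
})
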