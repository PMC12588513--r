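# Shared small fixtures built in code. The toy trained model is computed
# once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# Linearly structured 2-d feature data in 3 classes; identity encoder.
toyFeatureData <- function(nPerClass = 40, seed = 101) {
  set.seed(seed)
  mu <- rbind(c(-2, 0), c(0, 2), c(2, 0))
  labels <- rep(0:2, each = nPerClass)
  X <- mu[labels + 1L, ] + matrix(rnorm(2 * length(labels), sd = 0.45),
                                  ncol = 2)
  list(features = X, labels = labels,
       ids = sprintf("toy_%03d", seq_along(labels)))
}

# A small supervised model trained on the toy features (cached).
toyTrainedModel <- function() {
  if (!is.null(.fixtureCache$toyModel)) return(.fixtureCache$toyModel)
  tr <- toyFeatureData(40, seed = 101)
  va <- toyFeatureData(15, seed = 102)
  cfg <- trainingConfig(task = "classification", nClasses = 3L,
                        perClass = 8L, maxEpochs = 15L, batchPatches = 32L,
                        seed = 5L)
  m <- trainSupervised(tr, cfg, valData = va)
  .fixtureCache$toyModel <- m
  m
}

# Feature-space MIL bags where a diagnostic cluster determines the label:
# class-c bags contain `nDiag` patches near mu_c plus background patches
# near the origin shared by all classes.
diagnosticBags <- function(nBags, nClasses = 3, k = 12, nDiag = 4,
                           d = 8, seed = 1) {
  set.seed(seed)
  mu <- matrix(0, nClasses, d)
  for (cc in seq_len(nClasses)) mu[cc, cc] <- 4
  lapply(seq_len(nBags), function(i) {
    lab <- as.integer((i - 1L) %% nClasses)
    diag <- mu[rep(lab + 1L, nDiag), ] +
      matrix(rnorm(nDiag * d, sd = 0.4), nDiag)
    bg <- matrix(rnorm((k - nDiag) * d, sd = 0.6), k - nDiag)
    feats <- rbind(diag, bg)
    list(features = feats, label = lab, id = sprintf("diag_%03d", i),
         isDiagnostic = c(rep(TRUE, nDiag), rep(FALSE, k - nDiag)))
  })
}
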