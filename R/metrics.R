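# Evaluation metrics: weighted kappa, accuracy, ordinal MAE.

#' Quadratic-weighted Cohen's kappa
#'
#' Chance-corrected agreement with penalties growing as the squared class
#' distance: \eqn{\kappa = 1 - \sum W O / \sum W E} with
#' \eqn{W_{ij} = (i-j)^2/(n-1)^2}, O the observed confusion matrix and E the
#' outer product of the marginals scaled to the sample size. This is the
#' standard metric for ordinal grading agreement. Plain (unweighted) Cohen's
#' kappa is available via \code{weights = "unweighted"}.
#'
#' @param yTrue,yPred integer vectors of 0-based labels, equal length.
#' @param nClasses number of classes.
#' @param weights "quadratic" (default) or "unweighted".
#' @return numeric(1) in [-1, 1].
#' @examples
#' quadraticWeightedKappa(c(0, 1, 2, 3), c(0, 1, 2, 3), 4)  # 1
#' @export
quadraticWeightedKappa <- function(yTrue, yPred, nClasses,
                                   weights = c("quadratic", "unweighted")) {
  weights <- match.arg(weights)
  yTrue <- as.integer(yTrue); yPred <- as.integer(yPred)
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have the same length")
  if (any(c(yTrue, yPred) < 0L) || any(c(yTrue, yPred) >= nClasses))
    stop("labels must lie in [0, nClasses)")
  n <- length(yTrue)
  lev <- 0:(nClasses - 1L)
  O <- table(factor(yTrue, levels = lev), factor(yPred, levels = lev))
  Emat <- outer(rowSums(O), colSums(O)) / n
  idx <- lev
  W <- if (weights == "quadratic")
    outer(idx, idx, function(i, j) (i - j)^2 / (nClasses - 1)^2)
  else outer(idx, idx, function(i, j) as.numeric(i != j))
  den <- sum(W * Emat)
  if (den == 0) {
    if (all(yTrue == yPred)) return(1)
    stop("kappa undefined: degenerate single-class marginals")
  }
  1 - sum(W * O) / den
}

#' Evaluate predictions against ground truth
#'
#' Computes quadratic-weighted kappa, accuracy and MAE (on the [0, 1]
#' normalized ordinal scale). With a variance threshold, metrics are
#' computed only over the retained (low-variance) subset and the retained
#' fraction is reported; no information outside the retained subset enters
#' the scores.
#'
#' @param predictions data.frame from [predictBags()] (columns id,
#'   classIndex, expected, variance).
#' @param truths integer vector of true 0-based labels aligned with
#'   \code{predictions$id}, or a named vector indexed by id.
#' @param nClasses number of classes.
#' @param varianceThreshold optional positive threshold; predictions with
#'   variance >= threshold are dropped before scoring.
#' @return list (class \code{EvalResult}) with kappa, accuracy, mae, n,
#'   retainedFraction.
#' @export
evaluatePredictions <- function(predictions, truths, nClasses = 6L,
                                varianceThreshold = NULL) {
  if (!is.null(names(truths))) {
    if (!all(predictions$id %in% names(truths)))
      stop("prediction ids missing from 'truths'")
    truths <- truths[predictions$id]
  }
  if (length(truths) != nrow(predictions))
    stop("'truths' must align with 'predictions'")
  truths <- as.integer(truths)
  keepFrac <- 1
  if (!is.null(varianceThreshold)) {
    vf <- varianceFilter(predictions, varianceThreshold)
    predictions <- vf$retained
    truths <- truths[vf$keep]
    keepFrac <- vf$retainedFraction
  }
  if (nrow(predictions) < 1L) stop("no predictions retained")
  yhat <- predictions$classIndex
  structure(list(
    kappa = quadraticWeightedKappa(truths, yhat, nClasses),
    accuracy = mean(yhat == truths),
    mae = mean(abs(predictions$expected - toOrdinal(truths, nClasses))),
    n = nrow(predictions),
    retainedFraction = keepFrac), class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf(
    "EvalResult: kappa = %.3f, accuracy = %.3f, MAE = %.3f (n = %d, retained %.0f%%)\n",
    x$kappa, x$accuracy, x$mae, x$n, 100 * x$retainedFraction))
  invisible(x)
}
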