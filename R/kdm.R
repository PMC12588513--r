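# KDM projection, density and the inference operation mapping an input KDM
# through the joint feature-label KDM into a posterior label distribution.

#' Projection function of a KDM
#'
#' \eqn{f_\rho(x) = \sum_i p_i\, k(x, x^{(i)})^2}: the squared-kernel
#' projection of a point onto the mixture state represented by the KDM.
#'
#' @param rho a \linkS4class{KernelDensityMatrix}.
#' @param x numeric vector of the KDM's dimension.
#' @return numeric(1) in (0, 1].
#' @export
projection <- function(rho, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(rho@components))
    stop("'x' dimension does not match the KDM components")
  K <- kernelMatrix(matrix(x, nrow = 1L), rho@components, rho@kernel)
  sum(rho@probs * as.numeric(K)^2)
}

#' Probability density of a KDM
#'
#' The projection function scaled by the kernel's PDF normalization constant,
#' \eqn{\hat f_\rho(x) = M_k f_\rho(x)}, which integrates to one over
#' \eqn{R^d}.
#'
#' @inheritParams projection
#' @return nonnegative numeric(1).
#' @export
kdmDensity <- function(rho, x) {
  pdfNormalizer(rho@kernel) * projection(rho, x)
}

#' KDM inference: input distribution to label distribution
#'
#' Transforms the distribution of the input variables, represented by the KDM
#' \code{rhoX}, into a posterior distribution over label encodings through
#' the joint feature-label KDM. The posterior weight of joint component i is
#' \deqn{p''_i = \sum_\ell p_\ell \frac{p'_i k(x^{(\ell)}, x'^{(i)})^2}
#'   {\sum_j p'_j k(x^{(\ell)}, x'^{(j)})^2 + \epsilon}}
#' i.e. each input component distributes its mass over the prototypes in
#' proportion to squared kernel similarity, and the results are averaged
#' under the input mixture weights. A small \eqn{\epsilon = 10^{-10}} guards
#' the denominator against underflow when an input point is far from every
#' prototype.
#'
#' @param rhoX a \linkS4class{KernelDensityMatrix} over features.
#' @param joint a \linkS4class{JointKDM}.
#' @return A \linkS4class{LabelDistribution} whose values are the joint
#'   KDM's label encodings.
#' @export
setGeneric("infer", function(rhoX, joint) standardGeneric("infer"))

#' @rdname infer
#' @export
setMethod("infer", signature("KernelDensityMatrix", "JointKDM"),
  function(rhoX, joint) {
    if (ncol(rhoX@components) != ncol(joint@xComponents))
      stop("input KDM and joint KDM dimensions do not match")
    G <- kernelMatrix(rhoX@components, joint@xComponents, joint@kernel)^2
    W <- sweep(G, 2L, joint@probs, "*")           # ell x m': p'_i k^2
    S <- rowSums(W) + .KDMIL_EPS
    R <- W / S
    ppp <- as.numeric(crossprod(R, rhoX@probs))
    if (sum(ppp) <= 0) {
      warning("all kernel responses underflowed; posterior is degenerate ",
              "(returning a uniform distribution)")
      ppp <- rep(1 / nrow(joint@xComponents), nrow(joint@xComponents))
    }
    LabelDistribution(joint@yComponents, ppp)
  })

#' Class probabilities from a label distribution
#'
#' Normalizes each label-encoding row to unit Euclidean norm and the
#' posterior weights to unit sum, then reads off class probabilities as
#' \eqn{p_c = \sum_j p''_j\, \hat y'^2_{jc}}; squaring mirrors the Born-rule
#' readout of the underlying density-matrix formulation and guarantees a
#' distribution on the simplex.
#'
#' @param dist a \linkS4class{LabelDistribution} with c >= 1 label columns.
#' @return numeric(c) summing to one.
#' @export
classProbabilities <- function(dist) {
  V <- dist@values
  n2 <- rowSums(V^2)
  if (any(n2 <= 0)) stop("label encoding rows must have nonzero norm")
  p <- dist@probs / sum(dist@probs)
  as.numeric(crossprod(V^2 / n2, p))
}

#' Most probable class of a label distribution
#'
#' Argmax of [classProbabilities()], with ties broken toward the lowest
#' class index. Classes are 0-based.
#'
#' @param dist a \linkS4class{LabelDistribution}.
#' @return integer(1) in \code{0:(c-1)}.
#' @export
mapClass <- function(dist) {
  which.max(classProbabilities(dist)) - 1L
}
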