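#' @import methods
NULL

#' Kernel parameters
#'
#' Parameters of the normalized Gaussian (RBF) kernel
#' \eqn{k(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))} used by every kernel
#' density matrix. The bandwidth is stored on the log scale so that gradient
#' updates keep it positive without constraints.
#'
#' @slot logBandwidth numeric(1), \eqn{\log \sigma}.
#' @slot dim integer(1), feature dimension \eqn{d}.
#'
#' @exportClass KernelParams
setClass("KernelParams",
  representation(logBandwidth = "numeric", dim = "integer"))

setValidity("KernelParams", function(object) {
  if (length(object@logBandwidth) != 1L || !is.finite(object@logBandwidth))
    return("logBandwidth must be a single finite number")
  if (length(object@dim) != 1L || is.na(object@dim) || object@dim < 1L)
    return("dim must be a positive integer")
  TRUE
})

#' @param bandwidth positive numeric(1), kernel bandwidth \eqn{\sigma}.
#' @param dim positive integer(1), feature dimension.
#' @return A \code{KernelParams} object.
#' @rdname KernelParams-class
#' @examples
#' KernelParams(bandwidth = 0.7, dim = 2)
#' @export
KernelParams <- function(bandwidth, dim) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0)
    stop("'bandwidth' must be a single positive finite number")
  new("KernelParams", logBandwidth = log(bandwidth), dim = as.integer(dim))
}

#' Kernel density matrix
#'
#' A kernel density matrix (KDM) is a triplet (components, mixture
#' probabilities, kernel): a set of points \eqn{x^{(1)},\dots,x^{(m)}} with
#' nonnegative weights summing to one, together with a normalized kernel
#' (\eqn{k(x,x)=1}). It represents a mixture state in the kernel's
#' reproducing kernel Hilbert space without ever materializing the
#' Hilbert-space operator; densities and posteriors are obtained through
#' squared-kernel projections.
#'
#' @slot components numeric matrix, m x d; rows are the component points.
#' @slot probs numeric(m), mixture weights on the simplex.
#' @slot kernel a \linkS4class{KernelParams}.
#'
#' @seealso [projection()], [kdmDensity()], [infer()]
#' @exportClass KernelDensityMatrix
setClass("KernelDensityMatrix",
  representation(components = "matrix", probs = "numeric",
                 kernel = "KernelParams"))

setValidity("KernelDensityMatrix", function(object) {
  m <- nrow(object@components)
  if (is.null(m) || m < 1L) return("components must have at least one row")
  if (!is.numeric(object@components) || !all(is.finite(object@components)))
    return("components must be finite numeric")
  if (length(object@probs) != m)
    return("length(probs) must equal nrow(components)")
  if (any(object@probs < 0)) return("probs must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-6)
    return("probs must sum to 1 (within 1e-6)")
  if (ncol(object@components) != object@kernel@dim)
    return("ncol(components) must equal kernel dimension")
  TRUE
})

#' Construct a kernel density matrix
#'
#' Validates the components and re-normalizes the mixture weights so they sum
#' to one.
#'
#' @param components numeric matrix (m x d) or vector (treated as 1 x d).
#' @param probs nonnegative weights, length m, with positive sum.
#' @param kernel a \linkS4class{KernelParams}.
#' @return A \linkS4class{KernelDensityMatrix}.
#' @examples
#' kp <- KernelParams(1, 2)
#' KernelDensityMatrix(rbind(c(0, 0), c(1, 1)), c(2, 2), kp)
#' @export
KernelDensityMatrix <- function(components, probs, kernel) {
  if (is.null(dim(components))) components <- matrix(components, nrow = 1L)
  components <- as.matrix(components)
  if (nrow(components) < 1L) stop("'components' must have at least one row")
  probs <- as.numeric(probs)
  if (length(probs) != nrow(components))
    stop("'probs' must have one weight per component")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("'probs' must be finite and nonnegative")
  s <- sum(probs)
  if (s <= 0) stop("'probs' must have positive total mass")
  new("KernelDensityMatrix", components = components, probs = probs / s,
      kernel = kernel)
}

#' Joint kernel density matrix over feature-label pairs
#'
#' The model's probabilistic memory: a KDM whose components are paired
#' prototype positions \eqn{x'^{(i)}} in feature space and label encodings
#' \eqn{y'^{(i)}} (one-hot rows for classification, scalars on [0, 1] for
#' ordinal regression). All three parts -- positions, label encodings and
#' mixture weights -- are trainable.
#'
#' @slot xComponents numeric matrix, m' x d prototype positions.
#' @slot yComponents numeric matrix, m' x c label encodings.
#' @slot probs numeric(m'), mixture weights on the simplex.
#' @slot kernel the feature-space \linkS4class{KernelParams}.
#'
#' @exportClass JointKDM
setClass("JointKDM",
  representation(xComponents = "matrix", yComponents = "matrix",
                 probs = "numeric", kernel = "KernelParams"))

setValidity("JointKDM", function(object) {
  m <- nrow(object@xComponents)
  if (is.null(m) || m < 1L) return("xComponents must have at least one row")
  if (nrow(object@yComponents) != m)
    return("xComponents and yComponents must have the same number of rows")
  if (length(object@probs) != m)
    return("length(probs) must equal the number of components")
  if (any(object@probs < 0)) return("probs must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-6)
    return("probs must sum to 1 (within 1e-6)")
  if (ncol(object@xComponents) != object@kernel@dim)
    return("ncol(xComponents) must equal kernel dimension")
  TRUE
})

#' Construct a joint KDM
#'
#' @param xComponents m' x d matrix of prototype positions.
#' @param yComponents m' x c matrix of label encodings (a vector is treated
#'   as a single column).
#' @param probs nonnegative weights with positive sum; re-normalized.
#' @param kernel feature-space \linkS4class{KernelParams}.
#' @return A \linkS4class{JointKDM}.
#' @export
JointKDM <- function(xComponents, yComponents, probs, kernel) {
  xComponents <- as.matrix(xComponents)
  if (is.null(dim(yComponents)) || length(dim(yComponents)) != 2L)
    yComponents <- matrix(yComponents, ncol = 1L)
  yComponents <- as.matrix(yComponents)
  probs <- as.numeric(probs)
  s <- sum(probs)
  if (any(!is.finite(probs)) || any(probs < 0) || s <= 0)
    stop("'probs' must be finite, nonnegative, with positive total mass")
  new("JointKDM", xComponents = xComponents, yComponents = yComponents,
      probs = probs / s, kernel = kernel)
}

#' Posterior label distribution
#'
#' The result of KDM inference: the joint KDM's label encodings together with
#' their posterior weights \eqn{p''}. Class probabilities, expected values
#' and variances are derived from this object.
#'
#' @slot values numeric matrix, m' x c label encodings (c = 1 for ordinal).
#' @slot probs numeric(m'), posterior weights on the simplex.
#'
#' @seealso [classProbabilities()], [posteriorMoments()]
#' @exportClass LabelDistribution
setClass("LabelDistribution",
  representation(values = "matrix", probs = "numeric"))

setValidity("LabelDistribution", function(object) {
  if (nrow(object@values) != length(object@probs))
    return("values rows and probs length must agree")
  if (any(object@probs < 0)) return("probs must be nonnegative")
  if (abs(sum(object@probs) - 1) > 1e-6)
    return("probs must sum to 1 (within 1e-6)")
  TRUE
})

#' Construct a label distribution
#'
#' @param values m' x c matrix of label encodings (vector = one column).
#' @param probs nonnegative posterior weights; re-normalized to sum to one.
#' @return A \linkS4class{LabelDistribution}.
#' @export
LabelDistribution <- function(values, probs) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  probs <- as.numeric(probs)
  s <- sum(probs)
  if (any(!is.finite(probs)) || any(probs < 0) || s <= 0)
    stop("'probs' must be finite, nonnegative, with positive total mass")
  new("LabelDistribution", values = as.matrix(values), probs = probs / s)
}

#' Trained KDM model
#'
#' Bundles everything needed for prediction and interpretation: the encoder
#' (fixed convolutional features plus trainable projection, or the identity
#' on pre-encoded vectors), the attention parameters for bag pooling (NULL in
#' fully supervised patch mode), the joint KDM, the training configuration,
#' the prototype initialization registry (which training example seeded each
#' component) and the per-epoch training log.
#'
#' @slot encoder list; see [convEncoder()] and [identityEncoder()].
#' @slot attention list of MLP parameters or list() when unused.
#' @slot joint a \linkS4class{JointKDM}.
#' @slot config list; see [trainingConfig()].
#' @slot registry data.frame mapping component index to source example.
#' @slot task character(1), "classification" or "ordinal".
#' @slot trainingLog data.frame (epoch, split, loss, metric columns).
#'
#' @exportClass KdmModel
setClass("KdmModel",
  representation(encoder = "list", attention = "list", joint = "JointKDM",
                 config = "list", registry = "data.frame",
                 task = "character", trainingLog = "data.frame"))

setMethod("show", "KernelParams", function(object) {
  cat("KernelParams: RBF, sigma =", format(exp(object@logBandwidth)),
      ", d =", object@dim, "\n")
})

setMethod("show", "KernelDensityMatrix", function(object) {
  cat("KernelDensityMatrix with", nrow(object@components),
      "component(s) in d =", ncol(object@components),
      "; sigma =", format(exp(object@kernel@logBandwidth)), "\n")
})

setMethod("show", "JointKDM", function(object) {
  cat("JointKDM:", nrow(object@xComponents), "prototype(s), d =",
      ncol(object@xComponents), ", label dim =", ncol(object@yComponents),
      ", sigma =", format(exp(object@kernel@logBandwidth)), "\n")
})

setMethod("show", "LabelDistribution", function(object) {
  cat("LabelDistribution over", nrow(object@values),
      "component(s), label dim =", ncol(object@values), "\n")
})

setMethod("show", "KdmModel", function(object) {
  cat("KdmModel (", object@task, ")\n", sep = "")
  cat("  encoder:", object@encoder$type, "\n")
  cat("  prototypes:", nrow(object@joint@xComponents), "in d =",
      ncol(object@joint@xComponents), "\n")
  if (length(object@attention)) cat("  attention: local-global MLP pooling\n")
  if (nrow(object@trainingLog))
    cat("  trained for", max(object@trainingLog$epoch), "epoch(s)\n")
})

# ---- accessors ----

#' Accessors for KDM objects
#'
#' @param object a KDM-family object.
#' @return \code{bandwidth} returns \eqn{\sigma}; \code{components},
#'   \code{labelValues} and \code{mixtureProbs} return the corresponding
#'   slots; \code{jointKdm}, \code{initRegistry} and \code{trainingLog}
#'   extract the parts of a \linkS4class{KdmModel}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setMethod("bandwidth", "KernelParams", function(object)
  exp(object@logBandwidth))
#' @rdname accessors
#' @export
setMethod("bandwidth", "KernelDensityMatrix", function(object)
  exp(object@kernel@logBandwidth))
#' @rdname accessors
#' @export
setMethod("bandwidth", "JointKDM", function(object)
  exp(object@kernel@logBandwidth))

#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setMethod("components", "KernelDensityMatrix", function(object)
  object@components)
#' @rdname accessors
#' @export
setMethod("components", "JointKDM", function(object) object@xComponents)

#' @rdname accessors
#' @export
setGeneric("labelValues", function(object) standardGeneric("labelValues"))
#' @rdname accessors
#' @export
setMethod("labelValues", "JointKDM", function(object) object@yComponents)
#' @rdname accessors
#' @export
setMethod("labelValues", "LabelDistribution", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("mixtureProbs", function(object) standardGeneric("mixtureProbs"))
#' @rdname accessors
#' @export
setMethod("mixtureProbs", "KernelDensityMatrix", function(object)
  object@probs)
#' @rdname accessors
#' @export
setMethod("mixtureProbs", "JointKDM", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("mixtureProbs", "LabelDistribution", function(object) object@probs)

#' @rdname accessors
#' @export
setGeneric("jointKdm", function(object) standardGeneric("jointKdm"))
#' @rdname accessors
#' @export
setMethod("jointKdm", "KdmModel", function(object) object@joint)

#' @rdname accessors
#' @export
setGeneric("initRegistry", function(object) standardGeneric("initRegistry"))
#' @rdname accessors
#' @export
setMethod("initRegistry", "KdmModel", function(object) object@registry)

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(object) standardGeneric("trainingLog"))
#' @rdname accessors
#' @export
setMethod("trainingLog", "KdmModel", function(object) object@trainingLog)
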