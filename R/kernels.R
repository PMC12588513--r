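# Normalized RBF kernel, kernel matrices and the PDF normalization constant.
# Everything downstream (projection, density, inference) is built on these.

.KDMIL_EPS <- 1e-10

#' Normalized Gaussian kernel
#'
#' Evaluates \eqn{k(x, x') = \exp(-\|x - x'\|^2 / (2\sigma^2))}. The kernel
#' is normalized (\eqn{k(x, x) = 1}), symmetric and strictly positive, as
#' required for kernel density matrix components.
#'
#' @param x,x2 numeric vectors of equal length.
#' @param params a \linkS4class{KernelParams}.
#' @return numeric(1) in (0, 1].
#' @examples
#' kp <- KernelParams(0.7, 2)
#' rbfKernel(c(0.3, -1.2), c(0.3, -1.2), kp)  # exactly 1
#' @export
rbfKernel <- function(x, x2, params) {
  x <- as.numeric(x); x2 <- as.numeric(x2)
  if (length(x) != length(x2))
    stop("'x' and 'x2' must have the same dimension")
  if (length(x) != params@dim)
    stop("input dimension does not match kernel dimension")
  if (any(!is.finite(x)) || any(!is.finite(x2)))
    stop("kernel inputs must be finite")
  s2 <- exp(2 * params@logBandwidth)
  exp(-sum((x - x2)^2) / (2 * s2))
}

# Pairwise squared Euclidean distances between rows of A (m x d) and B (n x d),
# clamped at zero against floating-point cancellation.
.sqDist <- function(A, B) {
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Kernel matrix between two sets of points
#'
#' Entry (i, j) is \code{rbfKernel(A[i, ], B[j, ], params)}, computed with a
#' vectorized pairwise-distance expansion.
#'
#' @param A,B numeric matrices with the same number of columns (vectors are
#'   treated as single rows).
#' @param params a \linkS4class{KernelParams}.
#' @return numeric matrix, \code{nrow(A)} x \code{nrow(B)}, entries in (0, 1].
#' @export
kernelMatrix <- function(A, B, params) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  if (is.null(dim(B))) B <- matrix(B, nrow = 1L)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("'A' and 'B' must share the same column dimension")
  if (ncol(A) != params@dim)
    stop("input dimension does not match kernel dimension")
  s2 <- exp(2 * params@logBandwidth)
  exp(-.sqDist(A, B) / (2 * s2))
}

#' PDF normalization constant for the squared RBF kernel
#'
#' The squared normalized RBF kernel integrates to \eqn{(\pi\sigma^2)^{d/2}}
#' over \eqn{R^d} (squaring halves the length scale of the exponent), so
#' multiplying a KDM projection by \eqn{(\pi\sigma^2)^{-d/2}} turns it into a
#' probability density.
#'
#' @param params a \linkS4class{KernelParams}.
#' @return positive numeric(1), \eqn{(\pi\sigma^2)^{-d/2}}.
#' @examples
#' pdfNormalizer(KernelParams(1, 2))  # 1/pi
#' @export
pdfNormalizer <- function(params) {
  s2 <- exp(2 * params@logBandwidth)
  (pi * s2)^(-params@dim / 2)
}
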