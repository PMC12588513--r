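# Interpretation: prototype pruning and retrieval, overlapping-tile
# inference, per-tile class/uncertainty maps, and tissue-extension
# quantification.

#' Prune low-weight prototypes
#'
#' Components whose learned mixture weight falls below the threshold
#' contribute minimally to predictions. By default this is report-only (the
#' model is unchanged); with \code{drop = TRUE} a reduced joint KDM with
#' re-normalized weights is also returned.
#'
#' @param joint a \linkS4class{JointKDM} (or \linkS4class{KdmModel}).
#' @param tau weight threshold in (0, 1); default 0.01.
#' @param drop if TRUE, also return the pruned joint KDM.
#' @return list with \code{active} (indices with weight >= tau),
#'   \code{activeCount}, and (if \code{drop}) \code{joint}.
#' @export
prunePrototypes <- function(joint, tau = 0.01, drop = FALSE) {
  if (is(joint, "KdmModel")) joint <- joint@joint
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("'tau' must lie in (0, 1)")
  active <- which(joint@probs >= tau)
  out <- list(active = active, activeCount = length(active))
  if (drop) {
    if (!length(active)) stop("pruning would remove every component")
    out$joint <- JointKDM(joint@xComponents[active, , drop = FALSE],
                          joint@yComponents[active, , drop = FALSE],
                          joint@probs[active], joint@kernel)
  }
  out
}

#' Retrieve the nearest prototype of a query
#'
#' Encodes the query and returns the joint-KDM component closest in
#' Euclidean distance in the latent space, together with the initialization
#' example that seeded it (from the model's registry). Ties go to the
#' lowest component index.
#'
#' @param model a trained \linkS4class{KdmModel} with a registry.
#' @param x query image array or feature vector.
#' @return list with \code{component}, \code{distance}, \code{id},
#'   \code{label} (the registry row of the winning component).
#' @export
nearestPrototype <- function(model, x) {
  if (!nrow(model@registry)) stop("model has no initialization registry")
  z <- encodeFeatures(model@encoder, x)
  d2 <- .sqDist(z, model@joint@xComponents)
  i <- which.min(d2)            # which.min returns the first (lowest) index
  reg <- model@registry[i, ]
  list(component = i, distance = sqrt(d2[i]), id = reg$id,
       label = reg$label)
}

#' Overlapping tile grid over an image
#'
#' Raster-order square windows of side \code{size} with stride
#' \code{round(size * (1 - overlap))}; a trailing window clamped to the far
#' edge is appended on each axis when the stride does not land exactly.
#' Coordinates are 0-based half-open pixel intervals.
#'
#' @param imageShape integer(2) image height and width (a 3d array's first
#'   two dims are used).
#' @param size tile side length in pixels.
#' @param overlap fraction of overlap between neighboring tiles in [0, 1);
#'   0.8 by default (the high-overlap setting used for uncertainty maps).
#' @return list (class \code{TileGrid}) with \code{windows} (data.frame
#'   rowStart/colStart/size), \code{stride}, \code{size}, \code{overlap},
#'   \code{nRows}, \code{nCols}.
#' @examples
#' tileSlide(c(100, 100), 20, 0.8)$stride  # 4
#' @export
tileSlide <- function(imageShape, size, overlap = 0.8) {
  if (length(imageShape) > 2L) imageShape <- imageShape[1:2]
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  if (any(size > imageShape)) stop("'size' exceeds the image dimensions")
  stride <- max(1L, as.integer(round(size * (1 - overlap))))
  axisStarts <- function(n) {
    s <- seq.int(0L, n - size, by = stride)
    if (s[length(s)] != n - size) s <- c(s, n - size)
    s
  }
  rs <- axisStarts(imageShape[1]); cs <- axisStarts(imageShape[2])
  windows <- expand.grid(colStart = cs, rowStart = rs)[, 2:1]
  windows$size <- as.integer(size)
  structure(list(windows = windows, stride = stride, size = as.integer(size),
                 overlap = overlap, nRows = length(rs), nCols = length(cs)),
            class = "TileGrid")
}

#' Per-tile inference report over a slide image
#'
#' Tiles the image with [tileSlide()], runs the model's patch path on every
#' tile, and assembles the per-tile class map (argmax), expected-value map
#' and variance map, plus per-class area proportions (fraction of tiles
#' argmax-assigned to each class).
#'
#' @param image H x W x 3 array.
#' @param model a trained \linkS4class{KdmModel} (patch-trained for pattern
#'   maps; slide-trained models give grade maps).
#' @param size tile side length (must match the encoder input size for a
#'   convolutional encoder).
#' @param overlap tile overlap fraction; 0.8 by default.
#' @return list (class \code{SlideReport}) with \code{tiles} (data.frame
#'   row/col/class/expected/variance), \code{classMap}, \code{expectedMap},
#'   \code{varianceMap} (nRows x nCols matrices), \code{proportions},
#'   \code{grid}.
#' @export
slideReport <- function(image, model, size, overlap = 0.8) {
  grid <- tileSlide(dim(image), size, overlap)
  win <- grid$windows
  nT <- nrow(win)
  crops <- lapply(seq_len(nT), function(i)
    image[win$rowStart[i] + seq_len(size),
          win$colStart[i] + seq_len(size), , drop = FALSE])
  Z <- encodeFeatures(model@encoder, crops)
  joint <- model@joint
  nC <- model@config$nClasses
  cls <- integer(nT); ev <- numeric(nT); vv <- numeric(nT)
  for (i in seq_len(nT)) {
    dist <- infer(KernelDensityMatrix(Z[i, , drop = FALSE], 1,
                                      joint@kernel), joint)
    if (model@task == "classification") {
      q <- classProbabilities(dist)
      cls[i] <- which.max(q) - 1L
      mom <- posteriorMoments(q, toOrdinal(seq_along(q) - 1L, length(q)))
    } else {
      mom <- posteriorMoments(dist)
      cls[i] <- ordinalToClass(mom$expected, nC)
    }
    ev[i] <- mom$expected; vv[i] <- mom$variance
  }
  props <- tabulate(cls + 1L, nbins = nC) / nT
  names(props) <- if (nC == 5L) .PATTERN_NAMES else
    paste0("class", 0:(nC - 1L))
  asMap <- function(x) matrix(x, grid$nRows, grid$nCols, byrow = TRUE)
  structure(list(
    tiles = data.frame(row = win$rowStart, col = win$colStart,
                       class = cls, expected = ev, variance = vv),
    classMap = asMap(cls), expectedMap = asMap(ev), varianceMap = asMap(vv),
    proportions = props, grid = grid), class = "SlideReport")
}

#' Mean absolute error between pattern extension vectors
#'
#' Mean over classes of |true - predicted| area proportion (fractions on
#' [0, 1], not percentages).
#'
#' @param trueProps,predProps equal-length proportion vectors.
#' @return nonnegative numeric(1).
#' @export
extensionMae <- function(trueProps, predProps) {
  if (length(trueProps) != length(predProps))
    stop("proportion vectors must have equal length")
  mean(abs(as.numeric(trueProps) - as.numeric(predProps)))
}

#' @export
print.SlideReport <- function(x, ...) {
  cat("SlideReport:", nrow(x$tiles), "tiles (",
      x$grid$nRows, "x", x$grid$nCols, "), stride", x$grid$stride, "\n")
  print(round(x$proportions, 3))
  invisible(x)
}
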