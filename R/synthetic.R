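# Synthetic histology-like data: five tissue patterns (stroma, benign
# epithelium, Gleason 3/4/5) rendered as blob textures with monotone
# "severity" (more, smaller, darker, increasingly fused glands with grade),
# composed into 36-patch slides whose pattern composition determines an
# ISUP-style grade group 0-5, with full ground truth (per-patch labels,
# per-pattern area proportions, primary/secondary patterns).

.PATTERN_NAMES <- c("stroma", "benign", "gleason3", "gleason4", "gleason5")

#' Texture specification of a tissue pattern
#'
#' Returns the rendering parameters of one of the five pattern classes.
#' Blob count is expressed per 64x64 patch area and scaled with the rendered
#' area; severity increases with class: more and smaller blobs, higher
#' fusion probability, darker and more cellular background, loss of gland
#' lumina.
#'
#' @param classIndex integer in 0:4 (0 stroma, 1 benign epithelium,
#'   2 Gleason 3, 3 Gleason 4, 4 Gleason 5).
#' @return list of texture parameters.
#' @export
patternSpec <- function(classIndex) {
  if (!classIndex %in% 0:4) stop("'classIndex' must be in 0:4")
  specs <- list(
    list(blobCount = 0,  radiusMean = 0,   radiusSd = 0,   fusionProb = 0,
         lumen = FALSE, noiseSd = 0.020,
         base = c(0.93, 0.80, 0.88), blob = c(0.50, 0.30, 0.60)),
    list(blobCount = 5,  radiusMean = 9.0, radiusSd = 1.5, fusionProb = 0,
         lumen = TRUE,  noiseSd = 0.030,
         base = c(0.90, 0.75, 0.85), blob = c(0.45, 0.25, 0.55)),
    list(blobCount = 11, radiusMean = 5.5, radiusSd = 1.0, fusionProb = 0.15,
         lumen = TRUE,  noiseSd = 0.030,
         base = c(0.87, 0.70, 0.82), blob = c(0.40, 0.22, 0.52)),
    list(blobCount = 16, radiusMean = 4.5, radiusSd = 0.8, fusionProb = 0.60,
         lumen = TRUE,  noiseSd = 0.035,
         base = c(0.84, 0.66, 0.79), blob = c(0.35, 0.18, 0.48)),
    list(blobCount = 26, radiusMean = 3.0, radiusSd = 0.6, fusionProb = 0.90,
         lumen = FALSE, noiseSd = 0.040,
         base = c(0.80, 0.60, 0.75), blob = c(0.28, 0.14, 0.42)))
  spec <- specs[[classIndex + 1L]]
  spec$classIndex <- as.integer(classIndex)
  spec$name <- .PATTERN_NAMES[classIndex + 1L]
  spec
}

#' Render a synthetic tissue patch
#'
#' Draws the pattern's texture on a noisy background: gland-like blobs with
#' a dark rim and (for benign/Gleason 3) a bright lumen; fused blobs are
#' rendered as short chains of overlapping circles. Deterministic given
#' (spec, size, seed); pixel values lie in [0, 1]. Blob count scales with
#' area so a larger canvas keeps the same texture density.
#'
#' @param spec a pattern specification from [patternSpec()].
#' @param size side length in pixels (>= 16).
#' @param seed integer seed.
#' @return size x size x 3 array in [0, 1].
#' @export
genPatch <- function(spec, size = 64L, seed = 1L) {
  if (size < 16L) stop("'size' must be at least 16")
  rng <- .localRNG(seed)
  on.exit(rng$restore())
  size <- as.integer(size)
  img <- array(0, dim = c(size, size, 3L))
  noise <- matrix(stats::rnorm(size * size, sd = spec$noiseSd), size)
  for (ch in 1:3) img[, , ch] <- spec$base[ch] + noise
  nBlobs <- round(spec$blobCount * (size / 64)^2)
  if (nBlobs > 0) {
    for (b in seq_len(nBlobs)) {
      cx <- stats::runif(1, 3, size - 3)
      cy <- stats::runif(1, 3, size - 3)
      r <- max(1.5, stats::rnorm(1, spec$radiusMean, spec$radiusSd))
      fused <- stats::runif(1) < spec$fusionProb
      centers <- cbind(cx, cy)
      if (fused) {
        nSub <- sample(2:3, 1L)
        ang <- stats::runif(nSub, 0, 2 * pi)
        centers <- rbind(centers,
                         cbind(cx + 1.2 * r * cos(ang),
                               cy + 1.2 * r * sin(ang)))
      }
      coreCol <- if (spec$lumen) c(0.97, 0.97, 0.97) else spec$blob + 0.06
      for (ci in seq_len(nrow(centers))) {
        # draw only inside the circle's bounding box
        iLo <- max(1, floor(centers[ci, 1] - r))
        iHi <- min(size, ceiling(centers[ci, 1] + r))
        jLo <- max(1, floor(centers[ci, 2] - r))
        jHi <- min(size, ceiling(centers[ci, 2] + r))
        if (iLo > iHi || jLo > jHi) next
        ii <- iLo:iHi; jj <- jLo:jHi
        d <- sqrt(outer((ii - centers[ci, 1])^2, (jj - centers[ci, 2])^2,
                        "+"))
        rim <- d <= r & d > (r - 2.2)
        core <- d <= (r - 2.2)
        for (ch in 1:3) {
          sub <- img[ii, jj, ch]
          sub[rim] <- spec$blob[ch]
          sub[core] <- coreCol[ch]
          img[ii, jj, ch] <- sub
        }
      }
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

#' ISUP grade group from primary and secondary Gleason patterns
#'
#' Fixed standard grouping: benign (0+0) -> group 0; 3+3 -> 1; 3+4 -> 2;
#' 4+3 -> 3; 4+4, 3+5, 5+3 -> 4; 4+5, 5+4, 5+5 -> 5.
#'
#' @param primary,secondary Gleason patterns in \{0, 3, 4, 5\}; 0 only with 0.
#' @return integer grade group in 0:5.
#' @examples
#' gleasonToIsup(3, 4)  # 2
#' @export
gleasonToIsup <- function(primary, secondary) {
  ok <- c(0, 3, 4, 5)
  if (!(primary %in% ok) || !(secondary %in% ok))
    stop("Gleason patterns must be 0, 3, 4 or 5")
  if (xor(primary == 0, secondary == 0))
    stop("pattern 0 (benign) can only be paired with 0")
  key <- paste(primary, secondary, sep = "+")
  table <- c("0+0" = 0L, "3+3" = 1L, "3+4" = 2L, "4+3" = 3L,
             "4+4" = 4L, "3+5" = 4L, "5+3" = 4L,
             "4+5" = 5L, "5+4" = 5L, "5+5" = 5L)
  table[[key]]
}

# Gleason pattern (3/4/5) <-> pattern class index (2/3/4)
.gleasonToClass <- function(g) as.integer(g - 1L)
.classToGleason <- function(cl) as.integer(cl + 1L)

# pairs (primary, secondary) compatible with each group 1..5
.isupPairs <- list(
  `1` = list(c(3, 3)),
  `2` = list(c(3, 4)),
  `3` = list(c(4, 3)),
  `4` = list(c(4, 4), c(3, 5), c(5, 3)),
  `5` = list(c(4, 5), c(5, 4), c(5, 5)))

#' Generate a synthetic slide (bag of patches) with ground truth
#'
#' Samples a (primary, secondary) Gleason pair compatible with the requested
#' grade group, draws a malignant area fraction that grows with the group,
#' splits it between primary and secondary patterns (primary strictly more
#' prevalent when they differ), fills the rest with stroma and benign
#' epithelium, and assigns each of the \code{nPatches} patches a pattern.
#' Patch images are rendered lazily by [renderSlidePatches()] from per-patch
#' child seeds, so slides are cheap to hold in memory. Stored proportions
#' are exactly the empirical patch-label frequencies.
#'
#' @param isupGroup requested grade group in 0:5.
#' @param nPatches patches per slide (36 by default).
#' @param patchSize patch side length in pixels (64 by default).
#' @param seed integer seed; all slide randomness derives from it.
#' @param id optional slide identifier string.
#' @return object of class \code{SyntheticSlide}: a list with elements
#'   \code{id, isupGroup, primary, secondary, patterns} (0-based per-patch
#'   labels), \code{proportions} (named length-5 vector summing to 1),
#'   \code{nPatches, patchSize, seed, patchSeeds}.
#' @export
genSlide <- function(isupGroup, nPatches = 36L, patchSize = 64L, seed = 1L,
                     id = NULL) {
  if (!isupGroup %in% 0:5) stop("'isupGroup' must be in 0:5")
  rng <- .localRNG(childSeed(seed, 1L))
  on.exit(rng$restore())
  nPatches <- as.integer(nPatches)
  g <- as.integer(isupGroup)
  if (g == 0L) {
    primary <- 0L; secondary <- 0L
    nBenign <- round(nPatches * stats::rbeta(1, 2, 5))
    counts <- c(nPatches - nBenign, nBenign, 0L, 0L, 0L)
  } else {
    pairs <- .isupPairs[[as.character(g)]]
    pr <- pairs[[sample.int(length(pairs), 1L)]]
    primary <- as.integer(pr[1]); secondary <- as.integer(pr[2])
    mMean <- 0.35 + 0.06 * g
    phi <- 25
    mal <- stats::rbeta(1, mMean * phi, (1 - mMean) * phi)
    nMal <- max(if (primary == secondary) 2L else 3L, round(nPatches * mal))
    nMal <- min(nMal, nPatches - 1L)
    if (primary == secondary) {
      nP <- nMal; nS <- 0L
    } else {
      share <- stats::runif(1, 0.65, 0.85)
      nS <- max(1L, round(nMal * (1 - share)))
      nP <- nMal - nS
      if (nP <= nS) { nP <- nS + 1L; nMal <- nP + nS }
    }
    nBg <- nPatches - nMal
    nBenign <- round(nBg * stats::runif(1, 0.1, 0.5))
    counts <- integer(5)
    counts[1] <- nBg - nBenign
    counts[2] <- nBenign
    counts[.gleasonToClass(primary) + 1L] <- nP
    if (nS > 0L) counts[.gleasonToClass(secondary) + 1L] <- nS
  }
  stopifnot(sum(counts) == nPatches)
  patterns <- sample(rep.int(0:4, counts))
  structure(list(
    id = if (is.null(id)) sprintf("slide_g%d_s%d", g, as.integer(seed)) else id,
    isupGroup = g, primary = primary, secondary = secondary,
    patterns = as.integer(patterns),
    proportions = stats::setNames(counts / nPatches, .PATTERN_NAMES),
    nPatches = nPatches, patchSize = as.integer(patchSize),
    seed = as.integer(seed),
    patchSeeds = vapply(seq_len(nPatches), function(j)
      childSeed(seed, 1000L + j), integer(1))),
    class = "SyntheticSlide")
}

#' Recompute a slide's grade group from its stored patch labels
#'
#' Reads primary/secondary patterns off the per-pattern patch counts (the
#' most and second-most prevalent malignant patterns present) and maps them
#' through [gleasonToIsup()]; used to verify slide self-consistency.
#'
#' @param slide a \code{SyntheticSlide}.
#' @return integer grade group in 0:5.
#' @export
slideGroupFromPatterns <- function(slide) {
  counts <- tabulate(slide$patterns + 1L, nbins = 5L)
  malClasses <- which(counts[3:5] > 0) + 1L  # class indices 2:4
  if (length(malClasses) == 0L) return(0L)
  malCounts <- counts[malClasses + 1L]
  ord <- order(malCounts, decreasing = TRUE)
  primary <- .classToGleason(malClasses[ord[1]])
  secondary <- if (length(malClasses) > 1L)
    .classToGleason(malClasses[ord[2]]) else primary
  gleasonToIsup(primary, secondary)
}

#' Render all patch images of a slide
#'
#' @param slide a \code{SyntheticSlide} from [genSlide()].
#' @return list of \code{patchSize x patchSize x 3} arrays.
#' @export
renderSlidePatches <- function(slide) {
  lapply(seq_len(slide$nPatches), function(j)
    genPatch(patternSpec(slide$patterns[j]), slide$patchSize,
             slide$patchSeeds[j]))
}

#' Generate a slide-level dataset with disjoint splits
#'
#' Generates \code{nTrain + nVal + nTest} slides per grade group with
#' slide-level disjoint train/validation/test splits (each slide, hence each
#' patch, belongs to exactly one split). Both the weak bag labels and the
#' per-patch pattern labels are stored; supervised training and evaluation
#' may use the patch labels, weak training must only see the bag label.
#'
#' @param nTrain,nVal,nTest slides per group in each split.
#' @param nPatches patches per slide.
#' @param patchSize patch side length in pixels.
#' @param seed integer master seed.
#' @return list with elements \code{train}, \code{val}, \code{test}, each a
#'   list of \code{SyntheticSlide} objects.
#' @export
genDataset <- function(nTrain = 30L, nVal = 8L, nTest = 10L, nPatches = 36L,
                       patchSize = 64L, seed = 1L) {
  if (min(nTrain, nVal, nTest) < 1L) stop("each split needs >= 1 slide/group")
  splits <- list(train = nTrain, val = nVal, test = nTest)
  out <- list(); counter <- 0L
  for (sp in names(splits)) {
    slides <- list()
    for (g in 0:5) for (i in seq_len(splits[[sp]])) {
      counter <- counter + 1L
      slides[[length(slides) + 1L]] <-
        genSlide(g, nPatches, patchSize, seed = childSeed(seed, counter),
                 id = sprintf("%s_g%d_%03d", sp, g, i))
    }
    out[[sp]] <- slides
  }
  out
}

#' Generate a labeled patch dataset for fully supervised training
#'
#' Balanced patches over the five pattern classes, with disjoint
#' train/val/test splits; images are rendered lazily from stored seeds via
#' [renderPatchDataset()]. Each patch is rendered as a random-offset crop
#' from a larger canvas of its pattern, mirroring how patches are extracted
#' from slides (glands truncated at patch borders are the norm, not the
#' exception).
#'
#' @param nTrain,nVal,nTest patches per class in each split.
#' @param patchSize patch side length.
#' @param seed master seed.
#' @return list of splits; each split is a list with \code{labels} (0-based
#'   integer vector), \code{seeds}, \code{ids}, \code{patchSize}.
#' @export
genPatchDataset <- function(nTrain = 200L, nVal = 50L, nTest = 60L,
                            patchSize = 64L, seed = 1L) {
  splits <- list(train = nTrain, val = nVal, test = nTest)
  out <- list(); counter <- 0L
  for (sp in names(splits)) {
    n <- splits[[sp]]
    labels <- rep(0:4, each = n)
    seeds <- integer(length(labels))
    for (i in seq_along(labels)) {
      counter <- counter + 1L
      seeds[i] <- childSeed(seed, 50000L + counter)
    }
    out[[sp]] <- list(labels = as.integer(labels), seeds = seeds,
                      ids = sprintf("%s_c%d_%03d", sp, labels,
                                    sequence(rep(n, 5L))),
                      patchSize = as.integer(patchSize))
  }
  out
}

#' Render the images of a patch dataset split
#'
#' Each image is a random-offset crop (determined by the patch's stored
#' seed) from a canvas \code{patchSize + 32} pixels wide rendered with the
#' patch's pattern.
#'
#' @param split one split from [genPatchDataset()].
#' @return list of image arrays aligned with \code{split$labels}.
#' @export
renderPatchDataset <- function(split) {
  lapply(seq_along(split$labels), function(i)
    .renderCroppedPatch(split$labels[i], split$patchSize, split$seeds[i]))
}

# render a (size + margin) canvas and crop `size` at a seed-determined offset
.renderCroppedPatch <- function(classIndex, size, seed, margin = 32L) {
  canvas <- genPatch(patternSpec(classIndex), size + margin, seed)
  rng <- .localRNG(childSeed(seed, 2L))
  on.exit(rng$restore())
  r0 <- sample.int(margin + 1L, 1L) - 1L
  c0 <- sample.int(margin + 1L, 1L) - 1L
  canvas[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}

#' @export
print.SyntheticSlide <- function(x, ...) {
  cat("SyntheticSlide", x$id, ": ISUP group", x$isupGroup,
      sprintf("(Gleason %d+%d),", x$primary, x$secondary),
      x$nPatches, "patches\n")
  print(round(x$proportions, 3))
  invisible(x)
}
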