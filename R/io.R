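# Serialization: model checkpoints as JSON, prediction tables as CSV,
# per-tile maps as PNG heatmaps.

#' Save a model to a JSON checkpoint
#'
#' Stores the joint KDM (components, label encodings, weights,
#' log-bandwidth), encoder parameters, attention parameters, configuration
#' and the initialization registry as a single JSON document. Arrays are
#' written at full double precision so a round trip is lossless to within
#' JSON number formatting.
#'
#' @param model a \linkS4class{KdmModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
saveKdmModel <- function(model, path) {
  enc <- model@encoder
  payload <- list(
    format = "kdmil-model", version = 1L,
    task = model@task,
    config = model@config,
    joint = list(
      xComponents = model@joint@xComponents,
      yComponents = model@joint@yComponents,
      probs = model@joint@probs,
      logBandwidth = model@joint@kernel@logBandwidth,
      dim = model@joint@kernel@dim),
    encoder = enc,
    attention = model@attention,
    registry = model@registry,
    trainingLog = model@trainingLog)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model from a JSON checkpoint
#'
#' @param path file written by [saveKdmModel()].
#' @return a \linkS4class{KdmModel}.
#' @export
readKdmModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "kdmil-model"))
    stop("not a kdmil model checkpoint")
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))   # rowmajor lists
  joint <- JointKDM(mat(p$joint$xComponents), mat(p$joint$yComponents),
                    num(p$joint$probs),
                    new("KernelParams",
                        logBandwidth = num(p$joint$logBandwidth),
                        dim = as.integer(p$joint$dim)))
  enc <- p$encoder
  if (identical(enc$type, "conv")) {
    enc$layers <- lapply(enc$layers, function(l) {
      list(offsets = lapply(l$offsets, function(o) as.integer(unlist(o))),
           outH = as.integer(l$outH), outW = as.integer(l$outW),
           C = as.integer(l$C), K = as.integer(l$K), P = as.integer(l$P),
           Cout = as.integer(l$Cout), W = lapply(l$W, mat))
    })
    enc$We <- mat(p$encoder$We); enc$be <- num(p$encoder$be)
    enc$inputSize <- as.integer(enc$inputSize)
    enc$dFixed <- as.integer(enc$dFixed); enc$dOut <- as.integer(enc$dOut)
  } else {
    enc$d <- as.integer(enc$d); enc$dFixed <- as.integer(enc$dFixed)
    enc$dOut <- as.integer(enc$dOut)
  }
  attn <- p$attention
  if (length(attn)) {
    attn <- list(type = attn$type, d = as.integer(attn$d),
                 hidden = as.integer(attn$hidden),
                 W1 = mat(attn$W1), b1 = num(attn$b1),
                 W2 = mat(attn$W2), b2 = num(attn$b2),
                 w3 = num(attn$w3), b3 = num(attn$b3))
  }
  cfg <- lapply(p$config, function(x) if (is.list(x)) unlist(x) else x)
  intFields <- c("nClasses", "perClass", "mPrototypes", "warmupEpochs",
                 "batchBags", "batchPatches", "maxEpochs", "patience",
                 "encoderWarmupEpochs", "seed")
  for (f in intFields) if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  asDf <- function(x) {
    if (!length(x)) return(data.frame())
    do.call(rbind, lapply(x, function(row)
      as.data.frame(row, stringsAsFactors = FALSE)))
  }
  new("KdmModel", encoder = enc,
      attention = if (length(attn)) attn else list(),
      joint = joint, config = cfg,
      registry = asDf(p$registry),
      task = p$task,
      trainingLog = asDf(p$trainingLog))
}

#' Export predictions as CSV
#'
#' Writes id, expected, variance, class index and (when a threshold is
#' given) the retained flag of the variance filter.
#'
#' @param predictions data.frame from [predictBags()].
#' @param path output CSV path.
#' @param varianceThreshold optional threshold for the retained flag.
#' @return \code{path}, invisibly.
#' @export
exportPredictions <- function(predictions, path, varianceThreshold = NULL) {
  out <- predictions
  if (!is.null(varianceThreshold))
    out$retained <- predictions$variance < varianceThreshold
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-tile map as a PNG heatmap
#'
#' Renders one of a slide report's tile maps with a simple color ramp
#' (viridis-like for continuous maps, categorical for the class map).
#'
#' @param report a \code{SlideReport} from [slideReport()].
#' @param path output PNG path.
#' @param what "class", "expected" or "variance".
#' @return \code{path}, invisibly.
#' @export
writeHeatmapPng <- function(report, path,
                            what = c("variance", "expected", "class")) {
  what <- match.arg(what)
  M <- switch(what, class = report$classMap, expected = report$expectedMap,
              variance = report$varianceMap)
  if (what == "class") {
    pal <- rbind(c(0.90, 0.90, 0.90), c(0.55, 0.77, 0.55),
                 c(1.00, 0.85, 0.30), c(0.95, 0.55, 0.15),
                 c(0.85, 0.10, 0.10), c(0.45, 0.00, 0.20))
    idx <- as.integer(M) + 1L
    idx[idx > nrow(pal)] <- nrow(pal)
    img <- array(0, c(nrow(M), ncol(M), 3L))
    for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], nrow(M))
  } else {
    rng <- range(M)
    t <- if (diff(rng) > 0) (M - rng[1]) / diff(rng) else M * 0
    img <- array(0, c(nrow(M), ncol(M), 3L))
    img[, , 1] <- t
    img[, , 2] <- 0.2 + 0.3 * t
    img[, , 3] <- 1 - t
  }
  png::writePNG(img, path)
  invisible(path)
}
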