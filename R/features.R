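#' Preprocess an image for feature extraction
#'
#' Resizes to \code{targetSize} square (bilinear), replicates grayscale to 3
#' channels when per-channel means are given, and subtracts the channel
#' means.  With the default means (the RGB dataset means 123.68, 116.78,
#' 103.94) the output is a centred \code{H x W x 3} array that may leave
#' \code{[0, 255]}.
#'
#' @param image grayscale matrix or RGB array
#' @param targetSize output side length in pixels (>= 8)
#' @param channelMeans numeric: a single mean, or one per channel
#' @return preprocessed array (\code{H x W} or \code{H x W x 3})
#' @export
preprocessImage <- function(image, targetSize = 224L,
                            channelMeans = c(123.68, 116.78, 103.94)) {
  stopifnot(targetSize >= 8)
  if (any(!is.finite(image))) stop("non-finite input image")
  resize1 <- function(m) {
    if (nrow(m) == targetSize && ncol(m) == targetSize) return(m)
    EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                       w = targetSize, h = targetSize))
  }
  nch <- length(channelMeans)
  if (is.matrix(image)) {
    m <- resize1(image)
    if (nch == 1L) return(m - channelMeans)
    image <- array(rep(m, nch), c(dim(m), nch))
  } else {
    image <- array(apply(image, 3, resize1),
                   c(targetSize, targetSize, dim(image)[3]))
  }
  for (ch in seq_len(dim(image)[3]))
    image[, , ch] <- image[, , ch] - channelMeans[min(ch, nch)]
  image
}

## ---------------------------------------------------------------------------
## Extractor contract: a list of class "perceptExtractor" with elements
##   id      - character identifier
##   layers  - data.frame(index, name, kind)
##   forward - function(image, metaRow) -> list of per-layer numeric vectors
## Surrogate extractors read metaRow (stimulus tags) instead of pixels.

.newExtractor <- function(id, layers, forward) {
  structure(list(id = id, layers = layers, forward = forward),
            class = "perceptExtractor")
}

#' @export
print.perceptExtractor <- function(x, ...) {
  cat(sprintf("<perceptExtractor '%s': %d layers (%s)>\n", x$id,
              nrow(x$layers), paste(x$layers$kind, collapse = " ")))
  invisible(x)
}

.layerDf <- function(names, kinds)
  data.frame(index = seq_along(names) - 1L, name = names, kind = kinds,
             stringsAsFactors = FALSE)

#' Pixel feature extractor
#'
#' A single input layer whose activation vector is the row-major flattened
#' intensity grid, i.e. a pixel-like representation where each unit's
#' activation is proportional to the brightness of one pixel.
#'
#' @return an extractor usable with [extractFeatures()]
#' @export
pixelExtractor <- function() {
  .newExtractor("pixel", .layerDf("pixels", "input"),
                function(image, metaRow) {
                  if (is.matrix(image)) list(as.vector(t(image)))
                  else list(as.vector(aperm(image, c(3, 2, 1))))
                })
}

#' Seeded random convolutional network extractor
#'
#' A fixed small feedforward architecture -- three conv / relu / maxpool
#' blocks followed by two fully connected layers with an interposed relu --
#' with untrained weights drawn once from a zero-mean Gaussian with
#' fan-in scaling (sd = 1/sqrt(fan-in), biases 0) under the given seed.
#' Inputs are converted to grayscale, resized to \code{inputSize} and scaled
#' to roughly unit range.  Two instances with the same seed produce identical
#' activations on any image.
#'
#' @param seed integer seed for the weights
#' @param widthScale positive multiplier on all channel/unit counts
#' @param inputSize side length the input is resized to
#' @return an extractor usable with [extractFeatures()]
#' @export
referenceConvnet <- function(seed = 1L, widthScale = 1, inputSize = 64L) {
  stopifnot(widthScale > 0)
  cw <- pmax(1L, round(c(4, 8, 16) * widthScale))
  fw <- pmax(1L, round(c(32, 16) * widthScale))
  poolDim <- inputSize %/% 8L
  fcIn <- poolDim^2 * cw[3]
  withr::with_seed(seed, {
    Wc <- list(array(rnorm(9 * 1 * cw[1], sd = 1 / sqrt(9 * 1)), c(3, 3, 1, cw[1])),
               array(rnorm(9 * cw[1] * cw[2], sd = 1 / sqrt(9 * cw[1])),
                     c(3, 3, cw[1], cw[2])),
               array(rnorm(9 * cw[2] * cw[3], sd = 1 / sqrt(9 * cw[2])),
                     c(3, 3, cw[2], cw[3])))
    Wf <- list(matrix(rnorm(fcIn * fw[1], sd = 1 / sqrt(fcIn)), fcIn, fw[1]),
               matrix(rnorm(fw[1] * fw[2], sd = 1 / sqrt(fw[1])), fw[1], fw[2]))
  })
  layers <- .layerDf(
    c("input", "conv1", "relu1", "pool1", "conv2", "relu2", "pool2",
      "conv3", "relu3", "pool3", "fc1", "relu4", "fc2"),
    c("input", "conv", "relu", "pool", "conv", "relu", "pool",
      "conv", "relu", "pool", "fc", "relu", "fc"))
  forward <- function(image, metaRow) {
    if (!is.matrix(image)) image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
    if (nrow(image) != inputSize || ncol(image) != inputSize)
      image <- EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                                  w = inputSize, h = inputSize))
    x <- array(image / 255 - 0.5, c(inputSize, inputSize, 1))
    acts <- list(as.vector(x))
    for (b in 1:3) {
      x <- .conv2same(x, Wc[[b]])
      acts[[length(acts) + 1L]] <- as.vector(x)
      x <- pmax(x, 0)
      acts[[length(acts) + 1L]] <- as.vector(x)
      x <- .maxpool2(x)
      acts[[length(acts) + 1L]] <- as.vector(x)
    }
    v <- as.vector(x) %*% Wf[[1]]
    acts[[length(acts) + 1L]] <- as.vector(v)
    v <- pmax(v, 0)
    acts[[length(acts) + 1L]] <- as.vector(v)
    v <- v %*% Wf[[2]]
    acts[[length(acts) + 1L]] <- as.vector(v)
    acts
  }
  .newExtractor(sprintf("refnet(seed=%d,width=%g)", seed, widthScale),
                layers, forward)
}

## 3x3 same-padding convolution, x: H x W x Cin, Wf: 3 x 3 x Cin x Cout.
.conv2same <- function(x, Wf) {
  H <- dim(x)[1]; W <- dim(x)[2]
  Cin <- dim(x)[3]; Cout <- dim(Wf)[4]
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    acc <- matrix(0, H, W)
    for (ci in seq_len(Cin)) for (di in 0:2) for (dj in 0:2)
      acc <- acc + Wf[di + 1, dj + 1, ci, co] *
        xp[(1 + di):(H + di), (1 + dj):(W + dj), ci]
    out[, , co] <- acc
  }
  out
}

## 2x2 max pooling, stride 2 (trailing odd row/col dropped).
.maxpool2 <- function(x) {
  H2 <- dim(x)[1] %/% 2L; W2 <- dim(x)[2] %/% 2L
  i1 <- seq_len(H2) * 2L - 1L; j1 <- seq_len(W2) * 2L - 1L
  pmax(x[i1, j1, , drop = FALSE], x[i1 + 1L, j1, , drop = FALSE],
       x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE])
}

#' Analytic surrogate extractors
#'
#' Surrogates realise a declared response law exactly by reading stimulus
#' meta tags rather than pixels, providing closed-form oracles for the index
#' procedures.  All emit a single designated \code{fc} layer.
#'
#' Kinds and the meta tags they require:
#' \describe{
#'   \item{averager / summer}{multi-object displays
#'     (\code{obj_at_loc1..3}): each unit has a seeded base response to every
#'     (object, location) singleton; the response to any display is the mean
#'     (respectively sum) of the constituent singleton responses.}
#'   \item{length_linear / length_log}{bars (\code{length}): one unit per
#'     gain, responding \code{gain * L} or \code{gain * log(L)}.}
#'   \item{global_only / local_only}{hierarchical stimuli (\code{g} /
#'     \code{l}): a seeded random vector per tag level, identical for
#'     stimuli sharing the tag.}
#'   \item{size_ratio / size_sum}{size tetrads (\code{scale1},
#'     \code{scale2}): units respond \code{gain * scale1/scale2}
#'     (respectively \code{gain * (scale1 + scale2)}).}
#' }
#'
#' @param kind surrogate kind (see Details)
#' @param params list of surrogate parameters: \code{nUnits}, \code{seed},
#'   \code{nObjects} (averager/summer), \code{gains} (length/size kinds),
#'   \code{nLevels} (global/local)
#' @return an extractor usable with [extractFeatures()]
#' @export
surrogateExtractor <- function(kind, params = list()) {
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  seed <- p("seed", 1L)
  layers <- .layerDf("surrogate_fc", "fc")
  need <- function(metaRow, cols) {
    miss <- setdiff(cols, names(metaRow))
    if (length(miss))
      stop(sprintf("surrogate '%s' requires meta tag(s): %s", kind,
                   paste(miss, collapse = ", ")))
  }
  forward <- switch(kind,
    averager = , summer = {
      nUnits <- p("nUnits", 32L); nObjects <- p("nObjects", 49L)
      base <- withr::with_seed(seed,
        array(runif(nObjects * 3 * nUnits), c(nObjects, 3, nUnits)))
      agg <- if (kind == "averager") function(m) colMeans(m) else function(m) colSums(m)
      function(image, metaRow) {
        need(metaRow, c("obj_at_loc1", "obj_at_loc2", "obj_at_loc3"))
        objs <- unlist(metaRow[c("obj_at_loc1", "obj_at_loc2", "obj_at_loc3")])
        occ <- which(!is.na(objs))
        resp <- t(vapply(occ, function(l) base[objs[l], l, ], numeric(nUnits)))
        list(agg(resp))
      }
    },
    length_linear = {
      gains <- p("gains", 1)
      function(image, metaRow) {
        need(metaRow, "length")
        list(gains * metaRow$length)
      }
    },
    length_log = {
      gains <- p("gains", 1)
      function(image, metaRow) {
        need(metaRow, "length")
        list(gains * log(metaRow$length))
      }
    },
    global_only = , local_only = {
      nUnits <- p("nUnits", 16L); nLevels <- p("nLevels", 7L)
      tab <- withr::with_seed(seed, matrix(runif(nLevels * nUnits), nLevels, nUnits))
      tag <- if (kind == "global_only") "g" else "l"
      function(image, metaRow) {
        need(metaRow, tag)
        list(tab[metaRow[[tag]], ])
      }
    },
    size_ratio = {
      gains <- p("gains", seq(0.5, 1.5, length.out = p("nUnits", 8L)))
      function(image, metaRow) {
        need(metaRow, c("scale1", "scale2"))
        list(gains * metaRow$scale1 / metaRow$scale2)
      }
    },
    size_sum = {
      gains <- p("gains", seq(0.5, 1.5, length.out = p("nUnits", 8L)))
      function(image, metaRow) {
        need(metaRow, c("scale1", "scale2"))
        list(gains * (metaRow$scale1 + metaRow$scale2))
      }
    },
    stop("unrecognized surrogate kind: ", kind))
  .newExtractor(paste0("surrogate:", kind), layers, forward)
}

#' Class probabilities from a context-sensitive surrogate classifier
#'
#' Emits one probability vector over \code{nClasses} labels per stimulus:
#' seeded random positive scores, with the score of the stimulus's
#' ground-truth \code{label} multiplied by a boost that is larger for
#' congruent than for incongruent scenes, then normalized to sum to 1.
#'
#' @param stimuli a scene \linkS4class{StimulusSet} (meta columns
#'   \code{label}, \code{role})
#' @param nClasses number of class labels (>= max label)
#' @param congruentBoost,incongruentBoost multiplicative score boosts
#' @param seed integer seed
#' @return matrix (stimuli x classes) of probabilities
#' @export
contextClassifierProbs <- function(stimuli, nClasses = 1000L,
                                   congruentBoost = 50, incongruentBoost = 5,
                                   seed = 1L) {
  meta <- stimMeta(stimuli)
  if (!all(c("label", "role") %in% colnames(meta)))
    stop("context classifier requires meta tags: label, role")
  n <- nStimuli(stimuli)
  if (max(meta$label) > nClasses) stop("labels exceed class count")
  withr::with_seed(seed, {
    scores <- matrix(runif(n * nClasses, 0.01, 1), n, nClasses)
  })
  for (i in seq_len(n)) {
    boost <- switch(meta$role[i], congruent = congruentBoost,
                    incongruent = incongruentBoost, 1)
    scores[i, meta$label[i]] <- scores[i, meta$label[i]] * boost
  }
  probs <- scores / rowSums(scores)
  probs
}

#' Extract layer-wise activations for a stimulus set
#'
#' Runs the extractor on every stimulus and assembles per-layer
#' stimuli-by-unit matrices.  Per-layer dimensions must be constant across
#' stimuli; a mismatch raises an error naming the layer.  An empty stimulus
#' set yields an empty table with the layer list preserved.
#'
#' @param extractor an extractor from [pixelExtractor()],
#'   [referenceConvnet()], [surrogateExtractor()] or a user-supplied adapter
#'   obeying the same contract (fields \code{id}, \code{layers},
#'   \code{forward(image, metaRow)})
#' @param stimuli a \linkS4class{StimulusSet}
#' @return an \linkS4class{ActivationTable}
#' @export
extractFeatures <- function(extractor, stimuli) {
  stopifnot(inherits(extractor, "perceptExtractor") ||
              (is.list(extractor) && is.function(extractor$forward)))
  n <- nStimuli(stimuli)
  nl <- nrow(extractor$layers)
  meta <- stimMeta(stimuli)
  if (n == 0L) {
    acts <- replicate(nl, matrix(numeric(0), 0, 0), simplify = FALSE)
    return(ActivationTable(extractor$layers, acts, character(0)))
  }
  perStim <- vector("list", n)
  for (i in seq_len(n)) {
    out <- extractor$forward(images(stimuli)[[i]], meta[i, , drop = FALSE])
    if (length(out) != nl) stop("extractor returned wrong number of layers")
    perStim[[i]] <- lapply(out, as.numeric)
  }
  acts <- vector("list", nl)
  for (l in seq_len(nl)) {
    dims <- vapply(perStim, function(s) length(s[[l]]), integer(1))
    if (any(dims != dims[1]))
      stop(sprintf("dimension mismatch across stimuli in layer '%s'",
                   extractor$layers$name[l]))
    acts[[l]] <- do.call(rbind, lapply(perStim, `[[`, l))
  }
  ActivationTable(extractor$layers, acts, as.character(seq_len(n)))
}
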