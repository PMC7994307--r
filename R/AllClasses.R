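#' perceptBattery: distance-based perceptual property indices for layered
#' visual feature representations
#'
#' The package generates synthetic stimulus families, extracts layer-wise
#' activation vectors through pluggable feature extractors, and computes
#' twelve normalized distance-contrast indices of perceptual and neural
#' properties, together with a part-sum linear dissimilarity model and an
#' orchestration battery with per-layer reports and presence verdicts.
#'
#' @import methods
#' @importFrom stats cor dist as.dist lm coef sd var rnorm runif quantile setNames
#' @importFrom utils combn head
#' @include AllGenerics.R
#' @keywords internal
"_PACKAGE"

## ---------------------------------------------------------------------------
## Images are plain numeric matrices (grayscale, H x W, top-left origin) or
## H x W x 3 arrays (RGB), with intensities in [0, 255].  They deliberately
## stay base-R arrays; the S4 layer starts at the set level.

.validImage <- function(img) {
  if (!is.numeric(img)) return("image must be numeric")
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    return("image must be an H x W matrix or H x W x 3 array")
  if (length(d) == 3L && d[3] != 3L)
    return("3D image arrays must have exactly 3 channels")
  if (d[1] < 8L || d[2] < 8L) return("image must be at least 8 x 8")
  if (any(!is.finite(img))) return("image contains non-finite values")
  if (min(img) < 0 || max(img) > 255)
    return("image intensities must lie in [0, 255]")
  TRUE
}

#' StimulusSet: an ordered collection of raster stimuli with tags
#'
#' A \code{StimulusSet} holds an ordered list of grayscale raster images
#' (numeric matrices, intensities in \code{[0, 255]}, row 1 at the top)
#' together with one metadata row per image (experiment-specific tags such as
#' face id, mirror role, bar length or tetrad cell) and the integer seed the
#' set was generated from.  All generators in the package are pure functions
#' of their parameters and seed: regenerating with the same arguments
#' reproduces bit-identical pixels.
#'
#' @slot images list of numeric matrices (or \code{H x W x 3} arrays), all of
#'   equal dimensions within a set
#' @slot meta \code{data.frame} with one row per image
#' @slot seed integer scalar used for generation
#'
#' @seealso [makeFaces()], [makeMirrorSet()], [makeHierarchicalStimuli()] and
#'   the other \code{make*} generators; [extractFeatures()]
#' @export
setClass("StimulusSet",
  representation(images = "list", meta = "data.frame", seed = "integer"))

setValidity("StimulusSet", function(object) {
  if (length(object@images) != nrow(object@meta))
    return("images and meta must have equal length")
  if (length(object@seed) != 1L) return("seed must be a single integer")
  if (length(object@images)) {
    msgs <- vapply(object@images, function(im) {
      v <- .validImage(im)
      if (isTRUE(v)) "" else v
    }, character(1))
    bad <- which(nzchar(msgs))
    if (length(bad))
      return(sprintf("image %d invalid: %s", bad[1], msgs[bad[1]]))
    dims <- vapply(object@images, function(im) dim(im)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all images in a set must share dimensions")
  }
  TRUE
})

#' Construct a StimulusSet
#'
#' @param images list of images (numeric matrices in \code{[0, 255]})
#' @param meta \code{data.frame} of per-image tags, one row per image
#' @param seed integer seed recorded as provenance
#' @return a \linkS4class{StimulusSet}
#' @export
StimulusSet <- function(images, meta, seed = NA_integer_) {
  rownames(meta) <- NULL
  new("StimulusSet", images = images, meta = meta, seed = as.integer(seed))
}

#' @rdname accessors
#' @export
setMethod("images", "StimulusSet", function(x, ...) x@images)

#' @rdname accessors
#' @export
setMethod("stimMeta", "StimulusSet", function(x, ...) x@meta)

#' @rdname accessors
#' @export
setMethod("stimSeed", "StimulusSet", function(x, ...) x@seed)

#' @rdname accessors
#' @export
setMethod("nStimuli", "StimulusSet", function(x) length(x@images))

#' @describeIn StimulusSet number of stimuli
#' @param x a \code{StimulusSet}
#' @export
setMethod("length", "StimulusSet", function(x) length(x@images))

#' @describeIn StimulusSet subset by index, keeping images and meta aligned
#' @param i index vector
#' @param j,...,drop ignored
#' @export
setMethod("[", "StimulusSet", function(x, i, j, ..., drop = FALSE) {
  StimulusSet(x@images[i], x@meta[i, , drop = FALSE], x@seed)
})

setMethod("show", "StimulusSet", function(object) {
  d <- if (length(object@images)) dim(object@images[[1]]) else c(NA, NA)
  cat(sprintf("StimulusSet with %d images (%s x %s), seed %s\n",
              length(object@images), d[1], d[2], object@seed))
  cat("meta columns:", paste(colnames(object@meta), collapse = ", "), "\n")
})

#' Combine stimulus sets sharing image dimensions
#'
#' Metadata columns are unioned; missing tags become \code{NA}.
#'
#' @param ... \code{StimulusSet} objects
#' @return a single \linkS4class{StimulusSet}
#' @export
combineStimulusSets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  cols <- unique(unlist(lapply(sets, function(s) colnames(s@meta))))
  metas <- lapply(sets, function(s) {
    m <- s@meta
    for (cn in setdiff(cols, colnames(m))) m[[cn]] <- NA
    m[, cols, drop = FALSE]
  })
  StimulusSet(do.call(c, lapply(sets, images)),
              do.call(rbind, metas), sets[[1]]@seed)
}

## ---------------------------------------------------------------------------

#' ActivationTable: layer-wise unit responses for a stimulus set
#'
#' For each layer of an extractor, an \code{ActivationTable} stores a numeric
#' matrix with one row per stimulus and one column per unit.  The layer table
#' records index (0-based, contiguous), name and kind (one of \code{input},
#' \code{conv}, \code{relu}, \code{pool}, \code{fc}, \code{softmax}).
#'
#' @slot layers \code{data.frame} with columns \code{index}, \code{name},
#'   \code{kind}
#' @slot activations list of numeric matrices, one per layer, rows aligned to
#'   the stimulus set
#' @slot stimulusIds character vector of stimulus identifiers
#'
#' @seealso [extractFeatures()]
#' @export
setClass("ActivationTable",
  representation(layers = "data.frame", activations = "list",
                 stimulusIds = "character"))

setValidity("ActivationTable", function(object) {
  ly <- object@layers
  if (!all(c("index", "name", "kind") %in% colnames(ly)))
    return("layers must have columns index, name, kind")
  if (nrow(ly) != length(object@activations))
    return("one activation matrix per layer required")
  if (nrow(ly) && !identical(as.integer(ly$index), seq_len(nrow(ly)) - 1L))
    return("layer indices must be contiguous from 0")
  ok <- ly$kind %in% c("input", "conv", "relu", "pool", "fc", "softmax")
  if (!all(ok)) return("unknown layer kind")
  for (k in seq_along(object@activations)) {
    a <- object@activations[[k]]
    if (!is.matrix(a)) return(sprintf("layer %d: activations must be a matrix", k))
    if (nrow(a) != length(object@stimulusIds))
      return(sprintf("layer %d: row count does not match stimuli", k))
    if (length(a) && any(!is.finite(a)))
      return(sprintf("layer %d: non-finite activations", k))
  }
  TRUE
})

#' Construct an ActivationTable
#'
#' @param layers layer \code{data.frame} (\code{index}, \code{name},
#'   \code{kind})
#' @param activations list of stimuli-by-unit matrices, one per layer
#' @param stimulusIds character ids, one per stimulus
#' @return an \linkS4class{ActivationTable}
#' @export
ActivationTable <- function(layers, activations, stimulusIds) {
  rownames(layers) <- NULL
  new("ActivationTable", layers = layers, activations = activations,
      stimulusIds = as.character(stimulusIds))
}

#' @rdname accessors
#' @export
setMethod("layerInfo", "ActivationTable", function(x, ...) x@layers)

#' @rdname accessors
#' @export
setMethod("layerActivations", "ActivationTable", function(x, layer, ...) {
  if (is.character(layer)) layer <- match(layer, x@layers$name)
  x@activations[[layer]]
})

#' @rdname accessors
#' @export
setMethod("nStimuli", "ActivationTable", function(x) length(x@stimulusIds))

#' @rdname accessors
#' @export
setMethod("nLayers", "ActivationTable", function(x) nrow(x@layers))

setMethod("show", "ActivationTable", function(object) {
  cat(sprintf("ActivationTable: %d stimuli x %d layers\n",
              length(object@stimulusIds), nrow(object@layers)))
  if (nrow(object@layers)) {
    dims <- vapply(object@activations, ncol, integer(1))
    cat(paste0(sprintf("  [%d] %s (%s): %d units", object@layers$index,
                       object@layers$name, object@layers$kind, dims),
               collapse = "\n"), "\n")
  }
})

## ---------------------------------------------------------------------------

#' PartSumDesign: incidence design of the part-sum dissimilarity model
#'
#' Rows index unordered pairs of two-part objects; the 3 * choose(p, 2) + 1
#' columns are corresponding-part terms (\code{C_i_j}), across-location terms
#' (\code{X_i_j}), within-object terms (\code{W_i_j}) and a constant.  For 49
#' objects built from 7 parts the system has 1176 rows and 64 columns.
#'
#' @slot design numeric incidence matrix with labelled columns
#' @slot pairs \code{data.frame} with the object indices of each row
#' @slot objects two-column matrix of part labels (location 1, location 2)
#' @slot partCount integer number of distinct parts
#' @export
setClass("PartSumDesign",
  representation(design = "matrix", pairs = "data.frame",
                 objects = "matrix", partCount = "integer"))

setValidity("PartSumDesign", function(object) {
  p <- object@partCount
  if (ncol(object@design) != 3L * choose(p, 2) + 1L)
    return("design must have 3*choose(p,2) + 1 columns")
  if (nrow(object@design) != nrow(object@pairs))
    return("one pair per design row required")
  TRUE
})

#' PartSumFit: a fitted part-sum dissimilarity model
#'
#' @slot coefficients named coefficient vector (C/X/W terms plus constant)
#' @slot predicted model-predicted dissimilarity per design row
#' @slot residuals observed minus predicted
#' @slot rankDeficient \code{TRUE} when the normal equations were singular and
#'   the minimum-norm solution was returned
#' @export
setClass("PartSumFit",
  representation(coefficients = "numeric", predicted = "numeric",
                 residuals = "numeric", rankDeficient = "logical"))

setMethod("show", "PartSumFit", function(object) {
  cat(sprintf("PartSumFit: %d coefficients, %d pairs, RMSE %.4g%s\n",
              length(object@coefficients), length(object@predicted),
              sqrt(mean(object@residuals^2)),
              if (object@rankDeficient) " (rank-deficient, minimum-norm)" else ""))
})

## ---------------------------------------------------------------------------

#' BatteryReport: results of a battery run
#'
#' @slot results tidy per-(experiment, layer) index table
#' @slot verdicts one presence verdict per requested experiment
#' @slot config the configuration list the run was produced from
#' @slot provenance list with config hash, seed and package version
#' @export
setClass("BatteryReport",
  representation(results = "data.frame", verdicts = "data.frame",
                 config = "list", provenance = "list"))

setMethod("show", "BatteryReport", function(object) {
  cat(sprintf("BatteryReport: %d experiments, %d result rows\n",
              nrow(object@verdicts), nrow(object@results)))
  print(object@verdicts)
})
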