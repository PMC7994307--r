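#' Accessor generics
#'
#' Accessors for the core containers: \code{images} returns the list of raster
#' images in a \linkS4class{StimulusSet}, \code{stimMeta} its per-image tag
#' table, \code{stimSeed} its generating seed; \code{layerInfo} returns the
#' layer table of an \linkS4class{ActivationTable} and
#' \code{layerActivations} one layer's stimuli-by-unit matrix.
#'
#' @param x object
#' @param ... further arguments for methods
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("images", function(x, ...) standardGeneric("images"))

#' @rdname accessors
#' @export
setGeneric("stimMeta", function(x, ...) standardGeneric("stimMeta"))

#' @rdname accessors
#' @export
setGeneric("stimSeed", function(x, ...) standardGeneric("stimSeed"))

#' @rdname accessors
#' @export
setGeneric("layerInfo", function(x, ...) standardGeneric("layerInfo"))

#' @rdname accessors
#' @export
setGeneric("layerActivations", function(x, layer, ...)
  standardGeneric("layerActivations"))

#' @rdname accessors
#' @export
setGeneric("nStimuli", function(x) standardGeneric("nStimuli"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
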