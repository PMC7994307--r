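#' Reference shapes, morphlines, textures and silhouettes
#'
#' Generates the four stimulus subsets used for selectivity analyses:
#' \itemize{
#'   \item 8 reference silhouettes drawn from closed radial-contour templates;
#'   \item 4 morphlines between consecutive reference pairs, obtained by
#'     linear interpolation of the contour parameters at \code{nSteps}
#'     equally spaced morph parameters including both endpoints (parameter 0
#'     reproduces endpoint A bit-identically);
#'   \item \code{nTextures} band-pass filtered noise textures;
#'   \item \code{nSilhouettes} random radial silhouettes.
#' }
#'
#' @param seed integer seed
#' @param size canvas size in pixels
#' @param nTextures,nSilhouettes subset sizes (defaults 128 each)
#' @param nSteps images per morphline including endpoints (default 7, i.e.
#'   5 intermediate steps)
#' @return a \linkS4class{StimulusSet} with meta columns \code{subset}
#'   (\code{reference}, \code{morph}, \code{texture}, \code{shape}),
#'   \code{shape_id}, \code{morphline}, \code{alpha}
#' @export
makeShapeSets <- function(seed = 1L, size = 224L, nTextures = 128L,
                          nSilhouettes = 128L, nSteps = 7L) {
  stopifnot(nSteps >= 5)
  withr::with_seed(seed, {
    refShapes <- lapply(1:8, function(i)
      .randomRadialShape(0.30 * size, kmax = 5L, amp = 0.32))
    texImgs <- lapply(seq_len(nTextures), function(i)
      .noiseTexture(size, 1 + (i %% 3), 4 + (i %% 5)))
    silShapes <- lapply(seq_len(nSilhouettes), function(i)
      .randomRadialShape(0.28 * size, kmax = 5L, amp = 0.32))
  })
  renderShape <- function(sh) {
    img <- .canvas(size)
    .paintMask(img, .radialMask(img, 0.5 * size, 0.5 * size, sh), 255)
  }
  imgs <- list(); rows <- list(); k <- 0L
  add <- function(img, subset, shape_id = NA, morphline = NA, alpha = NA) {
    k <<- k + 1L
    imgs[[k]] <<- img
    rows[[k]] <<- data.frame(subset = subset, shape_id = shape_id,
                             morphline = morphline, alpha = alpha,
                             stringsAsFactors = FALSE)
  }
  for (i in 1:8) add(renderShape(refShapes[[i]]), "reference", shape_id = i)
  alphas <- seq(0, 1, length.out = nSteps)
  for (m in 1:4) {
    a <- refShapes[[2 * m - 1]]; b <- refShapes[[2 * m]]
    for (al in alphas)
      add(renderShape(.interpRadialShape(a, b, al)), "morph",
          morphline = m, alpha = al)
  }
  for (i in seq_len(nTextures)) add(texImgs[[i]], "texture", shape_id = i)
  for (i in seq_len(nSilhouettes))
    add(renderShape(silShapes[[i]]), "shape", shape_id = i)
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

#' Horizontal bars of varying length
#'
#' One centered horizontal bar per length, at fixed thickness, so the
#' foreground pixel count is exactly thickness times length.  The default
#' length ladder mixes geometric and arithmetic spacing (as fractions of the
#' canvas) so that absolute and relative length differences decorrelate
#' across pairs.
#'
#' @param lengths bar lengths in pixels; at least 4 distinct positive values,
#'   each smaller than the canvas width.  \code{NULL} selects the default
#'   ladder.
#' @param seed integer seed (recorded; bar rendering is deterministic)
#' @param size canvas size in pixels
#' @param thickness bar thickness in pixels
#' @return a \linkS4class{StimulusSet} with meta column \code{length}
#' @export
makeLengthBars <- function(lengths = NULL, seed = 1L, size = 224L,
                           thickness = max(2L, round(0.05 * size))) {
  if (is.null(lengths)) {
    fr <- c(0.10, 0.15, 0.225, 0.34, 0.51, 0.76, 0.20, 0.42, 0.64, 0.86)
    lengths <- unique(round(size * fr))
  }
  lengths <- as.integer(lengths)
  if (anyDuplicated(lengths)) stop("bar lengths must be distinct")
  if (length(lengths) < 4) stop("need at least 4 distinct lengths")
  if (any(lengths <= 0)) stop("bar lengths must be positive")
  if (any(lengths > size)) stop("bar length exceeds image width")
  imgs <- lapply(lengths, function(L) {
    img <- .canvas(size)
    r0 <- floor((size - thickness) / 2)
    c0 <- floor((size - L) / 2)
    img[(r0 + 1):(r0 + thickness), (c0 + 1):(c0 + L)] <- 255
    img
  })
  StimulusSet(imgs, data.frame(length = lengths), seed)
}
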