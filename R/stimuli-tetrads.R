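#' Two-part size tetrads
#'
#' Each tetrad crosses the sizes of the two parts of a black-silhouette
#' object at two levels: cell (i, j) renders part 1 at size level i and part
#' 2 at size level j, with level 2 scaled by a fixed factor relative to level
#' 1.  Cell (2,2) is therefore cell (1,1) with both parts scaled by the same
#' factor, while cells (1,2) and (2,1) change the parts' relative size.
#' Part shapes are drawn from a seeded random library.
#'
#' @param nTetrads number of tetrads
#' @param seed integer seed
#' @param size canvas size in pixels
#' @param sizeFactor scale factor between the two size levels
#' @return a \linkS4class{StimulusSet} with meta columns \code{tetrad_id},
#'   \code{s1}, \code{s2} (part-size levels in \{1, 2\}), \code{scale1},
#'   \code{scale2}
#' @export
makeSizeTetrads <- function(nTetrads, seed = 1L, size = 224L,
                            sizeFactor = 1.5) {
  stopifnot(nTetrads >= 1)
  withr::with_seed(seed, {
    lib <- lapply(seq_len(2 * nTetrads), function(i)
      .randomRadialShape(0.09 * size, kmax = 4L, amp = 0.28))
  })
  imgs <- list(); rows <- list(); k <- 0L
  baseR <- 0.09 * size
  for (tt in seq_len(nTetrads)) {
    p1 <- lib[[2 * tt - 1]]; p2 <- lib[[2 * tt]]
    for (s1 in 1:2) for (s2 in 1:2) {
      sc1 <- sizeFactor^(s1 - 1); sc2 <- sizeFactor^(s2 - 1)
      img <- .canvas(size)
      sh1 <- p1; sh1$r0 <- p1$r0 * sc1
      sh2 <- p2; sh2$r0 <- p2$r0 * sc2
      cy <- 0.5 * size
      x1 <- 0.30 * size; x2 <- 0.70 * size
      img <- .paintMask(img, .radialMask(img, cy, x1, sh1), 255)
      img <- .paintMask(img, .radialMask(img, cy, x2, sh2), 255)
      ## connecting stem keeps the object a single silhouette
      img <- .drawStrokes(img, list(c(cy, x1, cy, x2)), 255,
                          halfwidth = max(1, round(0.01 * size)))
      k <- k + 1L
      imgs[[k]] <- img
      rows[[k]] <- data.frame(tetrad_id = tt, s1 = s1, s2 = s2,
                              scale1 = sc1, scale2 = sc2)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

#' Pattern-on-surface tetrads
#'
#' For each pattern-surface pairing, four images cross the tilt of the
#' pattern and the tilt of the surface independently at two levels.  The
#' pattern's tilt at level k equals the surface's tilt at level k plus a
#' fixed offset, so the congruent cells (1,1) and (2,2) share an identical
#' pattern-relative-to-surface geometry parameter (recorded as
#' \code{rel_geom}), while the incongruent cells (1,2) and (2,1) do not.
#'
#' @param nPatterns number of patterns
#' @param nSurfaces number of surfaces
#' @param seed integer seed
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{tetrad_id},
#'   \code{pattern_id}, \code{surface_id}, \code{pattern_level},
#'   \code{surface_level}, \code{rel_geom}
#' @export
makeSurfaceTetrads <- function(nPatterns = 6L, nSurfaces = 4L, seed = 1L,
                               size = 224L) {
  stopifnot(nPatterns >= 1, nSurfaces >= 1)
  tilts <- c(-0.18, 0.22)          # surface slope at levels 1 and 2
  relOffset <- 0.55                # pattern slope relative to its surface level
  withr::with_seed(seed, {
    spacing <- round(runif(nPatterns, 0.07, 0.13) * size)
    phase <- round(runif(nPatterns, 0, 10))
    bandH <- round(runif(nSurfaces, 0.16, 0.24) * size)
    bandY <- round(runif(nSurfaces, 0.42, 0.58) * size)
  })
  imgs <- list(); rows <- list(); k <- 0L; tid <- 0L
  for (p in seq_len(nPatterns)) for (su in seq_len(nSurfaces)) {
    tid <- tid + 1L
    for (pl in 1:2) for (sl in 1:2) {
      thS <- tilts[sl]
      thP <- tilts[pl] + relOffset
      img <- .canvas(size)
      r <- .rowIdx(img); cc <- .colIdx(img)
      yOnSurf <- r - thS * (cc - size / 2)
      band <- abs(yOnSurf - bandY[su]) <= bandH[su] / 2
      img <- .paintMask(img, band, 140)
      stripePos <- (r - thP * (cc - size / 2) + phase[p]) %% spacing[p]
      stripes <- band & stripePos < max(2, spacing[p] / 3)
      img <- .paintMask(img, stripes, 250)
      k <- k + 1L
      imgs[[k]] <- img
      rows[[k]] <- data.frame(tetrad_id = tid, pattern_id = p, surface_id = su,
                              pattern_level = pl, surface_level = sl,
                              rel_geom = thP - thS)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}
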