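#' Line-drawing pairs probing 3D shape processing
#'
#' Three shape families (cuboid, cube, frustum proportions).  Each family
#' emits a 3D pair (an isometric-looking outline containing either a Y
#' junction or an alternative junction at its centre) and two 2D control
#' pairs (flat outlines containing the identical junction strokes).  The
#' junction strokes are drawn at identical canvas positions in all three
#' pairs and the outlines never enter the junction region, so the
#' changed-stroke mask (the set of pixels that differ between the two members
#' of a pair) is identical across the three pairs of a family by
#' construction.
#'
#' @param seed integer seed (controls a small global scale jitter and stroke
#'   width rounding)
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{family}
#'   (\code{cuboid}, \code{cube}, \code{frustum}), \code{pair_type}
#'   (\code{threeD}, \code{control1}, \code{control2}), \code{member}
#' @export
make3dPairs <- function(seed = 1L, size = 224L) {
  withr::with_seed(seed, {
    scale <- runif(1, 0.95, 1.05)
    hw <- max(1L, round(size / 100))
  })
  ctr <- size / 2
  rin <- 0.17 * size * scale        # junction region radius
  rout <- 0.34 * size * scale       # outline radius (clear of the junction)
  aspects <- c(cuboid = 1.25, cube = 1.0, frustum = 0.8)

  hexagon <- function(aspect) {
    th <- pi / 6 + (0:5) * pi / 3
    lapply(1:6, function(i) {
      j <- i %% 6 + 1
      c(ctr + rout * aspect * sin(th[i]), ctr + rout * cos(th[i]),
        ctr + rout * aspect * sin(th[j]), ctr + rout * cos(th[j]))
    })
  }
  squareOutline <- function(aspect) {
    h <- rout * aspect * 0.95; w <- rout * 0.95
    list(c(ctr - h, ctr - w, ctr - h, ctr + w),
         c(ctr - h, ctr + w, ctr + h, ctr + w),
         c(ctr + h, ctr + w, ctr + h, ctr - w),
         c(ctr + h, ctr - w, ctr - h, ctr - w))
  }
  diamondOutline <- function(aspect) {
    h <- rout * aspect * 1.05; w <- rout * 1.05
    list(c(ctr - h, ctr, ctr, ctr + w), c(ctr, ctr + w, ctr + h, ctr),
         c(ctr + h, ctr, ctr, ctr - w), c(ctr, ctr - w, ctr - h, ctr))
  }
  junction <- function(version) {
    ang <- if (version == 1) c(90, 210, 330) else c(30, 150, 270)
    lapply(ang * pi / 180, function(a)
      c(ctr, ctr, ctr - rin * sin(a), ctr + rin * cos(a)))
  }

  imgs <- list(); rows <- list(); k <- 0L
  for (fam in names(aspects)) {
    outlines <- list(threeD = hexagon(aspects[[fam]]),
                     control1 = squareOutline(aspects[[fam]]),
                     control2 = diamondOutline(aspects[[fam]]))
    for (pt in names(outlines)) for (member in 1:2) {
      img <- .canvas(size)
      img <- .drawStrokes(img, outlines[[pt]], 255, hw)
      img <- .drawStrokes(img, junction(member), 255, hw)
      k <- k + 1L
      imgs[[k]] <- img
      rows[[k]] <- data.frame(family = fam, pair_type = pt, member = member,
                              stringsAsFactors = FALSE)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

#' Square-disk occlusion and depth-ordering displays
#'
#' Two effect groups built from a gray square and a darker disk:
#' \describe{
#'   \item{occlusion}{\code{unoccluded} places the full disk beside the
#'     square; \code{occluded} moves the disk behind the square (the square
#'     is drawn on top, hiding a crescent).  The control pair
#'     (\code{control_a}, \code{control_b}) shows the identical two disk
#'     configurations without the square, so the pixelwise difference within
#'     the control pair equals that of the occlusion pair.}
#'   \item{depth_order}{\code{over1} (square over disk) and \code{over2}
#'     (disk over square) share all pixels outside the square-disk overlap
#'     region.  Their control pair shows the shapes without overlap plus a
#'     detached lens-shaped patch toggling between the two gray values.}
#' }
#' The bounding box of the pixels that differ within each real pair is
#' stored in meta (\code{diff_top} .. \code{diff_right}, 0-based half-open).
#'
#' @param seed integer seed (gray levels and geometry jitter)
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{effect},
#'   \code{role} and the diff-region box
#' @export
makeOcclusionDisplays <- function(seed = 1L, size = 224L) {
  withr::with_seed(seed, {
    gSquare <- round(runif(1, 190, 215))
    gDisk <- round(runif(1, 100, 130))
  })
  w <- round(0.15 * size)               # square half-width
  rad <- round(0.13 * size)             # disk radius
  sqC <- c(0.45 * size, 0.38 * size)    # square centre (row, col)
  diskFar <- c(0.45 * size, sqC[2] + w + rad + 0.03 * size)
  diskNear <- c(0.45 * size, sqC[2] + w + rad - 0.10 * size)

  blank <- .canvas(size)
  sqMask <- .boxMask(blank, boxRegion(sqC[1] - w, sqC[2] - w,
                                      sqC[1] + w, sqC[2] + w))
  dFarM <- .diskMask(blank, diskFar[1], diskFar[2], rad)
  dNearM <- .diskMask(blank, diskNear[1], diskNear[2], rad)

  paint <- function(...) {
    img <- blank
    for (lay in list(...)) img <- .paintMask(img, lay$mask, lay$value)
    img
  }
  L <- function(mask, value) list(mask = mask, value = value)

  unocc <- paint(L(sqMask, gSquare), L(dFarM, gDisk))
  occ <- paint(L(dNearM, gDisk), L(sqMask, gSquare))   # square drawn on top
  ctlA <- paint(L(dFarM, gDisk))
  ctlB <- paint(L(dNearM & !sqMask, gDisk))

  over1 <- paint(L(dNearM, gDisk), L(sqMask, gSquare)) # square over disk
  over2 <- paint(L(sqMask, gSquare), L(dNearM, gDisk)) # disk over square
  lens <- sqMask & dNearM
  ## detached patch congruent to the overlap lens, placed in a clear area
  shift <- round(0.32 * size)
  lensLow <- matrix(FALSE, size, size)
  lensLow[(shift + 1):size, ] <- lens[1:(size - shift), ]
  base2 <- paint(L(sqMask, gSquare), L(dFarM, gDisk))
  dctlA <- .paintMask(base2, lensLow, gSquare)
  dctlB <- .paintMask(base2, lensLow, gDisk)

  diffBox <- function(a, b) {
    d <- which(a != b, arr.ind = TRUE)
    boxRegion(min(d[, 1]) - 1, min(d[, 2]) - 1, max(d[, 1]), max(d[, 2]))
  }
  b1 <- diffBox(unocc, occ)
  b2 <- diffBox(over1, over2)

  imgs <- list(unocc, occ, ctlA, ctlB, over1, over2, dctlA, dctlB)
  meta <- data.frame(
    effect = rep(c("occlusion", "depth_order"), each = 4),
    role = c("unoccluded", "occluded", "control_a", "control_b",
             "over1", "over2", "control_a", "control_b"),
    stringsAsFactors = FALSE)
  for (f in c("top", "left", "bottom", "right")) {
    meta[[paste0("diff_", f)]] <- c(rep(b1[[f]], 4), rep(b2[[f]], 4))
  }
  StimulusSet(imgs, meta, seed)
}
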