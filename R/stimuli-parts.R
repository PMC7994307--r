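#' Whole objects with natural/unnatural breaks and part recombinations
#'
#' Seven whole silhouette objects are each generated from a top part contour
#' and a bottom part contour that join at a fixed seam row.  The natural cut
#' runs along the seam (the junction between the two generating part
#' contours, a curvature minimum of the outline); the unnatural cut runs at a
#' constant offset below it, through the middle of the bottom part.  Break
#' stimuli shift everything below the cut down by a background gap, which
#' preserves the foreground pixel count exactly.  Recombining the 7 top and 7
#' bottom pieces of each cut yields 49 natural-part and 49 unnatural-part
#' composite objects; the diagonal (part1 == part2) of both composite sets
#' reproduces the 7 original objects, forming the common set.
#'
#' @param seed integer seed
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{role}
#'   (\code{whole}, \code{break_natural}, \code{break_unnatural},
#'   \code{composite_natural}, \code{composite_unnatural}),
#'   \code{object_id}, \code{part1}, \code{part2}, \code{common}
#' @export
makePartObjects <- function(seed = 1L, size = 224L) {
  nObj <- 7L
  seam <- round(0.48 * size)
  cutUnnat <- round(0.62 * size)
  gap <- round(0.06 * size)
  withr::with_seed(seed, {
    tops <- lapply(seq_len(nObj), function(i)
      .randomRadialShape(0.20 * size, kmax = 4L, amp = 0.25))
    bots <- lapply(seq_len(nObj), function(i)
      .randomRadialShape(0.20 * size, kmax = 4L, amp = 0.25))
  })
  blank <- .canvas(size)
  rr <- .rowIdx(blank)
  topMask <- function(i) .radialMask(blank, 0.33 * size, 0.5 * size, tops[[i]]) & rr <= seam
  botMask <- function(i) .radialMask(blank, 0.63 * size, 0.5 * size, bots[[i]]) & rr > seam
  render <- function(mask) .paintMask(blank, mask, 255)
  breakAt <- function(mask, cut) {
    upper <- mask & rr <= cut
    lowerRows <- mask & rr > cut
    shifted <- matrix(FALSE, size, size)
    shifted[(cut + gap + 1):size, ] <- lowerRows[(cut + 1):(size - gap), ]
    if (sum(lowerRows) != sum(shifted))
      stop("break shifted part off canvas; increase size")
    upper | shifted
  }
  imgs <- list(); rows <- list(); k <- 0L
  add <- function(img, role, object_id = NA, part1 = NA, part2 = NA) {
    k <<- k + 1L
    imgs[[k]] <<- img
    rows[[k]] <<- data.frame(role = role, object_id = object_id,
                             part1 = part1, part2 = part2,
                             common = !is.na(part1) && part1 == part2,
                             stringsAsFactors = FALSE)
  }
  wholeMasks <- lapply(seq_len(nObj), function(i) topMask(i) | botMask(i))
  for (i in seq_len(nObj)) {
    add(render(wholeMasks[[i]]), "whole", object_id = i)
    add(render(breakAt(wholeMasks[[i]], seam)), "break_natural", object_id = i)
    add(render(breakAt(wholeMasks[[i]], cutUnnat)), "break_unnatural",
        object_id = i)
  }
  for (i in seq_len(nObj)) for (j in seq_len(nObj)) {
    natural <- (wholeMasks[[i]] & rr <= seam) | (wholeMasks[[j]] & rr > seam)
    unnat <- (wholeMasks[[i]] & rr <= cutUnnat) | (wholeMasks[[j]] & rr > cutUnnat)
    add(render(natural), "composite_natural", part1 = i, part2 = j)
    add(render(unnat), "composite_unnatural", part1 = i, part2 = j)
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

## Small filled glyph masks used both as local elements and (via their
## outlines) as global arrangements of hierarchical stimuli.
.glyphMask <- function(img, kind, cy, cx, r) {
  switch(kind,
    circle = .diskMask(img, cy, cx, r),
    square = .boxMask(img, boxRegion(cy - r, cx - r, cy + r, cx + r)),
    triangle = .polygonMask(img, c(cy - r, cy + r, cy + r),
                            c(cx, cx - r, cx + r)),
    diamond = .polygonMask(img, c(cy - r, cy, cy + r, cy),
                           c(cx, cx + r, cx, cx - r)),
    cross = (.boxMask(img, boxRegion(cy - r, cx - r / 2.5, cy + r, cx + r / 2.5)) |
             .boxMask(img, boxRegion(cy - r / 2.5, cx - r, cy + r / 2.5, cx + r))),
    hbar = .boxMask(img, boxRegion(cy - r / 2.5, cx - r, cy + r / 2.5, cx + r)),
    vbar = .boxMask(img, boxRegion(cy - r, cx - r / 2.5, cy + r, cx + r / 2.5)))
}

## Element positions tracing the outline of a glyph at global scale.
.glyphPositions <- function(kind, cy, cx, r, n = 12L) {
  perim <- function(ys, xs) {
    ys <- c(ys, ys[1]); xs <- c(xs, xs[1])
    seg <- sqrt(diff(ys)^2 + diff(xs)^2)
    cum <- c(0, cumsum(seg))
    tt <- seq(0, cum[length(cum)], length.out = n + 1)[seq_len(n)]
    t(vapply(tt, function(d) {
      i <- max(which(cum <= d)); i <- min(i, length(seg))
      f <- (d - cum[i]) / seg[i]
      c(ys[i] + f * (ys[i + 1] - ys[i]), xs[i] + f * (xs[i + 1] - xs[i]))
    }, numeric(2)))
  }
  switch(kind,
    circle = {
      th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
      cbind(cy + r * sin(th), cx + r * cos(th))
    },
    square = perim(c(cy - r, cy - r, cy + r, cy + r),
                   c(cx - r, cx + r, cx + r, cx - r)),
    triangle = perim(c(cy - r, cy + r, cy + r), c(cx, cx + r, cx - r)),
    diamond = perim(c(cy - r, cy, cy + r, cy), c(cx, cx + r, cx, cx - r)),
    cross = rbind(cbind(seq(cy - r, cy + r, length.out = ceiling(n / 2)), cx),
                  cbind(cy, seq(cx - r, cx + r, length.out = floor(n / 2)))),
    hbar = cbind(cy, seq(cx - r, cx + r, length.out = n)),
    vbar = cbind(seq(cy - r, cy + r, length.out = n), cx))
}

.hierGlyphs <- c("circle", "square", "triangle", "diamond", "cross",
                 "hbar", "vbar")

#' Hierarchical (global/local) stimuli
#'
#' Combines seven shapes at the global scale with the same seven shapes at
#' the local scale: stimulus (g, l) places identical local elements of shape
#' l at positions tracing the outline of shape g.  Stimuli sharing g share
#' element positions exactly; stimuli sharing l share the element shape.
#'
#' @param seed integer seed (recorded; the layout itself is deterministic)
#' @param size canvas size in pixels
#' @param nElements number of local elements per stimulus
#' @return a \linkS4class{StimulusSet} of 49 images with meta columns
#'   \code{g}, \code{l}, \code{g_name}, \code{l_name}
#' @export
makeHierarchicalStimuli <- function(seed = 1L, size = 224L, nElements = 12L) {
  rg <- 0.34 * size
  rl <- max(2, 0.045 * size)
  blank <- .canvas(size)
  positions <- lapply(.hierGlyphs, function(kind)
    .glyphPositions(kind, size / 2, size / 2, rg, nElements))
  imgs <- list(); rows <- list(); k <- 0L
  for (g in 1:7) for (l in 1:7) {
    img <- blank
    for (e in seq_len(nrow(positions[[g]]))) {
      img <- .paintMask(img, .glyphMask(blank, .hierGlyphs[l],
                                        positions[[g]][e, 1],
                                        positions[[g]][e, 2], rl), 255)
    }
    k <- k + 1L
    imgs[[k]] <- img
    rows[[k]] <- data.frame(g = g, l = l, g_name = .hierGlyphs[g],
                            l_name = .hierGlyphs[l], stringsAsFactors = FALSE)
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}
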