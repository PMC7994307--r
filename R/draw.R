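## Internal raster drawing helpers.  All images are numeric matrices,
## row 1 = top of the image, intensities in [0, 255].

.canvas <- function(size, bg = 0) matrix(bg, nrow = size, ncol = size)

.rowIdx <- function(img) row(img)
.colIdx <- function(img) col(img)

.paintMask <- function(img, mask, value) {
  img[mask] <- value
  img
}

## Rectangle mask from a 0-based half-open box (top, left, bottom, right).
.boxMask <- function(img, box) {
  r <- .rowIdx(img); c <- .colIdx(img)
  r > box$top & r <= box$bottom & c > box$left & c <= box$right
}

.ellipseMask <- function(img, cy, cx, ry, rx) {
  r <- .rowIdx(img); c <- .colIdx(img)
  ((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1
}

.diskMask <- function(img, cy, cx, rad) .ellipseMask(img, cy, cx, rad, rad)

## Closed radial contour r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k)),
## filled.  `shape` is list(r0, a, phi); radii are clamped positive.
.radialMask <- function(img, cy, cx, shape) {
  r <- .rowIdx(img); c <- .colIdx(img)
  th <- atan2(r - cy, c - cx)
  rad <- shape$r0 * (1 + Reduce(`+`, lapply(seq_along(shape$a), function(k)
    shape$a[k] * cos(k * th + shape$phi[k])), accumulate = FALSE))
  rad <- pmax(rad, 1)
  sqrt((r - cy)^2 + (c - cx)^2) <= rad
}

## Random radial shape parameters; amplitude budget keeps contours simple.
.randomRadialShape <- function(r0, kmax = 5L, amp = 0.25) {
  list(r0 = r0,
       a = runif(kmax, -amp, amp) / seq_len(kmax),
       phi = runif(kmax, 0, 2 * pi))
}

.interpRadialShape <- function(a, b, alpha) {
  list(r0 = (1 - alpha) * a$r0 + alpha * b$r0,
       a = (1 - alpha) * a$a + alpha * b$a,
       phi = (1 - alpha) * a$phi + alpha * b$phi)
}

## Convex/simple polygon mask by ray casting, vertices as (rowY, colX).
.polygonMask <- function(img, ys, xs) {
  r <- .rowIdx(img); c <- .colIdx(img)
  n <- length(xs)
  inside <- matrix(FALSE, nrow(img), ncol(img))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((ys[i] > r) != (ys[j] > r)) &
      (c < (xs[j] - xs[i]) * (r - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

## Straight stroke from (r0,c0) to (r1,c1) with square pen of given half-width.
.lineMask <- function(img, r0, c0, r1, c1, halfwidth = 1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1) * 2 + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  mask <- matrix(FALSE, nrow(img), ncol(img))
  off <- seq(-halfwidth, halfwidth)
  for (dr in off) for (dc in off) {
    ri <- rr + dr; ci <- cc + dc
    keep <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
    mask[cbind(ri[keep], ci[keep])] <- TRUE
  }
  mask
}

.drawStrokes <- function(img, strokes, value = 255, halfwidth = 1) {
  for (s in strokes)
    img <- .paintMask(img, .lineMask(img, s[1], s[2], s[3], s[4], halfwidth), value)
  img
}

## Separable Gaussian blur with replicate padding; kernel clipped to the
## image so small canvases stay valid.
.gaussBlur <- function(m, sigma) {
  h <- min(ceiling(3 * sigma), nrow(m) - 1L, ncol(m) - 1L)
  k <- exp(-(-h:h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, n) x[c(rep(1, n), seq_len(nrow(x)), rep(nrow(x), n)), , drop = FALSE]
  conv1 <- function(x) {           # along rows
    xp <- pad(x, h)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

## Smooth band-pass noise texture in [0, 255]: difference of two Gaussian
## blurs of white noise, rescaled.
.noiseTexture <- function(size, sigmaLow, sigmaHigh) {
  z <- matrix(rnorm(size * size), size, size)
  bp <- .gaussBlur(z, sigmaLow) - .gaussBlur(z, sigmaHigh)
  rng <- range(bp)
  if (diff(rng) == 0) return(.canvas(size, 128))
  round(255 * (bp - rng[1]) / diff(rng))
}

.clamp255 <- function(img) pmin(pmax(img, 0), 255)

## Composite foreground over background wherever mask is TRUE.
.compose <- function(bg, fg, mask) {
  bg[mask] <- fg[mask]
  bg
}
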