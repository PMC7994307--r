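#' Box regions
#'
#' A box region is a 0-based, half-open rectangle \code{list(top, left,
#' bottom, right)}: pixel rows \code{top .. bottom-1} and columns
#' \code{left .. right-1} (top-left origin).  Used to mark eye and mouth
#' regions on schematic faces.
#'
#' @param top,left,bottom,right 0-based bounds, half-open on bottom/right
#' @return a box region list
#' @export
boxRegion <- function(top, left, bottom, right) {
  stopifnot(bottom > top, right > left, top >= 0, left >= 0)
  list(top = as.integer(top), left = as.integer(left),
       bottom = as.integer(bottom), right = as.integer(right))
}

.boxInBounds <- function(box, img)
  box$top >= 0 && box$left >= 0 && box$bottom <= nrow(img) && box$right <= ncol(img)

.boxesOverlap <- function(a, b)
  a$top < b$bottom && b$top < a$bottom && a$left < b$right && b$left < a$right

#' Generate schematic faces with known eye and mouth boxes
#'
#' Draws parametric grayscale faces: an oval head, two eyes (sclera, iris and
#' an off-centre pupil so the eye region is vertically asymmetric), a nose
#' and a mouth with a darker lower lip.  Feature positions and sizes are
#' jittered per face from the seed, so faces differ across ids but are
#' bit-identical across reruns with the same seed.  The bounding boxes of the
#' left eye, right eye and mouth are known by construction and stored in the
#' \code{boxes} meta column (a list of three \code{\link{boxRegion}}s per
#' face, named \code{left_eye}, \code{right_eye}, \code{mouth}).
#'
#' @param nFaces number of faces (>= 1)
#' @param seed integer seed
#' @param size canvas size in pixels (square); must be at least 48 so the
#'   feature boxes fit
#' @return a \linkS4class{StimulusSet} with meta columns \code{face_id},
#'   \code{orientation}, \code{version}, \code{boxes}
#' @examples
#' faces <- makeFaces(2, seed = 1, size = 64)
#' stimMeta(faces)$boxes[[1]]$mouth
#' @export
makeFaces <- function(nFaces, seed = 1L, size = 224L) {
  stopifnot(nFaces >= 1)
  if (size < 48)
    stop("size too small to contain eye and mouth boxes (need >= 48)")
  withr::with_seed(seed, {
    imgs <- vector("list", nFaces)
    boxes <- vector("list", nFaces)
    for (f in seq_len(nFaces)) {
      drawn <- .drawFace(size)
      imgs[[f]] <- drawn$img
      boxes[[f]] <- drawn$boxes
    }
  })
  meta <- data.frame(face_id = seq_len(nFaces),
                     orientation = "upright", version = "normal",
                     stringsAsFactors = FALSE)
  meta$boxes <- boxes
  StimulusSet(imgs, meta, seed)
}

## One face; returns image plus named eye/mouth boxRegions.
.drawFace <- function(s) {
  img <- .canvas(s, bg = 20)
  jit <- function(x, f = 0.02) x + runif(1, -f * s, f * s)
  cy <- jit(0.52 * s); cx <- jit(0.50 * s)
  ry <- 0.38 * s * runif(1, 0.9, 1.05)
  rx <- 0.27 * s * runif(1, 0.9, 1.1)
  img <- .paintMask(img, .ellipseMask(img, cy, cx, ry, rx), 200)

  eyeRow <- jit(0.42 * s, 0.015)
  eyeOff <- 0.12 * s * runif(1, 0.9, 1.1)
  eyeRy <- max(2, 0.035 * s * runif(1, 0.85, 1.15))
  eyeRx <- max(3, 0.060 * s * runif(1, 0.85, 1.15))
  eyes <- list()
  for (sideName in c("left_eye", "right_eye")) {
    side <- if (sideName == "left_eye") -1 else 1
    ex <- cx + side * eyeOff
    img <- .paintMask(img, .ellipseMask(img, eyeRow, ex, eyeRy, eyeRx), 250)
    img <- .paintMask(img, .diskMask(img, eyeRow, ex, max(1, 0.45 * eyeRy)), 120)
    ## pupil sits above centre: makes the eye region vertically asymmetric
    img <- .paintMask(img,
                      .diskMask(img, eyeRow - 0.35 * eyeRy, ex, max(1, 0.25 * eyeRy)), 40)
    m <- 2
    eyes[[sideName]] <- boxRegion(floor(eyeRow - eyeRy - m), floor(ex - eyeRx - m),
                                  ceiling(eyeRow + eyeRy + m), ceiling(ex + eyeRx + m))
  }

  noseTop <- eyeRow + 2 * eyeRy + 2
  noseBot <- jit(0.60 * s, 0.01)
  img <- .drawStrokes(img, list(c(noseTop, cx, noseBot, cx - 0.03 * s),
                                c(noseBot, cx - 0.03 * s, noseBot, cx + 0.02 * s)),
                      value = 120, halfwidth = max(1, round(s / 150)))

  mouthRow <- jit(0.70 * s, 0.015)
  mouthRy <- max(2, 0.030 * s * runif(1, 0.85, 1.15))
  mouthRx <- max(4, 0.110 * s * runif(1, 0.85, 1.15))
  img <- .paintMask(img, .ellipseMask(img, mouthRow, cx, mouthRy, mouthRx), 90)
  ## darker lower lip: vertical asymmetry inside the mouth box
  lower <- .ellipseMask(img, mouthRow, cx, mouthRy, mouthRx) &
    .rowIdx(img) > mouthRow
  img <- .paintMask(img, lower, 50)
  m <- 2
  mouth <- boxRegion(floor(mouthRow - mouthRy - m), floor(cx - mouthRx - m),
                     ceiling(mouthRow + mouthRy + m), ceiling(cx + mouthRx + m))

  boxes <- c(eyes, list(mouth = mouth))
  for (b in boxes)
    if (!.boxInBounds(b, img))
      stop("size too small to contain eye and mouth boxes")
  list(img = img, boxes = boxes)
}

#' Locally invert image rows within box regions (Thatcherization)
#'
#' Flips the pixel rows upside down inside each box and leaves everything
#' outside untouched: within a box of height h, output row k is input row
#' h - 1 - k.  Applying the operation twice restores the original image.
#'
#' @param image grayscale image matrix
#' @param boxes list of \code{\link{boxRegion}}s, within bounds and mutually
#'   non-overlapping
#' @return the locally inverted image
#' @export
thatcherize <- function(image, boxes) {
  stopifnot(is.matrix(image))
  for (b in boxes)
    if (!.boxInBounds(b, image)) stop("box out of image bounds")
  if (length(boxes) > 1) {
    idx <- combn(length(boxes), 2)
    for (k in seq_len(ncol(idx)))
      if (.boxesOverlap(boxes[[idx[1, k]]], boxes[[idx[2, k]]]))
        stop("overlapping boxes: local inversion is ill-defined")
  }
  for (b in boxes) {
    rows <- (b$top + 1L):b$bottom
    cols <- (b$left + 1L):b$right
    image[rows, cols] <- image[rev(rows), cols]
  }
  image
}

#' Invert an image (180-degree in-plane rotation)
#'
#' Output pixel (i, j) equals input pixel (H-1-i, W-1-j); an involution that
#' permutes pixels without changing intensities.
#'
#' @param image grayscale matrix or RGB array
#' @return the rotated image
#' @export
invertImage <- function(image) {
  if (is.matrix(image)) return(image[nrow(image):1, ncol(image):1])
  for (ch in seq_len(dim(image)[3]))
    image[, , ch] <- image[dim(image)[1]:1, dim(image)[2]:1, ch]
  image
}

#' Build the four-role Thatcher stimulus set from generated faces
#'
#' For every face produces the upright normal, upright Thatcherized, inverted
#' normal and inverted Thatcherized versions (inversion = 180-degree
#' rotation).
#'
#' @param faces a \linkS4class{StimulusSet} from [makeFaces()]
#' @return a \linkS4class{StimulusSet} with meta columns \code{face_id},
#'   \code{orientation}, \code{version}
#' @export
thatcherStimuli <- function(faces) {
  meta <- stimMeta(faces)
  imgs <- list(); rows <- list(); k <- 0L
  for (f in seq_len(nStimuli(faces))) {
    base <- images(faces)[[f]]
    thatch <- thatcherize(base, meta$boxes[[f]])
    versions <- list(
      list(base, "upright", "normal"),
      list(thatch, "upright", "thatcherized"),
      list(invertImage(base), "inverted", "normal"),
      list(invertImage(thatch), "inverted", "thatcherized"))
    for (v in versions) {
      k <- k + 1L
      imgs[[k]] <- v[[1]]
      rows[[k]] <- data.frame(face_id = meta$face_id[f], orientation = v[[2]],
                              version = v[[3]], stringsAsFactors = FALSE)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), stimSeed(faces))
}
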