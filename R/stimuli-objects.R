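#' Silhouette objects with mirror companions
#'
#' Generates asymmetric silhouette objects together with their vertical-mirror
#' (left-right flip) and horizontal-mirror (up-down flip) versions.  Half of
#' the base objects are 90-degree rotations of the other half, so that
#' elongation along one axis cannot bias the horizontal/vertical comparison.
#' Asymmetry is enforced: a base silhouette is redrawn until it differs from
#' both of its own mirror images.
#'
#' @param nObjects even number of base objects
#' @param seed integer seed
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{object_id},
#'   \code{role} (\code{original}, \code{vmirror}, \code{hmirror}) and
#'   \code{rotated}
#' @export
makeMirrorSet <- function(nObjects, seed = 1L, size = 224L) {
  if (nObjects %% 2 != 0) stop("nObjects must be even")
  half <- nObjects %/% 2
  withr::with_seed(seed, {
    bases <- vector("list", half)
    for (o in seq_len(half)) {
      for (try in 1:20) {
        img <- .canvas(size)
        sh <- .randomRadialShape(0.30 * size, kmax = 5L, amp = 0.35)
        ## off-centre placement adds asymmetry
        cy <- size * runif(1, 0.45, 0.55); cx <- size * runif(1, 0.45, 0.55)
        img <- .paintMask(img, .radialMask(img, cy, cx, sh), 255)
        if (!identical(img, img[, ncol(img):1]) &&
            !identical(img, img[nrow(img):1, ])) break
      }
      bases[[o]] <- img
    }
  })
  rot90 <- function(m) t(m[nrow(m):1, ])   # clockwise quarter turn
  allBases <- c(bases, lapply(bases, rot90))
  imgs <- list(); rows <- list(); k <- 0L
  for (o in seq_len(nObjects)) {
    b <- allBases[[o]]
    vers <- list(original = b, vmirror = b[, ncol(b):1], hmirror = b[nrow(b):1, ])
    for (role in names(vers)) {
      k <- k + 1L
      imgs[[k]] <- vers[[role]]
      rows[[k]] <- data.frame(object_id = o, role = role,
                              rotated = o > half, stringsAsFactors = FALSE)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

#' Objects on congruent and incongruent backgrounds
#'
#' Each synthetic object (a textured silhouette) has its own context texture,
#' statistically associated with the object class by construction.  The
#' congruent scene composites the object onto its own context; the
#' incongruent scene composites the identical object pixels, at the identical
#' position, onto the context of another object (cyclic assignment).  An
#' isolated-object image on a blank ground is also emitted.
#'
#' @param nObjects number of object classes (>= 2)
#' @param seed integer seed
#' @param size canvas size in pixels
#' @return a \linkS4class{StimulusSet} with meta columns \code{object_id},
#'   \code{role} (\code{isolated}, \code{congruent}, \code{incongruent}),
#'   \code{context_id}, \code{label}
#' @export
makeScenes <- function(nObjects, seed = 1L, size = 224L) {
  if (nObjects < 2) stop("need at least 2 objects for an incongruent context")
  withr::with_seed(seed, {
    masks <- vector("list", nObjects)
    fills <- vector("list", nObjects)
    contexts <- vector("list", nObjects)
    for (o in seq_len(nObjects)) {
      img <- .canvas(size)
      sh <- .randomRadialShape(0.22 * size, kmax = 4L, amp = 0.30)
      masks[[o]] <- .radialMask(img, 0.5 * size, 0.5 * size, sh)
      ## object's own fine texture; contexts are coarser
      fills[[o]] <- 80 + 0.55 * .noiseTexture(size, 0.8, 2.5)
      contexts[[o]] <- 0.75 * .noiseTexture(size, 3 + o %% 4, 9 + o %% 4)
    }
  })
  imgs <- list(); rows <- list(); k <- 0L
  for (o in seq_len(nObjects)) {
    objOnly <- .compose(.canvas(size), fills[[o]], masks[[o]])
    incCtx <- o %% nObjects + 1L
    for (role in c("isolated", "congruent", "incongruent")) {
      ctx <- switch(role, isolated = NA_integer_,
                    congruent = o, incongruent = incCtx)
      bg <- if (role == "isolated") .canvas(size) else contexts[[ctx]]
      k <- k + 1L
      imgs[[k]] <- .clamp255(.compose(bg, fills[[o]], masks[[o]]))
      rows[[k]] <- data.frame(object_id = o, role = role, context_id = ctx,
                              label = o, stringsAsFactors = FALSE)
    }
  }
  StimulusSet(imgs, do.call(rbind, rows), seed)
}

#' Singleton, pair and triplet multi-object displays
#'
#' Places each of \code{nObjects} silhouette objects at each of three fixed,
#' non-overlapping locations (a horizontal row with equal spacing) to form
#' the singleton displays, then composes randomly selected pairs and triplets
#' of singletons pixelwise (maximum composition on a blank ground), so every
#' multi-object display restricted to a location's region equals the
#' corresponding singleton's region.
#'
#' @param nObjects number of distinct objects (>= 3)
#' @param nPairs number of two-object displays
#' @param nTriplets number of three-object displays
#' @param seed integer seed
#' @param size canvas size in pixels
#' @param objectRadius nominal object radius in pixels; locations must not
#'   overlap at this radius
#' @return a \linkS4class{StimulusSet}; meta columns \code{role}
#'   (\code{singleton}, \code{pair}, \code{triplet}), \code{object_id} and
#'   \code{location} for singletons, and \code{obj_at_loc1..3} (NA when the
#'   location is empty)
#' @export
makeMultiObjectDisplays <- function(nObjects, nPairs, nTriplets, seed = 1L,
                                    size = 224L, objectRadius = 0.11 * size) {
  if (nObjects < 3) stop("need at least 3 objects")
  locX <- size * c(0.2, 0.5, 0.8)
  if (2 * objectRadius >= size * 0.3)
    stop("locations overlap at the requested object size")
  withr::with_seed(seed, {
    shapes <- lapply(seq_len(nObjects), function(o)
      .randomRadialShape(objectRadius * runif(1, 0.8, 1.0), kmax = 4L, amp = 0.3))
    singles <- vector("list", nObjects)
    for (o in seq_len(nObjects)) {
      singles[[o]] <- lapply(1:3, function(l) {
        img <- .canvas(size)
        .paintMask(img, .radialMask(img, 0.5 * size, locX[l], shapes[[o]]), 255)
      })
    }
    pairSel <- lapply(seq_len(nPairs), function(i) {
      objs <- sample(nObjects, 2)
      locs <- sort(sample(3, 2))
      list(objs = objs, locs = locs)
    })
    tripSel <- lapply(seq_len(nTriplets), function(i)
      list(objs = sample(nObjects, 3), locs = 1:3))
  })
  imgs <- list(); rows <- list(); k <- 0L
  emptyLoc <- c(obj_at_loc1 = NA_integer_, obj_at_loc2 = NA_integer_,
                obj_at_loc3 = NA_integer_)
  for (o in seq_len(nObjects)) for (l in 1:3) {
    k <- k + 1L
    imgs[[k]] <- singles[[o]][[l]]
    at <- emptyLoc; at[l] <- o
    rows[[k]] <- data.frame(role = "singleton", object_id = o, location = l,
                            display_id = k, t(at), stringsAsFactors = FALSE)
  }
  addMulti <- function(sel, role) {
    for (s in sel) {
      k <<- k + 1L
      img <- .canvas(size)
      at <- emptyLoc
      for (m in seq_along(s$objs)) {
        img <- pmax(img, singles[[s$objs[m]]][[s$locs[m]]])
        at[s$locs[m]] <- s$objs[m]
      }
      imgs[[k]] <<- img
      rows[[k]] <<- data.frame(role = role, object_id = NA_integer_,
                               location = NA_integer_, display_id = k, t(at),
                               stringsAsFactors = FALSE)
    }
  }
  addMulti(pairSel, "pair")
  addMulti(tripSel, "triplet")
  StimulusSet(imgs, do.call(rbind, rows), seed)
}
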