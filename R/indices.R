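## The twelve experiment procedures.  Each maps (StimulusSet,
## ActivationTable) to a per-layer profile data.frame via the shared
## contrast-index machinery in metrics.R.

.layerLoop <- function(table, f) {
  lapply(seq_len(nLayers(table)), function(l) f(table@activations[[l]], l))
}

.rowDist <- function(acts, i, j, metric = "euclidean")
  featureDistance(acts[i, ], acts[j, ], metric)

.matchRow <- function(meta, cond) {
  idx <- which(cond)
  if (length(idx) != 1L) stop("expected exactly one stimulus for a role")
  idx
}

#' Thatcher index across layers
#'
#' Per face, the contrast between the normal-vs-Thatcherized distance in the
#' upright orientation and the same distance in the inverted orientation:
#' \code{(d_upright - d_inverted) / (d_upright + d_inverted)}.  For any
#' pixel-like representation the index is exactly zero, because inversion is
#' a fixed pixel permutation applied to both members of the pair and so
#' preserves the distance.
#'
#' @param stimuli four-role face set from [thatcherStimuli()]
#' @param table aligned \linkS4class{ActivationTable}
#' @param metric distance metric (see [featureDistance()])
#' @return per-layer profile \code{data.frame} (see [aggregateProfile()])
#' @export
thatcherIndex <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  faces <- unique(meta$face_id)
  vals <- .layerLoop(table, function(acts, l) {
    vapply(faces, function(f) {
      r <- function(o, v) .matchRow(meta, meta$face_id == f &
                                      meta$orientation == o & meta$version == v)
      dUp <- .rowDist(acts, r("upright", "normal"), r("upright", "thatcherized"), metric)
      dInv <- .rowDist(acts, r("inverted", "normal"), r("inverted", "thatcherized"), metric)
      contrastIndex(dUp, dInv)
    }, numeric(1))
  })
  aggregateProfile(vals, layerInfo(table))
}

#' Mirror confusion index across layers
#'
#' Per object, \code{(d_horizontal - d_vertical) / (d_horizontal +
#' d_vertical)} where \code{d_vertical} is the distance to the left-right
#' (vertical-axis) mirror and \code{d_horizontal} the distance to the
#' up-down mirror.  Positive values mean left-right mirrors are closer, the
#' human-like pattern.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeMirrorSet()]
#' @export
mirrorConfusionIndex <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  objs <- unique(meta$object_id)
  vals <- .layerLoop(table, function(acts, l) {
    vapply(objs, function(o) {
      r <- function(role) .matchRow(meta, meta$object_id == o & meta$role == role)
      dH <- .rowDist(acts, r("original"), r("hmirror"), metric)
      dV <- .rowDist(acts, r("original"), r("vmirror"), metric)
      contrastIndex(dH, dV)
    }, numeric(1))
  })
  aggregateProfile(vals, layerInfo(table))
}

#' Scene incongruence distance index across layers
#'
#' Per object, both scenes are compared to the object's average feature
#' vector; the index contrasts the incongruent-scene distance with the
#' congruent-scene distance, so a positive mean indicates that incongruent
#' scenes sit further from the object's average representation.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeScenes()]
#' @param average which images define the object's average vector:
#'   \code{"all"} (isolated + both scenes, default) or \code{"scenes"}
#'   (congruent + incongruent only; with a single scene of each kind this
#'   average is their midpoint and the index degenerates to zero)
#' @export
sceneIncongruenceIndex <- function(stimuli, table, metric = "euclidean",
                                   average = c("all", "scenes")) {
  average <- match.arg(average)
  meta <- stimMeta(stimuli)
  objs <- unique(meta$object_id)
  vals <- .layerLoop(table, function(acts, l) {
    vapply(objs, function(o) {
      sceneRows <- which(meta$object_id == o & meta$role %in% c("congruent", "incongruent"))
      if (length(sceneRows) < 2) stop("object with fewer than 2 scenes")
      avgRows <- if (average == "all") which(meta$object_id == o) else sceneRows
      avg <- colMeans(acts[avgRows, , drop = FALSE])
      dC <- featureDistance(acts[.matchRow(meta, meta$object_id == o &
                                             meta$role == "congruent"), ], avg, metric)
      dI <- featureDistance(acts[.matchRow(meta, meta$object_id == o &
                                             meta$role == "incongruent"), ], avg, metric)
      contrastIndex(dI, dC)
    }, numeric(1))
  })
  aggregateProfile(vals, layerInfo(table))
}

#' Top-k classification accuracy on congruent vs incongruent scenes
#'
#' @param probs stimuli-by-class probability matrix (e.g. from
#'   [contextClassifierProbs()])
#' @param meta scene metadata with columns \code{label} and \code{role}
#' @param k top-k level (1 or 5 typically); must not exceed the class count
#' @return one-row \code{data.frame} with \code{k}, \code{congruent},
#'   \code{incongruent} accuracies
#' @export
sceneIncongruenceAccuracy <- function(probs, meta, k = 1L) {
  if (k > ncol(probs)) stop("k larger than class count")
  if (max(meta$label) > ncol(probs)) stop("labels outside class set")
  topk <- function(p) order(-p, seq_along(p))[seq_len(k)]  # stable tie-break
  hit <- vapply(seq_len(nrow(probs)), function(i)
    meta$label[i] %in% topk(probs[i, ]), logical(1))
  data.frame(k = k,
             congruent = mean(hit[meta$role == "congruent"]),
             incongruent = mean(hit[meta$role == "incongruent"]))
}

#' Multiple-object normalization slopes across layers
#'
#' Units are kept only when they respond with non-zero variance to the
#' singleton images at every one of the three locations.  For each selected
#' unit and each pair (triplet) display, the display response is plotted
#' against the sum of the unit's responses to the constituent singletons;
#' the pooled ordinary least-squares slope is reported per layer.  A slope
#' of 0.5 for pairs and 1/3 for triplets is the signature of divisive
#' (averaging) normalization.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeMultiObjectDisplays()]
#' @param nUnitsSample optional cap on selected units per layer (uniform
#'   subsample under \code{seed})
#' @param seed seed for the unit subsample
#' @param tol relative variance tolerance for unit selection
#' @return \code{data.frame} per layer: \code{slope_pairs},
#'   \code{slope_triplets}, \code{n_units}, \code{n_points_pairs},
#'   \code{n_points_triplets}, \code{defined}
#' @export
normalizationSlopes <- function(stimuli, table, nUnitsSample = Inf, seed = 1L,
                                tol = 1e-12) {
  meta <- stimMeta(stimuli)
  locRows <- lapply(1:3, function(l)
    which(meta$role == "singleton" & meta$location == l))
  if (any(lengths(locRows) == 0)) stop("singleton roles missing")
  singRow <- function(o, l)
    which(meta$role == "singleton" & meta$object_id == o & meta$location == l)
  atCols <- c("obj_at_loc1", "obj_at_loc2", "obj_at_loc3")
  multiRows <- function(role) which(meta$role == role)
  out <- .layerLoop(table, function(acts, l) {
    keep <- which(selectVisuallyActive(acts, locRows, tol))
    if (!length(keep))
      return(data.frame(layer = l - 1L, slope_pairs = NA_real_,
                        slope_triplets = NA_real_, n_units = 0L,
                        n_points_pairs = 0L, n_points_triplets = 0L,
                        defined = FALSE))
    if (length(keep) > nUnitsSample)
      keep <- withr::with_seed(seed, sort(sample(keep, nUnitsSample)))
    slopeFor <- function(role) {
      rows <- multiRows(role)
      if (!length(rows)) return(list(slope = NA_real_, n = 0L))
      xs <- matrix(0, length(rows), length(keep))
      ys <- acts[rows, keep, drop = FALSE]
      for (ri in seq_along(rows)) {
        at <- unlist(meta[rows[ri], atCols])
        for (loc in which(!is.na(at)))
          xs[ri, ] <- xs[ri, ] + acts[singRow(at[loc], loc), keep]
      }
      list(slope = fitSlope(as.vector(xs), as.vector(ys)), n = length(xs))
    }
    sp <- slopeFor("pair"); st <- slopeFor("triplet")
    data.frame(layer = l - 1L, slope_pairs = sp$slope,
               slope_triplets = st$slope, n_units = length(keep),
               n_points_pairs = sp$n, n_points_triplets = st$n, defined = TRUE)
  })
  cbind(do.call(rbind, out),
        name = layerInfo(table)$name, kind = layerInfo(table)$kind)
}

## Columnwise sparseness of a nonnegative stimuli-by-unit matrix.
.colSparseness <- function(m) {
  n <- nrow(m)
  s1 <- colMeans(m)
  s2 <- colMeans(m^2)
  out <- (1 - s1^2 / s2) / (1 - 1 / n)
  out[s2 == 0] <- NA_real_
  out
}

## Columnwise min-max normalization to [0, 1] (columns assumed non-constant).
.colNormalize <- function(m) {
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  sweep(sweep(m, 2, lo), 2, hi - lo, "/")
}

#' Correlated sparseness across layers
#'
#' For each layer, units visually active (non-zero variance) on both members
#' of a subset pairing are normalized to \code{[0, 1]} across the union of
#' the two subsets; sparseness is then computed per subset and correlated
#' across units.  Two pairings are reported: reference shapes vs morphlines
#' (morphline sparseness averaged over the four lines) and textures vs
#' silhouette shapes.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeShapeSets()]
#' @param tol relative variance tolerance for unit selection
#' @return \code{data.frame} per layer: \code{r_ref_morph},
#'   \code{r_texture_shape}, unit counts, \code{defined}
#' @export
correlatedSparseness <- function(stimuli, table, tol = 1e-12) {
  meta <- stimMeta(stimuli)
  refRows <- which(meta$subset == "reference")
  morphRows <- which(meta$subset == "morph")
  texRows <- which(meta$subset == "texture")
  shapeRows <- which(meta$subset == "shape")
  morphLines <- lapply(sort(unique(meta$morphline[morphRows])), function(m)
    which(meta$subset == "morph" & meta$morphline == m))
  pairCor <- function(acts, rowsA, rowsB, sparseB) {
    keep <- which(selectVisuallyActive(acts, list(rowsA, rowsB), tol))
    if (length(keep) < 3) return(list(r = NA_real_, n = length(keep)))
    m <- .colNormalize(acts[c(rowsA, rowsB), keep, drop = FALSE])
    nA <- length(rowsA)
    sA <- .colSparseness(m[seq_len(nA), , drop = FALSE])
    sB <- sparseB(m[-seq_len(nA), , drop = FALSE], keep)
    list(r = sparsenessCorrelation(sA, sB), n = length(keep))
  }
  out <- .layerLoop(table, function(acts, l) {
    rm <- pairCor(acts, refRows, morphRows, function(mB, keep) {
      ## average sparseness over the four morphlines
      perLine <- vapply(morphLines, function(rows) {
        sub <- mB[match(rows, morphRows), , drop = FALSE]
        .colSparseness(sub)
      }, numeric(ncol(mB)))
      rowMeans(perLine)
    })
    ts <- pairCor(acts, texRows, shapeRows, function(mB, keep) .colSparseness(mB))
    data.frame(layer = l - 1L, r_ref_morph = rm$r, n_ref_morph = rm$n,
               r_texture_shape = ts$r, n_texture_shape = ts$n,
               defined = !is.na(rm$r) || !is.na(ts$r))
  })
  cbind(do.call(rbind, out),
        name = layerInfo(table)$name, kind = layerInfo(table)$kind)
}

#' Weber's-law correlations across layers
#'
#' Per layer, pairwise dissimilarities between the bar images are correlated
#' with absolute and with relative length differences (see
#' [weberCorrelations()]); layers where \code{r_rel - r_abs > 0} exhibit
#' Weber's-law-like coding of length.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeLengthBars()]
#' @export
weberIndex <- function(stimuli, table, metric = "euclidean") {
  lengths <- stimMeta(stimuli)$length
  out <- .layerLoop(table, function(acts, l) {
    w <- weberCorrelations(lengths, .pairwiseDistances(acts, metric))
    cbind(data.frame(layer = l - 1L), w,
          n = choose(length(lengths), 2), defined = TRUE)
  })
  cbind(do.call(rbind, out),
        name = layerInfo(table)$name, kind = layerInfo(table)$kind)
}

## Shared machinery of the two tetrad experiments: per (unit, tetrad) entry,
## interaction |r11 + r22 - r12 - r21|; keep the top fraction of entries
## (stable ties by entry order); index = contrast of |r12 - r21| (incongruent
## cells) vs |r11 - r22| (congruent cells).
.tetradIndex <- function(table, cellRows, topFraction, tol, normalize) {
  allRows <- sort(unique(unlist(cellRows)))
  .layerLoop(table, function(acts, l) {
    keep <- which(selectVisuallyActive(acts, list(allRows), tol))
    if (!length(keep)) return(NA)
    m <- acts[, keep, drop = FALSE]
    if (normalize) m[allRows, ] <- .colNormalize(m[allRows, , drop = FALSE])
    R11 <- m[cellRows$r11, , drop = FALSE]; R12 <- m[cellRows$r12, , drop = FALSE]
    R21 <- m[cellRows$r21, , drop = FALSE]; R22 <- m[cellRows$r22, , drop = FALSE]
    inter <- abs(R11 + R22 - R12 - R21)
    if (all(inter == 0)) return(NA)
    nKeep <- ceiling(topFraction * length(inter))
    sel <- order(-as.vector(inter), seq_along(inter))[seq_len(nKeep)]
    d1 <- abs(R12 - R21)[sel]
    d2 <- abs(R11 - R22)[sel]
    contrastIndex(d1, d2)
  })
}

#' Relative size index across layers
#'
#' For each visually responsive unit and each two-part size tetrad, the size
#' interaction \code{|r11 + r22 - r12 - r21|} ranks all (unit, tetrad)
#' entries; the top fraction (default 7 percent) is kept and the index
#' contrasts the incongruent-cell response difference \code{|r12 - r21|}
#' with the congruent one \code{|r11 - r22|}.  Positive values mean the
#' congruent (both parts covarying in size) stimuli are closer: relative
#' size coding.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeSizeTetrads()]
#' @param topFraction fraction of (unit, tetrad) entries kept
#' @param tol relative variance tolerance for unit selection
#' @export
relativeSizeIndex <- function(stimuli, table, topFraction = 0.07, tol = 1e-12) {
  meta <- stimMeta(stimuli)
  tets <- sort(unique(meta$tetrad_id))
  cellRows <- list(
    r11 = vapply(tets, function(t) .matchRow(meta, meta$tetrad_id == t & meta$s1 == 1 & meta$s2 == 1), integer(1)),
    r12 = vapply(tets, function(t) .matchRow(meta, meta$tetrad_id == t & meta$s1 == 1 & meta$s2 == 2), integer(1)),
    r21 = vapply(tets, function(t) .matchRow(meta, meta$tetrad_id == t & meta$s1 == 2 & meta$s2 == 1), integer(1)),
    r22 = vapply(tets, function(t) .matchRow(meta, meta$tetrad_id == t & meta$s1 == 2 & meta$s2 == 2), integer(1)))
  vals <- .tetradIndex(table, cellRows, topFraction, tol, normalize = FALSE)
  vals <- lapply(vals, function(v) if (length(v) == 1 && is.na(v)) NA_real_ else v)
  aggregateProfile(vals, layerInfo(table))
}

#' Surface invariance index across layers
#'
#' As [relativeSizeIndex()], on pattern-by-surface tetrads with unit
#' responses first normalized to \code{[0, 1]} across the stimulus set;
#' the top fraction defaults to 9 percent.  Congruent cells are those where
#' pattern and surface tilt levels agree (equal pattern-relative-to-surface
#' geometry).
#'
#' @inheritParams relativeSizeIndex
#' @param stimuli set from [makeSurfaceTetrads()]
#' @export
surfaceInvarianceIndex <- function(stimuli, table, topFraction = 0.09,
                                   tol = 1e-12) {
  meta <- stimMeta(stimuli)
  tets <- sort(unique(meta$tetrad_id))
  cellOf <- function(pl, sl) vapply(tets, function(t)
    .matchRow(meta, meta$tetrad_id == t & meta$pattern_level == pl &
                meta$surface_level == sl), integer(1))
  cellRows <- list(r11 = cellOf(1, 1), r12 = cellOf(1, 2),
                   r21 = cellOf(2, 1), r22 = cellOf(2, 2))
  vals <- .tetradIndex(table, cellRows, topFraction, tol, normalize = TRUE)
  vals <- lapply(vals, function(v) if (length(v) == 1 && is.na(v)) NA_real_ else v)
  aggregateProfile(vals, layerInfo(table))
}

#' 3D processing index across layers
#'
#' Per shape family, \code{d1} is the distance between the two members of
#' the 3D pair and \code{d2} the distance between the members of a 2D
#' control pair carrying the identical changed strokes; the index
#' \code{(d1 - d2)/(d1 + d2)} is reported separately for the two control
#' conditions.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [make3dPairs()]
#' @return profile \code{data.frame} with an added \code{condition} column
#'   (1 or 2)
#' @export
depth3dIndex <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  fams <- unique(meta$family)
  pairDist <- function(acts, fam, pt) {
    r <- function(memb) .matchRow(meta, meta$family == fam &
                                    meta$pair_type == pt & meta$member == memb)
    .rowDist(acts, r(1), r(2), metric)
  }
  out <- lapply(1:2, function(cond) {
    ctl <- paste0("control", cond)
    vals <- .layerLoop(table, function(acts, l)
      vapply(fams, function(fam)
        contrastIndex(pairDist(acts, fam, "threeD"), pairDist(acts, fam, ctl)),
        numeric(1)))
    cbind(aggregateProfile(vals, layerInfo(table)), condition = cond)
  })
  do.call(rbind, out)
}

#' Occlusion and depth-ordering indices across layers
#'
#' For each effect group, \code{d1} is the distance between the two displays
#' that differ by occlusion (or by depth order) and \code{d2} the distance
#' between the control pair with the same 2D feature difference; the index
#' \code{(d2 - d1)/(d2 + d1)} is positive when the occlusion-related change
#' costs less than the equivalent 2D change, the human-like pattern.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeOcclusionDisplays()]
#' @return profile \code{data.frame} with an added \code{effect} column
#' @export
occlusionIndex <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  realRoles <- list(occlusion = c("unoccluded", "occluded"),
                    depth_order = c("over1", "over2"))
  realRoles <- realRoles[intersect(names(realRoles), unique(meta$effect))]
  if (!length(realRoles)) stop("no occlusion/depth-order effect groups in meta")
  out <- lapply(names(realRoles), function(eff) {
    r <- function(role) .matchRow(meta, meta$effect == eff & meta$role == role)
    vals <- .layerLoop(table, function(acts, l) {
      d1 <- .rowDist(acts, r(realRoles[[eff]][1]), r(realRoles[[eff]][2]), metric)
      d2 <- .rowDist(acts, r("control_a"), r("control_b"), metric)
      contrastIndex(d2, d1)
    })
    cbind(aggregateProfile(vals, layerInfo(table)), effect = eff)
  })
  do.call(rbind, out)
}

#' Part-break (natural part) index across layers
#'
#' Per object, \code{(d_u - d_n)/(d_u + d_n)} where \code{d_n} and
#' \code{d_u} are the distances from the intact object to its
#' natural-break and unnatural-break versions.  Positive values mean
#' natural breaks cost less: part-structured representation.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makePartObjects()]
#' @export
partBreakIndex <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  objs <- unique(meta$object_id[meta$role == "whole"])
  vals <- .layerLoop(table, function(acts, l) {
    vapply(objs, function(o) {
      r <- function(role) .matchRow(meta, meta$role == role &
                                      !is.na(meta$object_id) & meta$object_id == o)
      dN <- .rowDist(acts, r("whole"), r("break_natural"), metric)
      dU <- .rowDist(acts, r("whole"), r("break_unnatural"), metric)
      contrastIndex(dU, dN)
    }, numeric(1))
  })
  aggregateProfile(vals, layerInfo(table))
}

#' Natural part advantage across layers
#'
#' Fits the part-sum model (see [buildPartSumDesign()]) separately to the
#' pairwise distances of the natural-part and unnatural-part composite sets,
#' evaluates each fit as the observed-vs-predicted correlation on the 21
#' pairs between the 7 common objects, and reports \code{r_natural},
#' \code{r_unnatural} and their difference.
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makePartObjects()]
#' @return \code{data.frame} per layer: \code{r_natural},
#'   \code{r_unnatural}, \code{advantage}, \code{defined}
#' @export
naturalPartAdvantage <- function(stimuli, table, metric = "euclidean") {
  meta <- stimMeta(stimuli)
  setRows <- function(role) {
    rows <- which(meta$role == role)
    rows[order(meta$part1[rows], meta$part2[rows])]
  }
  natRows <- setRows("composite_natural")
  unnatRows <- setRows("composite_unnatural")
  objects <- cbind(meta$part1[natRows], meta$part2[natRows])
  design <- buildPartSumDesign(objects, partCount = max(objects))
  evalIdx <- commonPairIndices(design)
  out <- .layerLoop(table, function(acts, l) {
    rFor <- function(rows) {
      d <- .pairwiseDistances(acts[rows, , drop = FALSE], metric)
      fit <- suppressWarnings(fitPartSum(design, d))
      evaluatePartSum(fit, evalIdx, d)
    }
    rn <- rFor(natRows); ru <- rFor(unnatRows)
    data.frame(layer = l - 1L, r_natural = rn, r_unnatural = ru,
               advantage = rn - ru, defined = is.finite(rn) && is.finite(ru))
  })
  cbind(do.call(rbind, out),
        name = layerInfo(table)$name, kind = layerInfo(table)$kind)
}

#' Global advantage index across layers
#'
#' On the 7 x 7 hierarchical grid, \code{d_global} is the mean distance over
#' the 147 image pairs sharing the local shape but differing in global
#' shape, and \code{d_local} the mean over the 147 pairs sharing the global
#' shape; the index is \code{(d_global - d_local)/(d_global + d_local)}.
#' The s.e.m. is obtained by a seeded bootstrap over pairs (the index is a
#' ratio of means, so no per-item decomposition exists).
#'
#' @inheritParams thatcherIndex
#' @param stimuli set from [makeHierarchicalStimuli()]
#' @param nBoot bootstrap resamples for the s.e.m.
#' @param seed bootstrap seed
#' @export
globalAdvantageIndex <- function(stimuli, table, metric = "euclidean",
                                 nBoot = 1000L, seed = 1L) {
  meta <- stimMeta(stimuli)
  if (nrow(meta) != 49 || !all(table(meta$g, meta$l) == 1))
    stop("incomplete 7 x 7 hierarchical grid")
  pr <- combn(nrow(meta), 2)
  sameL <- meta$l[pr[1, ]] == meta$l[pr[2, ]]
  sameG <- meta$g[pr[1, ]] == meta$g[pr[2, ]]
  globalPairs <- which(sameL & !sameG)
  localPairs <- which(sameG & !sameL)
  out <- .layerLoop(table, function(acts, l) {
    d <- .pairwiseDistances(acts, metric)
    dG <- mean(d[globalPairs]); dL <- mean(d[localPairs])
    idx <- contrastIndex(dG, dL)
    boots <- withr::with_seed(seed, vapply(seq_len(nBoot), function(b) {
      contrastIndex(mean(d[sample(globalPairs, replace = TRUE)]),
                    mean(d[sample(localPairs, replace = TRUE)]))
    }, numeric(1)))
    data.frame(layer = l - 1L, mean = idx, sem = sd(boots, na.rm = TRUE),
               n = length(globalPairs), excluded = sum(is.na(boots)),
               defined = !is.na(idx))
  })
  cbind(do.call(rbind, out),
        name = layerInfo(table)$name, kind = layerInfo(table)$kind)
}
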