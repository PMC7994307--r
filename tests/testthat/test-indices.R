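test_that("pixel Thatcher index is exactly zero for every face", {
  ts <- thatcherStimuli(smallFaces(4, seed = 2))
  prof <- thatcherIndex(ts, pixelTable(ts))
  expect_identical(prof$mean, 0)
  expect_identical(prof$sem, 0)
  expect_equal(prof$n, 4)
})

test_that("thatcher index reproduces constructed distances", {
  ## hand-built activations: d_upright = 2, d_inverted = 1
  m <- rbind(c(0, 0), c(2, 0), c(5, 0), c(5, 1))
  st <- StimulusSet(replicate(4, matrix(0, 8, 8), simplify = FALSE),
                    data.frame(face_id = 1,
                               orientation = c("upright", "upright",
                                               "inverted", "inverted"),
                               version = c("normal", "thatcherized",
                                           "normal", "thatcherized")), 1L)
  prof <- thatcherIndex(st, tableFromMatrix(m))
  expect_equal(prof$mean, 1 / 3)
})

test_that("mirror confusion hits +1 / -1 / 0 at the symmetry extremes", {
  sym <- matrix(0, 16, 16)
  sym[4:13, 6:11] <- 255                  # symmetric about both axes
  mkSet <- function(orig) {
    StimulusSet(list(orig, orig[nrow(orig):1, ], orig[, ncol(orig):1]),
                data.frame(object_id = 1,
                           role = c("original", "hmirror", "vmirror")), 1L)
  }
  ## vertically symmetric object: d_vertical = 0 -> +1 (if d_h > 0)
  obj <- sym; obj[3, 8:9] <- 255          # asymmetric up-down, symmetric left-right
  profV <- mirrorConfusionIndex(mkSet(obj), pixelTable(mkSet(obj)))
  expect_equal(profV$mean, 1)
  ## horizontally symmetric object: d_horizontal = 0 -> -1
  obj2 <- sym; obj2[8:9, 3] <- 255
  profH <- mirrorConfusionIndex(mkSet(obj2), pixelTable(mkSet(obj2)))
  expect_equal(profH$mean, -1)
  ## constructed equal distances -> 0
  m <- rbind(c(0, 0), c(0, 3), c(3, 0))
  st <- StimulusSet(replicate(3, matrix(0, 8, 8), simplify = FALSE),
                    data.frame(object_id = 1,
                               role = c("original", "hmirror", "vmirror")), 1L)
  expect_equal(mirrorConfusionIndex(st, tableFromMatrix(m))$mean, 0)
})

test_that("label-swap antisymmetry holds for mirror and part-break indices", {
  ms <- makeMirrorSet(4, seed = 6, size = 48)
  tab <- pixelTable(ms)
  prof <- mirrorConfusionIndex(ms, tab)
  meta <- stimMeta(ms)
  meta$role <- c(vmirror = "hmirror", hmirror = "vmirror",
                 original = "original")[meta$role]
  msSwap <- StimulusSet(images(ms), meta, stimSeed(ms))
  profSwap <- mirrorConfusionIndex(msSwap, tab)
  expect_equal(profSwap$mean, -prof$mean)
  po <- makePartObjects(seed = 2, size = 64)
  ptab <- pixelTable(po)
  pb <- partBreakIndex(po, ptab)
  pmeta <- stimMeta(po)
  pmeta$role <- c(break_natural = "break_unnatural",
                  break_unnatural = "break_natural",
                  whole = "whole", composite_natural = "composite_natural",
                  composite_unnatural = "composite_unnatural")[pmeta$role]
  pbSwap <- partBreakIndex(StimulusSet(images(po), pmeta, 1L), ptab)
  expect_equal(pbSwap$mean, -pb$mean)
})

test_that("scene incongruence responds to context perturbation size", {
  ## surrogate activations: object vector plus a context shift that is
  ## larger for the incongruent context
  set.seed(5)
  nObj <- 6
  imgs <- list(); rows <- list(); acts <- NULL
  for (o in seq_len(nObj)) {
    base <- rnorm(10)
    for (role in c("isolated", "congruent", "incongruent")) {
      shift <- switch(role, isolated = 0, congruent = 0.3, incongruent = 1.5)
      acts <- rbind(acts, base + shift * rnorm(10))
      imgs[[length(imgs) + 1]] <- matrix(0, 8, 8)
      rows[[length(rows) + 1]] <- data.frame(object_id = o, role = role)
    }
  }
  st <- StimulusSet(imgs, do.call(rbind, rows), 1L)
  prof <- sceneIncongruenceIndex(st, tableFromMatrix(acts))
  expect_gt(prof$mean, 0)
  ## congruent scene equal to the average exactly -> +1
  st1 <- StimulusSet(replicate(3, matrix(0, 8, 8), simplify = FALSE),
                     data.frame(object_id = 1,
                                role = c("isolated", "congruent", "incongruent")), 1L)
  m3 <- rbind(c(0, 0), c(1, 0), c(2, 0))   # mean is (1, 0), the congruent row
  p1 <- sceneIncongruenceIndex(st1, tableFromMatrix(m3), average = "all")
  expect_equal(p1$mean, 1)
  ## both scenes equidistant from the average -> 0
  m4 <- rbind(c(1, 0), c(0, 0), c(2, 0))
  p0 <- sceneIncongruenceIndex(st1, tableFromMatrix(m4), average = "all")
  expect_equal(p0$mean, 0)
})

test_that("normalization slopes match the averaging and summing laws", {
  mo <- makeMultiObjectDisplays(8, 30, 30, seed = 4, size = 48)
  avg <- extractFeatures(surrogateExtractor("averager",
                                            list(nObjects = 8, nUnits = 10, seed = 3)), mo)
  sl <- normalizationSlopes(mo, avg)
  expect_equal(sl$slope_pairs, 0.5, tolerance = 1e-12)
  expect_equal(sl$slope_triplets, 1 / 3, tolerance = 1e-12)
  sm <- extractFeatures(surrogateExtractor("summer",
                                           list(nObjects = 8, nUnits = 10, seed = 3)), mo)
  sl2 <- normalizationSlopes(mo, sm)
  expect_equal(sl2$slope_pairs, 1, tolerance = 1e-12)
  expect_equal(sl2$slope_triplets, 1, tolerance = 1e-12)
})

test_that("image-nonselective units give a trivial slope of 0.5", {
  ## unit-specific constant response to every display: response to AB equals
  ## response to A and to B, so AB = (A + B) / 2 across units
  mo <- makeMultiObjectDisplays(5, 12, 0, seed = 2, size = 48)
  meta <- stimMeta(mo)
  nUnits <- 7
  consts <- seq(0.2, 2, length.out = nUnits)
  acts <- matrix(rep(consts, each = nrow(meta)), nrow(meta), nUnits)
  ## add tiny per-location jitter so units pass the variance screen
  set.seed(9)
  for (u in seq_len(nUnits)) {
    sing <- meta$role == "singleton"
    acts[sing, u] <- acts[sing, u] + rnorm(sum(sing), sd = 1e-3)
    acts[!sing, u] <- consts[u] +
      vapply(which(!sing), function(r) {
        at <- unlist(meta[r, c("obj_at_loc1", "obj_at_loc2", "obj_at_loc3")])
        occ <- which(!is.na(at))
        mean(vapply(occ, function(l)
          acts[which(sing & meta$object_id == at[l] & meta$location == l), u],
          numeric(1))) - consts[u]
      }, numeric(1))
  }
  tab <- tableFromMatrix(acts)
  sl <- normalizationSlopes(StimulusSet(images(mo), meta, 1L), tab)
  expect_equal(sl$slope_pairs, 0.5, tolerance = 1e-6)
})

test_that("correlated sparseness recovers shared and independent tuning", {
  ss <- makeShapeSets(seed = 2, size = 48, nTextures = 12, nSilhouettes = 12)
  meta <- stimMeta(ss)
  n <- nrow(meta)
  ## per-unit threshold applied to a common within-subset rank position:
  ## equal-sized subsets then have identical sparseness vectors, so the
  ## correlation across units is exactly 1
  nUnits <- 30
  pos <- numeric(n)
  for (s in split(seq_len(n), meta$subset))
    pos[s] <- seq(0, 1, length.out = length(s))
  acts <- vapply(seq_len(nUnits), function(u)
    pmax(pos - u / (nUnits + 1), 0), numeric(n))
  tabS <- tableFromMatrix(acts)
  csS <- correlatedSparseness(StimulusSet(images(ss), meta, 1L), tabS)
  expect_equal(csS$r_texture_shape, 1, tolerance = 1e-8)
  expect_gt(csS$r_ref_morph, 0.99)
  ## independent random tuning across subsets: correlation near 0
  ss2 <- makeShapeSets(seed = 2, size = 48, nTextures = 64, nSilhouettes = 64)
  m2 <- stimMeta(ss2); n2 <- nrow(m2)
  set.seed(13)
  acts2 <- matrix(runif(n2 * 1000), n2, 1000)
  csI <- correlatedSparseness(StimulusSet(images(ss2), m2, 1L),
                              tableFromMatrix(acts2))
  expect_lt(abs(csI$r_texture_shape), 0.1)
  expect_lt(abs(csI$r_ref_morph), 0.1)
  ## a unit active in only one subset is excluded
  acts3 <- acts[, 1:10] + matrix(runif(n * 10, 0, 1e-3), n, 10)
  acts3[meta$subset == "texture", 1] <- 0.5   # constant on textures
  cs3 <- correlatedSparseness(StimulusSet(images(ss), meta, 1L),
                              tableFromMatrix(acts3))
  expect_equal(cs3$n_texture_shape, 9)
})

test_that("weber index recovers coding regimes from surrogates and pixels", {
  bars <- makeLengthBars(NULL, seed = 1, size = 64)
  lin <- weberIndex(bars, extractFeatures(surrogateExtractor("length_linear"), bars))
  expect_lt(lin$difference, 0)
  lg <- weberIndex(bars, extractFeatures(surrogateExtractor("length_log"), bars))
  expect_gt(lg$difference, 0)
  pxw <- weberIndex(bars, pixelTable(bars))
  expect_lt(pxw$difference, 0)
})

test_that("relative size index separates ratio and sum coders", {
  tet <- makeSizeTetrads(6, seed = 3, size = 48)
  ratio <- relativeSizeIndex(tet,
    extractFeatures(surrogateExtractor("size_ratio"), tet))
  expect_equal(ratio$mean, 1)
  sum_ <- relativeSizeIndex(tet,
    extractFeatures(surrogateExtractor("size_sum"), tet))
  expect_equal(sum_$mean, -1)
  ## selection keeps exactly ceiling(fraction * N) entries
  rt <- extractFeatures(surrogateExtractor("size_ratio",
                                           list(nUnits = 8)), tet)
  prof <- relativeSizeIndex(tet, rt, topFraction = 0.07)
  expect_equal(prof$n + prof$excluded, ceiling(0.07 * 8 * 6))
  ## a pixel representation has separable parts, hence zero interaction
  ## everywhere: the layer is flagged undefined, never imputed
  pxProf <- relativeSizeIndex(tet, pixelTable(tet))
  expect_false(pxProf$defined)
})

test_that("surface invariance index has the declared extremes and bounds", {
  st <- makeSurfaceTetrads(3, 2, seed = 2, size = 48)
  meta <- stimMeta(st)
  ## units coding pattern-relative-to-surface geometry: congruent cells equal
  relActs <- vapply(seq(0.5, 1.5, length.out = 6), function(g)
    g * meta$rel_geom, numeric(nrow(meta)))
  profRel <- surfaceInvarianceIndex(StimulusSet(images(st), meta, 1L),
                                    tableFromMatrix(relActs))
  expect_equal(profRel$mean, 1)
  ## units coding the retinal pattern level only have d1 = d2 cellwise
  ## (index 0) and zero interaction, so no entry survives selection and the
  ## layer is flagged undefined
  patActs <- vapply(seq(0.5, 1.5, length.out = 6), function(g)
    g * meta$pattern_level, numeric(nrow(meta)))
  r <- function(pl, sl) which(meta$tetrad_id == 1 & meta$pattern_level == pl &
                                meta$surface_level == sl)
  d1 <- abs(patActs[r(1, 2), 1] - patActs[r(2, 1), 1])
  d2 <- abs(patActs[r(1, 1), 1] - patActs[r(2, 2), 1])
  expect_equal(contrastIndex(d1, d2), 0)
  profPat <- surfaceInvarianceIndex(StimulusSet(images(st), meta, 1L),
                                    tableFromMatrix(patActs))
  expect_false(profPat$defined)
  pxProf <- surfaceInvarianceIndex(st, pixelTable(st))
  expect_lte(abs(pxProf$mean), 1)
})

test_that("3d and occlusion indices respect constructed distances", {
  d3 <- make3dPairs(seed = 1, size = 64)
  prof <- depth3dIndex(d3, pixelTable(d3))
  expect_true(all(abs(prof$mean) <= 1))
  expect_equal(nrow(prof), 2)          # two control conditions
  ## constructed: d1 = d2 -> 0 ; d2 = 0 -> +1
  mEq <- rbind(c(0, 0), c(3, 0), c(0, 0), c(3, 0), c(0, 0), c(3, 0))
  st <- StimulusSet(replicate(6, matrix(0, 8, 8), simplify = FALSE),
                    data.frame(family = "cuboid",
                               pair_type = rep(c("threeD", "control1", "control2"), each = 2),
                               member = rep(1:2, 3)), 1L)
  profEq <- depth3dIndex(st, tableFromMatrix(mEq))
  expect_equal(profEq$mean, c(0, 0))
  mZero <- rbind(c(0, 0), c(3, 0), c(1, 1), c(1, 1), c(2, 2), c(2, 2))
  profZ <- depth3dIndex(st, tableFromMatrix(mZero))
  expect_equal(profZ$mean, c(1, 1))
  ## occlusion: d1 = 0 -> +1 ; pixel route gives d1 > 0 so index < 1
  oc <- makeOcclusionDisplays(seed = 1, size = 64)
  ocProf <- occlusionIndex(oc, pixelTable(oc))
  expect_true(all(ocProf$mean < 1))
  mOcc <- rbind(c(0, 0), c(0, 0), c(1, 0), c(4, 0))
  stO <- StimulusSet(replicate(4, matrix(0, 8, 8), simplify = FALSE),
                     data.frame(effect = "occlusion",
                                role = c("unoccluded", "occluded",
                                         "control_a", "control_b")), 1L)
  profO <- occlusionIndex(stO, tableFromMatrix(mOcc))
  expect_equal(profO$mean, 1)
})

test_that("natural part advantage is positive under the natural generative model", {
  po <- makePartObjects(seed = 3, size = 64)
  meta <- stimMeta(po)
  natRows <- which(meta$role == "composite_natural")
  natRows <- natRows[order(meta$part1[natRows], meta$part2[natRows])]
  objects <- cbind(meta$part1[natRows], meta$part2[natRows])
  des <- buildPartSumDesign(objects, 7)
  gen <- partSumGenerativeDistances(des, noiseSd = 0, seed = 10)
  ## embed the generated distances: natural set follows the part-sum law
  ## exactly; the unnatural set scrambles all non-common pairs
  evalIdx <- commonPairIndices(des)
  dNat <- gen$distances
  dUnnat <- dNat
  scramble <- setdiff(seq_along(dNat), evalIdx)
  dUnnat[scramble] <- withr::with_seed(2, sample(dNat[scramble]))
  fitN <- fitPartSum(des, dNat)
  fitU <- fitPartSum(des, dUnnat)
  rN <- evaluatePartSum(fitN, evalIdx, dNat)
  rU <- evaluatePartSum(fitU, evalIdx, dUnnat)
  expect_equal(rN, 1, tolerance = 1e-9)
  expect_gt(rN - rU, 0)
  ## pure-noise distances: advantage centred on zero
  set.seed(77)
  advs <- vapply(1:40, function(i) {
    dA <- runif(nrow(des@design)); dB <- dA
    dB[scramble] <- runif(length(scramble))
    rA <- evaluatePartSum(fitPartSum(des, dA), evalIdx, dA)
    rB <- evaluatePartSum(fitPartSum(des, dB), evalIdx, dB)
    rA - rB
  }, numeric(1))
  expect_lt(abs(mean(advs)), 0.1)
})

test_that("natural part advantage runs end-to-end on images", {
  po <- makePartObjects(seed = 1, size = 64)
  adv <- naturalPartAdvantage(po, pixelTable(po))
  expect_true(is.finite(adv$advantage))
  expect_true(abs(adv$r_natural) <= 1 && abs(adv$r_unnatural) <= 1)
})

test_that("global advantage hits the pure-coding extremes and pair counts", {
  hs <- makeHierarchicalStimuli(seed = 1, size = 48)
  g <- globalAdvantageIndex(hs,
    extractFeatures(surrogateExtractor("global_only"), hs), nBoot = 50)
  expect_equal(g$mean, 1)
  l <- globalAdvantageIndex(hs,
    extractFeatures(surrogateExtractor("local_only"), hs), nBoot = 50)
  expect_equal(l$mean, -1)
  expect_equal(g$n, 147)   # 7 * choose(7, 2) global-change pairs
  ## incomplete grid errors
  expect_error(globalAdvantageIndex(hs[1:40],
    extractFeatures(surrogateExtractor("global_only"), hs[1:40])), "incomplete")
})
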