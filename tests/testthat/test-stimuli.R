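test_that("face generation is seeded, counted and boxed", {
  faces <- makeFaces(20, seed = 1, size = 64)
  expect_equal(nStimuli(faces), 20)
  expect_true(all(vapply(stimMeta(faces)$boxes, length, integer(1)) == 3))
  again <- makeFaces(1, seed = 7, size = 64)
  again2 <- makeFaces(1, seed = 7, size = 64)
  expect_identical(images(again), images(again2))
  a <- makeFaces(2, seed = 1, size = 64)
  b <- makeFaces(2, seed = 2, size = 64)
  expect_false(identical(images(a)[[1]], images(b)[[1]]))
  expect_error(makeFaces(1, seed = 1, size = 16), "too small")
})

test_that("thatcherize flips rows within boxes and is an involution", {
  img <- matrix(0, 10, 10)
  img[3, 3:6] <- 1; img[4, 3:6] <- 2      # rows (A, B) inside the box
  box <- boxRegion(2, 2, 4, 6)
  out <- thatcherize(img, list(box))
  expect_equal(out[3, 3:6], rep(2, 4))
  expect_equal(out[4, 3:6], rep(1, 4))
  expect_equal(out[5:10, ], img[5:10, ])  # untouched outside
  expect_identical(thatcherize(out, list(box)), img)
  ## vertically symmetric content inside the box is a fixed point
  sym <- matrix(0, 10, 10); sym[3, ] <- 5; sym[4, ] <- 5
  expect_identical(thatcherize(sym, list(box)), sym)
  expect_error(thatcherize(img, list(box, boxRegion(3, 3, 6, 8))), "overlap")
  expect_error(thatcherize(img, list(boxRegion(8, 8, 12, 12))), "bounds")
})

test_that("image inversion is a 180-degree rotation and involution", {
  m <- matrix(c(1, 2), 1, 2)
  m8 <- rbind(matrix(runif(7 * 8), 7, 8), c(1:8))  # 8x8 minimum respected below
  img <- matrix(runif(64), 8, 8)
  inv <- invertImage(img)
  expect_equal(inv[1, 1], img[8, 8])
  expect_identical(invertImage(inv), img)
  expect_equal(sum(inv), sum(img))
})

test_that("mirror set enforces asymmetry, rotation halves and mirror involution", {
  ms <- makeMirrorSet(8, seed = 3, size = 48)
  meta <- stimMeta(ms)
  expect_equal(nrow(meta), 24)
  expect_equal(sum(meta$role == "original"), 8)
  expect_error(makeMirrorSet(7, seed = 1), "even")
  for (o in unique(meta$object_id)) {
    orig <- images(ms)[[which(meta$object_id == o & meta$role == "original")]]
    vm <- images(ms)[[which(meta$object_id == o & meta$role == "vmirror")]]
    hm <- images(ms)[[which(meta$object_id == o & meta$role == "hmirror")]]
    expect_identical(vm[, ncol(vm):1], orig)      # v-mirror of v-mirror
    expect_false(identical(orig, vm))             # asymmetry enforced
    expect_false(identical(orig, hm))
  }
  ## second half are quarter-turned copies of the first half
  rot90 <- function(m) t(m[nrow(m):1, ])
  o1 <- images(ms)[[which(meta$object_id == 1 & meta$role == "original")]]
  o5 <- images(ms)[[which(meta$object_id == 5 & meta$role == "original")]]
  expect_identical(o5, rot90(o1))
})

test_that("scenes keep object pixels fixed across contexts", {
  sc <- makeScenes(4, seed = 2, size = 48)
  meta <- stimMeta(sc)
  expect_equal(sum(meta$role == "congruent"), 4)
  expect_equal(sum(meta$role == "incongruent"), 4)
  expect_error(makeScenes(1), "at least 2")
  iso <- images(sc)[[which(meta$object_id == 2 & meta$role == "isolated")]]
  con <- images(sc)[[which(meta$object_id == 2 & meta$role == "congruent")]]
  inc <- images(sc)[[which(meta$object_id == 2 & meta$role == "incongruent")]]
  mask <- iso > 0
  expect_identical(con[mask], inc[mask])  # identical object pixels, same place
  expect_false(identical(con[!mask], inc[!mask]))
})

test_that("multi-object displays are compositions of their singletons", {
  mo <- makeMultiObjectDisplays(5, 6, 4, seed = 5, size = 48)
  meta <- stimMeta(mo)
  expect_equal(sum(meta$role == "singleton"), 15)
  expect_equal(sum(meta$role == "pair"), 6)
  expect_equal(sum(meta$role == "triplet"), 4)
  prow <- which(meta$role == "pair")[1]
  at <- unlist(meta[prow, c("obj_at_loc1", "obj_at_loc2", "obj_at_loc3")])
  occ <- which(!is.na(at))
  comp <- Reduce(pmax, lapply(occ, function(l)
    images(mo)[[which(meta$role == "singleton" & meta$object_id == at[l] &
                        meta$location == l)]]))
  expect_identical(images(mo)[[prow]], comp)
  ## seeded reproducibility of the member lists
  m2 <- makeMultiObjectDisplays(5, 6, 4, seed = 5, size = 48)
  expect_identical(stimMeta(m2), meta)
  expect_error(makeMultiObjectDisplays(5, 1, 1, seed = 1, size = 48,
                                       objectRadius = 20), "overlap")
})

test_that("shape sets have the declared subsets and exact morph endpoints", {
  ss <- makeShapeSets(seed = 4, size = 48, nTextures = 10, nSilhouettes = 10)
  meta <- stimMeta(ss)
  expect_equal(sum(meta$subset == "reference"), 8)
  expect_equal(length(unique(meta$morphline[meta$subset == "morph"])), 4)
  expect_equal(sum(meta$subset == "texture"), 10)
  expect_equal(sum(meta$subset == "shape"), 10)
  ## morph parameter 0 reproduces endpoint A bit-identically
  m1a <- images(ss)[[which(meta$subset == "morph" & meta$morphline == 1 &
                             meta$alpha == 0)]]
  refA <- images(ss)[[which(meta$subset == "reference" & meta$shape_id == 1)]]
  expect_identical(m1a, refA)
  mid <- images(ss)[[which(meta$subset == "morph" & meta$morphline == 1 &
                             meta$alpha == 0.5)]]
  refB <- images(ss)[[which(meta$subset == "reference" & meta$shape_id == 2)]]
  expect_false(identical(mid, refA))
  expect_false(identical(mid, refB))
})

test_that("bars have exact pixel counts and a decorrelated default ladder", {
  bars <- makeLengthBars(c(16, 24, 32, 48), seed = 1, size = 64, thickness = 4)
  for (i in seq_len(4)) {
    L <- stimMeta(bars)$length[i]
    expect_equal(sum(images(bars)[[i]] > 0), 4 * L)
  }
  expect_error(makeLengthBars(c(16, 16, 24, 32)), "distinct")
  expect_error(makeLengthBars(c(16, 24, 32, 100), size = 64), "exceeds")
  expect_error(makeLengthBars(c(16, 24, 32)), "at least 4")
  dflt <- makeLengthBars(NULL, seed = 1, size = 64)
  L <- stimMeta(dflt)$length
  pr <- combn(length(L), 2)
  ab <- abs(L[pr[1, ]] - L[pr[2, ]])
  rel <- ab / (0.5 * (L[pr[1, ]] + L[pr[2, ]]))
  expect_lt(cor(ab, rel), 0.95)
})

test_that("size tetrads cross part sizes at two levels", {
  tet <- makeSizeTetrads(24, seed = 1, size = 48)
  meta <- stimMeta(tet)
  expect_equal(nrow(meta), 96)
  expect_equal(unname(unlist(meta[meta$s1 == 2 & meta$s2 == 2, c("scale1", "scale2")][1, ])),
               1.5 * unname(unlist(meta[meta$s1 == 1 & meta$s2 == 1, c("scale1", "scale2")][1, ])))
  i12 <- which(meta$tetrad_id == 1 & meta$s1 == 1 & meta$s2 == 2)
  i21 <- which(meta$tetrad_id == 1 & meta$s1 == 2 & meta$s2 == 1)
  expect_false(identical(images(tet)[[i12]], images(tet)[[i21]]))
})

test_that("surface tetrads share relative geometry on congruent cells", {
  st <- makeSurfaceTetrads(6, 4, seed = 1, size = 48)
  meta <- stimMeta(st)
  expect_equal(length(unique(meta$tetrad_id)), 24)
  for (tt in c(1, 24)) {
    sub <- meta[meta$tetrad_id == tt, ]
    r11 <- sub$rel_geom[sub$pattern_level == 1 & sub$surface_level == 1]
    r22 <- sub$rel_geom[sub$pattern_level == 2 & sub$surface_level == 2]
    r12 <- sub$rel_geom[sub$pattern_level == 1 & sub$surface_level == 2]
    expect_equal(r11, r22)
    expect_false(isTRUE(all.equal(r11, r12)))
  }
  st2 <- makeSurfaceTetrads(6, 4, seed = 1, size = 48)
  expect_identical(images(st), images(st2))
})

test_that("3d pair families share an identical changed-stroke mask", {
  d3 <- make3dPairs(seed = 1, size = 64)
  meta <- stimMeta(d3)
  expect_equal(nStimuli(d3), 18)
  for (fam in unique(meta$family)) {
    masks <- lapply(c("threeD", "control1", "control2"), function(pt) {
      m1 <- images(d3)[[which(meta$family == fam & meta$pair_type == pt & meta$member == 1)]]
      m2 <- images(d3)[[which(meta$family == fam & meta$pair_type == pt & meta$member == 2)]]
      m1 != m2
    })
    expect_identical(masks[[1]], masks[[2]])
    expect_identical(masks[[1]], masks[[3]])
  }
  expect_identical(images(make3dPairs(seed = 1, size = 64)), images(d3))
})

test_that("occlusion displays respect their composition contracts", {
  oc <- makeOcclusionDisplays(seed = 1, size = 64)
  meta <- stimMeta(oc)
  expect_setequal(unique(meta$effect), c("occlusion", "depth_order"))
  expect_setequal(meta$role[meta$effect == "occlusion"],
                  c("unoccluded", "occluded", "control_a", "control_b"))
  img <- function(eff, role) images(oc)[[which(meta$effect == eff & meta$role == role)]]
  ## occluded equals unoccluded outside the recorded diff region
  row1 <- meta[meta$effect == "occlusion" & meta$role == "occluded", ]
  inBox <- function(m) {
    r <- row(m); cc <- col(m)
    r > row1$diff_top & r <= row1$diff_bottom & cc > row1$diff_left & cc <= row1$diff_right
  }
  u <- img("occlusion", "unoccluded"); o <- img("occlusion", "occluded")
  expect_identical(u[!inBox(u)], o[!inBox(o)])
  ## control pair carries the same pixelwise feature difference
  ca <- img("occlusion", "control_a"); cb <- img("occlusion", "control_b")
  expect_identical(u != o, ca != cb)
  ## the two depth orders differ only inside the overlap region
  o1 <- img("depth_order", "over1"); o2 <- img("depth_order", "over2")
  d <- which(o1 != o2, arr.ind = TRUE)
  row2 <- meta[meta$effect == "depth_order" & meta$role == "over1", ]
  expect_true(all(d[, 1] > row2$diff_top & d[, 1] <= row2$diff_bottom))
  expect_true(all(d[, 2] > row2$diff_left & d[, 2] <= row2$diff_right))
})

test_that("part objects: counts, area-preserving breaks, common set", {
  po <- makePartObjects(seed = 1, size = 64)
  meta <- stimMeta(po)
  expect_equal(sum(meta$role == "composite_natural"), 49)
  expect_equal(sum(meta$role == "composite_unnatural"), 49)
  expect_equal(sum(meta$common & meta$role == "composite_natural"), 7)
  for (o in 1:7) {
    whole <- images(po)[[which(meta$role == "whole" & meta$object_id == o)]]
    bn <- images(po)[[which(meta$role == "break_natural" & meta$object_id == o)]]
    bu <- images(po)[[which(meta$role == "break_unnatural" & meta$object_id == o)]]
    expect_equal(sum(bn > 0), sum(whole > 0))
    expect_equal(sum(bu > 0), sum(whole > 0))
  }
  ## diagonal composites reproduce the originals in both sets
  w3 <- images(po)[[which(meta$role == "whole" & meta$object_id == 3)]]
  cn <- images(po)[[which(meta$role == "composite_natural" & meta$part1 == 3 & meta$part2 == 3)]]
  cu <- images(po)[[which(meta$role == "composite_unnatural" & meta$part1 == 3 & meta$part2 == 3)]]
  expect_identical(cn, w3)
  expect_identical(cu, w3)
  expect_identical(images(makePartObjects(seed = 1, size = 64)), images(po))
})

test_that("hierarchical stimuli share positions within g and shapes within l", {
  hs <- makeHierarchicalStimuli(seed = 1, size = 64)
  meta <- stimMeta(hs)
  expect_equal(nStimuli(hs), 49)
  expect_equal(as.vector(table(meta$g)), rep(7, 7))
  img <- function(g, l) images(hs)[[which(meta$g == g & meta$l == l)]]
  ## same g, different l: same positions (bounding pattern), different glyphs
  expect_false(identical(img(1, 1), img(1, 2)))
  ## same l, different g: different positions
  expect_false(identical(img(1, 1), img(2, 1)))
  ## the (g, l) and (g, l') elements are centred at the same positions: the
  ## union of foreground differs but both are nonempty and of equal count
  ## per element shape across arrangements
  expect_equal(sum(img(1, 1) > 0) > 0, TRUE)
})

test_that("all generated images satisfy the range and dimension invariants", {
  sets <- list(makeFaces(2, 1, 64), makeMirrorSet(2, 1, 48),
               makeScenes(2, 1, 48), makeLengthBars(NULL, 1, 48),
               makeSizeTetrads(1, 1, 48), makeSurfaceTetrads(2, 2, 1, 48),
               make3dPairs(1, 48), makeOcclusionDisplays(1, 48),
               makeHierarchicalStimuli(1, 48))
  for (s in sets) {
    for (im in images(s)) {
      expect_true(all(is.finite(im)))
      expect_gte(min(im), 0)
      expect_lte(max(im), 255)
      expect_gte(nrow(im), 8)
    }
  }
})

test_that("stimulus sets export to PNG with a sidecar and round-trip", {
  dir <- withr::local_tempdir()
  bars <- makeLengthBars(c(8, 12, 16, 24), seed = 1, size = 48)
  paths <- writeStimulusSet(bars, dir, sidecar = "json")
  expect_true(all(file.exists(paths)))
  back <- png::readPNG(paths[1]) * 255
  expect_equal(round(back), images(bars)[[1]], tolerance = 1e-8)
  side <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  expect_equal(side$meta$length, stimMeta(bars)$length)
})
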