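#' Names of the twelve battery experiments
#'
#' @return character vector of experiment keys, in canonical order
#' @export
batteryExperiments <- function() {
  c("thatcher", "mirror", "scene", "normalization", "sparseness", "weber",
    "relative_size", "surface", "depth3d", "occlusion", "parts",
    "global_local")
}

#' Battery configuration
#'
#' Collects every knob of a battery run: the extractor, the experiment
#' subset, the distance metric, canvas size, seeds, stimulus-set sizes
#' (defaulting to the study conditions: 20 faces, 100 mirror objects, 40
#' scene objects, 49 objects x 3 locations with 200 pairs and 200 triplets,
#' 24 size tetrads, 6 patterns x 4 surfaces, 128 textures and silhouettes)
#' and the tetrad top fractions (7 and 9 percent).
#'
#' @param extractor \code{"pixel"}, \code{"refnet"}, or an extractor object
#'   obeying the contract of [extractFeatures()]
#' @param experiments subset of [batteryExperiments()]
#' @param metric distance metric
#' @param imageSize canvas side length in pixels
#' @param seed master seed; per-experiment stimulus seeds are derived from it
#' @param refnetWidth width multiplier for the reference convnet
#' @param nFaces,nMirrorObjects,nSceneObjects,nMultiObjects,nPairs,nTriplets
#'   stimulus-set sizes
#' @param nSizeTetrads,nPatterns,nSurfaces,nTextures,nSilhouettes more sizes
#' @param topFractionSize,topFractionSurface tetrad selection fractions in
#'   (0, 1]
#' @param nUnitsSample cap on units pooled in the normalization-slope fit
#' @param nBoot bootstrap resamples for the global-advantage s.e.m.
#' @return a validated config list of class \code{batteryConfig}
#' @export
batteryConfig <- function(extractor = "refnet",
                          experiments = batteryExperiments(),
                          metric = "euclidean", imageSize = 64L, seed = 1L,
                          refnetWidth = 1, nFaces = 20L,
                          nMirrorObjects = 100L, nSceneObjects = 40L,
                          nMultiObjects = 49L, nPairs = 200L,
                          nTriplets = 200L, nSizeTetrads = 24L,
                          nPatterns = 6L, nSurfaces = 4L, nTextures = 128L,
                          nSilhouettes = 128L, topFractionSize = 0.07,
                          topFractionSurface = 0.09, nUnitsSample = 2000L,
                          nBoot = 500L) {
  bad <- setdiff(experiments, batteryExperiments())
  if (length(bad)) stop("unknown experiment(s): ", paste(bad, collapse = ", "))
  stopifnot(topFractionSize > 0, topFractionSize <= 1,
            topFractionSurface > 0, topFractionSurface <= 1,
            imageSize >= 48)
  cfg <- as.list(environment())
  class(cfg) <- "batteryConfig"
  cfg
}

#' Read a battery configuration from JSON or YAML
#'
#' @param path file path; extension selects the parser
#' @return a \code{batteryConfig}
#' @export
readBatteryConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(batteryConfig, vals)
}

## Rolling polynomial hash of the deparsed config; provenance only.
.configHash <- function(cfg) {
  bytes <- as.integer(charToRaw(paste(deparse(unclass(cfg)), collapse = "")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.expSeed <- function(cfg, exp) {
  (cfg$seed + 101L + match(exp, batteryExperiments())) %% .Machine$integer.max
}

.buildExtractor <- function(cfg) {
  if (inherits(cfg$extractor, "perceptExtractor")) return(cfg$extractor)
  switch(cfg$extractor,
    pixel = pixelExtractor(),
    refnet = referenceConvnet(cfg$seed, cfg$refnetWidth, cfg$imageSize),
    stop("unknown extractor spec: ", cfg$extractor))
}

## Per-experiment stimulus generation at the configured conditions.
.expStimuli <- function(cfg, exp) {
  s <- .expSeed(cfg, exp); sz <- cfg$imageSize
  switch(exp,
    thatcher = thatcherStimuli(makeFaces(cfg$nFaces, s, sz)),
    mirror = makeMirrorSet(cfg$nMirrorObjects, s, sz),
    scene = makeScenes(cfg$nSceneObjects, s, sz),
    normalization = makeMultiObjectDisplays(cfg$nMultiObjects, cfg$nPairs,
                                            cfg$nTriplets, s, sz),
    sparseness = makeShapeSets(s, sz, cfg$nTextures, cfg$nSilhouettes),
    weber = makeLengthBars(NULL, s, sz),
    relative_size = makeSizeTetrads(cfg$nSizeTetrads, s, sz),
    surface = makeSurfaceTetrads(cfg$nPatterns, cfg$nSurfaces, s, sz),
    depth3d = make3dPairs(s, sz),
    occlusion = makeOcclusionDisplays(s, sz),
    parts = makePartObjects(s, sz),
    global_local = makeHierarchicalStimuli(s, sz))
}

.profRows <- function(exp, prof, measure = "index") {
  data.frame(experiment = exp, layer = prof$layer, name = prof$name,
             kind = prof$kind, measure = measure, mean = prof$mean,
             sem = prof$sem, n = prof$n,
             excluded = if ("excluded" %in% names(prof)) prof$excluded else 0L,
             defined = prof$defined, stringsAsFactors = FALSE)
}

## Run one experiment: returns tidy rows; rows with measure == "index" carry
## the experiment's presence measure.
.runExperiment <- function(cfg, exp, stim, tab) {
  metric <- cfg$metric
  switch(exp,
    thatcher = .profRows(exp, thatcherIndex(stim, tab, metric)),
    mirror = .profRows(exp, mirrorConfusionIndex(stim, tab, metric)),
    scene = .profRows(exp, sceneIncongruenceIndex(stim, tab, metric)),
    normalization = {
      sl <- normalizationSlopes(stim, tab, cfg$nUnitsSample, cfg$seed)
      prox <- function(x, target) 1 - abs(x - target) / target
      idx <- pmin(prox(sl$slope_pairs, 0.5), prox(sl$slope_triplets, 1 / 3))
      rows <- data.frame(experiment = exp, layer = sl$layer, name = sl$name,
                         kind = sl$kind, measure = "index", mean = idx,
                         sem = 0, n = sl$n_units, excluded = 0L,
                         defined = sl$defined, stringsAsFactors = FALSE)
      extra <- do.call(rbind, lapply(c("slope_pairs", "slope_triplets"),
        function(ms) data.frame(experiment = exp, layer = sl$layer,
                                name = sl$name, kind = sl$kind, measure = ms,
                                mean = sl[[ms]], sem = NA_real_,
                                n = sl$n_units, excluded = 0L,
                                defined = sl$defined,
                                stringsAsFactors = FALSE)))
      rbind(rows, extra)
    },
    sparseness = {
      cs <- correlatedSparseness(stim, tab)
      idx <- pmin(cs$r_ref_morph, cs$r_texture_shape)
      rows <- data.frame(experiment = exp, layer = cs$layer, name = cs$name,
                         kind = cs$kind, measure = "index", mean = idx,
                         sem = 0, n = pmin(cs$n_ref_morph, cs$n_texture_shape),
                         excluded = 0L, defined = cs$defined & !is.na(idx),
                         stringsAsFactors = FALSE)
      extra <- do.call(rbind, lapply(c("r_ref_morph", "r_texture_shape"),
        function(ms) data.frame(experiment = exp, layer = cs$layer,
                                name = cs$name, kind = cs$kind, measure = ms,
                                mean = cs[[ms]], sem = NA_real_,
                                n = cs$n_ref_morph, excluded = 0L,
                                defined = !is.na(cs[[ms]]),
                                stringsAsFactors = FALSE)))
      rbind(rows, extra)
    },
    weber = {
      w <- weberIndex(stim, tab, metric)
      data.frame(experiment = exp, layer = w$layer, name = w$name,
                 kind = w$kind, measure = "index", mean = w$difference,
                 sem = 0, n = w$n, excluded = 0L, defined = w$defined,
                 stringsAsFactors = FALSE)
    },
    relative_size = .profRows(exp,
      relativeSizeIndex(stim, tab, cfg$topFractionSize)),
    surface = .profRows(exp,
      surfaceInvarianceIndex(stim, tab, cfg$topFractionSurface)),
    depth3d = {
      pr <- depth3dIndex(stim, tab, metric)
      byCond <- lapply(split(pr, pr$condition), function(d)
        data.frame(experiment = exp, layer = d$layer, name = d$name,
                   kind = d$kind, measure = paste0("index_cond", d$condition[1]),
                   mean = d$mean, sem = d$sem, n = d$n, excluded = d$excluded,
                   defined = d$defined, stringsAsFactors = FALSE))
      agg <- stats::aggregate(cbind(mean, sem) ~ layer + name + kind,
                              data = pr, FUN = mean)
      agg <- agg[order(agg$layer), ]
      rows <- data.frame(experiment = exp, layer = agg$layer, name = agg$name,
                         kind = agg$kind, measure = "index", mean = agg$mean,
                         sem = agg$sem, n = pr$n[1],
                         excluded = 0L, defined = !is.na(agg$mean),
                         stringsAsFactors = FALSE)
      rbind(rows, do.call(rbind, byCond))
    },
    occlusion = {
      pr <- occlusionIndex(stim, tab, metric)
      byEff <- lapply(split(pr, pr$effect), function(d)
        data.frame(experiment = exp, layer = d$layer, name = d$name,
                   kind = d$kind, measure = paste0("index_", d$effect[1]),
                   mean = d$mean, sem = d$sem, n = d$n, excluded = d$excluded,
                   defined = d$defined, stringsAsFactors = FALSE))
      agg <- stats::aggregate(mean ~ layer + name + kind, data = pr, FUN = mean)
      agg <- agg[order(agg$layer), ]
      rows <- data.frame(experiment = exp, layer = agg$layer, name = agg$name,
                         kind = agg$kind, measure = "index", mean = agg$mean,
                         sem = 0, n = 2L, excluded = 0L,
                         defined = !is.na(agg$mean), stringsAsFactors = FALSE)
      rbind(rows, do.call(rbind, byEff))
    },
    parts = {
      rows <- .profRows(exp, partBreakIndex(stim, tab, metric))
      adv <- naturalPartAdvantage(stim, tab, metric)
      extra <- do.call(rbind, lapply(c("advantage", "r_natural", "r_unnatural"),
        function(ms) data.frame(experiment = exp, layer = adv$layer,
                                name = adv$name, kind = adv$kind,
                                measure = ms, mean = adv[[ms]],
                                sem = NA_real_, n = 21L, excluded = 0L,
                                defined = adv$defined,
                                stringsAsFactors = FALSE)))
      rbind(rows, extra)
    },
    global_local = .profRows(exp,
      globalAdvantageIndex(stim, tab, metric, nBoot = cfg$nBoot,
                           seed = cfg$seed)))
}

#' Presence verdict from a per-layer profile
#'
#' The battery deems a property present in a representation when, at the
#' last fully connected layer, the mean index is positive and its magnitude
#' exceeds its s.e.m.; \code{"undefined"} when that layer is flagged
#' undefined.  The rule (sign plus s.e.m. exclusion of zero) is the
#' package's operationalization of presence at the last fc layer and is
#' recorded with the verdict.
#'
#' @param rows tidy rows for one experiment (must contain \code{measure ==
#'   "index"} rows and at least one \code{fc} layer)
#' @return \code{"present"}, \code{"absent"} or \code{"undefined"}
#' @export
presenceVerdict <- function(rows) {
  rows <- rows[rows$measure == "index", , drop = FALSE]
  fc <- rows[rows$kind == "fc", , drop = FALSE]
  if (!nrow(fc)) {
    ## single-layer profiles (e.g. the pixel representation) are judged at
    ## their only layer; deeper profiles must expose an fc layer
    if (length(unique(rows$layer)) > 1L)
      stop("no fully connected layer in profile")
    fc <- rows
  }
  last <- fc[which.max(fc$layer), ]
  if (!isTRUE(last$defined) || is.na(last$mean)) return("undefined")
  sem <- if (is.na(last$sem)) 0 else last$sem
  if (last$mean > 0 && abs(last$mean) > sem) "present" else "absent"
}

#' Run the battery
#'
#' Generates the stimulus sets for every requested experiment (seeded from
#' the config), extracts activations with the configured extractor, computes
#' each index profile and assembles a \linkS4class{BatteryReport} with tidy
#' results, one presence verdict per experiment, and provenance (config
#' hash, seed, package version).  Reruns with an identical config reproduce
#' identical results.
#'
#' @param config a [batteryConfig()]
#' @param verbose log experiment progress to standard error
#' @return a \linkS4class{BatteryReport}
#' @export
runBattery <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "batteryConfig"))
  extractor <- .buildExtractor(config)
  allRows <- list(); verdicts <- list()
  for (exp in config$experiments) {
    if (verbose) message("[battery] ", exp)
    stim <- .expStimuli(config, exp)
    tab <- extractFeatures(extractor, stim)
    rows <- .runExperiment(config, exp, stim, tab)
    allRows[[exp]] <- rows
    verdicts[[exp]] <- data.frame(experiment = exp,
                                  verdict = presenceVerdict(rows),
                                  stringsAsFactors = FALSE)
  }
  new("BatteryReport",
      results = do.call(rbind, c(allRows, list(make.row.names = FALSE))),
      verdicts = do.call(rbind, c(verdicts, list(make.row.names = FALSE))),
      config = unclass(config),
      provenance = list(config_hash = .configHash(config),
                        seed = config$seed,
                        extractor = extractor$id,
                        rule = "present iff mean > 0 and |mean| > sem at last fc layer",
                        package_version = as.character(utils::packageVersion("perceptBattery"))))
}

#' Bundled human/monkey reference constants
#'
#' Numeric values from prior perceptual and neurophysiological studies,
#' carried as plot annotations only, each with a provenance string.
#'
#' @return \code{data.frame} with columns \code{experiment}, \code{measure},
#'   \code{value}, \code{provenance}
#' @export
referenceConstants <- function() {
  path <- system.file("extdata", "reference_constants.json",
                      package = "perceptBattery")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a battery report to disk
#'
#' Writes \code{results.csv} (the tidy table), \code{summary.json}
#' (verdicts, provenance and config) and, optionally, one PNG profile plot
#' per experiment with layer-kind glyphs (unfilled circle = conv, filled
#' circle = relu, diamond = pool, unfilled square = fc) and dashed
#' reference-constant annotations.
#'
#' @param report a \linkS4class{BatteryReport}
#' @param dir output directory (created if missing)
#' @param plots also write profile plots
#' @return invisibly, the paths written
#' @export
writeBatteryReport <- function(report, dir, plots = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "results.csv")
  utils::write.csv(report@results, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  jsonlite::write_json(list(verdicts = report@verdicts,
                            provenance = report@provenance,
                            config = report@config[!vapply(report@config, is.object, logical(1))]),
                       js, auto_unbox = TRUE, digits = NA, force = TRUE)
  paths <- c(csv, js)
  if (plots) {
    glyph <- c(input = 3, conv = 1, relu = 16, pool = 5, fc = 0, softmax = 2)
    consts <- tryCatch(referenceConstants(), error = function(e) NULL)
    for (exp in unique(report@results$experiment)) {
      d <- report@results
      d <- d[d$experiment == exp & d$measure == "index", , drop = FALSE]
      p <- file.path(dir, paste0("profile_", exp, ".png"))
      grDevices::png(p, width = 720, height = 480)
      plot(d$layer, d$mean, type = "l", xlab = "layer",
           ylab = "index", main = exp, ylim = range(c(d$mean - d$sem,
                                                      d$mean + d$sem, 0),
                                                    na.rm = TRUE))
      graphics::arrows(d$layer, d$mean - d$sem, d$layer, d$mean + d$sem,
                       angle = 90, code = 3, length = 0.02)
      graphics::points(d$layer, d$mean, pch = glyph[d$kind])
      graphics::abline(h = 0, col = "gray")
      if (!is.null(consts)) {
        cc <- consts[consts$experiment == exp, , drop = FALSE]
        if (nrow(cc)) graphics::abline(h = cc$value, lty = 2)
      }
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
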