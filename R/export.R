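#' Export a stimulus set as PNG files plus a metadata sidecar
#'
#' Writes one lossless 8-bit grayscale PNG per image, named
#' \code{{index:04d}_{tags}.png} where the tag string concatenates the
#' image's non-missing meta values, plus a single sidecar
#' (\code{metadata.json} or \code{metadata.csv}) holding the full tag table,
#' the seed, and the file names.
#'
#' @param stimuli a \linkS4class{StimulusSet}
#' @param dir output directory (created if missing)
#' @param sidecar \code{"json"} or \code{"csv"}
#' @return invisibly, the written file paths
#' @export
writeStimulusSet <- function(stimuli, dir, sidecar = c("json", "csv")) {
  sidecar <- match.arg(sidecar)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- stimMeta(stimuli)
  simple <- meta[, !vapply(meta, is.list, logical(1)), drop = FALSE]
  tagStr <- function(i) {
    vals <- unlist(lapply(simple[i, , drop = FALSE], as.character))
    vals <- vals[!is.na(vals) & nzchar(vals)]
    s <- paste(vals, collapse = "-")
    gsub("[^A-Za-z0-9._-]", "_", substr(s, 1, 60))
  }
  files <- vapply(seq_len(nStimuli(stimuli)), function(i) {
    f <- sprintf("%04d_%s.png", i - 1L, tagStr(i))
    png::writePNG(images(stimuli)[[i]] / 255, file.path(dir, f))
    f
  }, character(1))
  simple$file <- files
  if (sidecar == "json") {
    sp <- file.path(dir, "metadata.json")
    jsonlite::write_json(list(seed = stimSeed(stimuli), meta = simple), sp,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    sp <- file.path(dir, "metadata.csv")
    utils::write.csv(simple, sp, row.names = FALSE)
  }
  invisible(c(file.path(dir, files), sp))
}
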