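#' Dissimilarity between two activation vectors
#'
#' @param x,y numeric vectors of equal length
#' @param metric \code{"euclidean"} (default), \code{"cityblock"} or
#'   \code{"pearson"} (one minus the Pearson correlation; errors on
#'   zero-variance input)
#' @return nonnegative dissimilarity (symmetric; zero iff \code{x == y} for
#'   euclidean/cityblock)
#' @export
featureDistance <- function(x, y, metric = c("euclidean", "cityblock", "pearson")) {
  metric <- match.arg(metric)
  if (length(x) != length(y)) stop("dimension mismatch")
  switch(metric,
    euclidean = sqrt(sum((x - y)^2)),
    cityblock = sum(abs(x - y)),
    pearson = {
      if (sd(x) == 0 || sd(y) == 0)
        stop("zero-variance vector under correlation metric")
      1 - cor(x, y)
    })
}

## All pairwise distances between rows of a matrix, as a dist-ordered vector.
.pairwiseDistances <- function(m, metric = "euclidean") {
  switch(metric,
    euclidean = as.vector(dist(m, method = "euclidean")),
    cityblock = as.vector(dist(m, method = "manhattan")),
    pearson = {
      sds <- apply(m, 1, sd)
      if (any(sds == 0)) stop("zero-variance vector under correlation metric")
      as.vector(as.dist(1 - cor(t(m))))
    })
}

#' Normalized contrast index
#'
#' The shared form of all indices in the battery: \code{(dA - dB) / (dA +
#' dB)}, bounded in \code{[-1, 1]} and antisymmetric under swapping the two
#' distances.  When \code{dA + dB == 0} the index is undefined and \code{NA}
#' is returned; callers exclude such items and count them.
#'
#' @param dA,dB nonnegative finite dissimilarities (vectorized)
#' @return index value(s) in \code{[-1, 1]}, \code{NA} where undefined
#' @export
contrastIndex <- function(dA, dB) {
  stopifnot(all(dA >= 0), all(dB >= 0), all(is.finite(dA)), all(is.finite(dB)))
  out <- (dA - dB) / (dA + dB)
  out[dA + dB == 0] <- NA_real_
  out
}

#' Aggregate per-item indices into a per-layer profile
#'
#' Means and s.e.m. (= sd / sqrt(n)) are computed over defined (non-NA)
#' items; undefined items are excluded and counted, never imputed.  A layer
#' with zero defined items is flagged \code{defined = FALSE} rather than
#' dropped.
#'
#' @param valuesByLayer list (one element per layer) of per-item index
#'   vectors, possibly containing \code{NA}
#' @param layers optional layer \code{data.frame} to attach
#' @return \code{data.frame} with columns \code{layer}, \code{name},
#'   \code{kind}, \code{mean}, \code{sem}, \code{n}, \code{excluded},
#'   \code{defined}
#' @export
aggregateProfile <- function(valuesByLayer, layers = NULL) {
  nl <- length(valuesByLayer)
  if (is.null(layers))
    layers <- .layerDf(paste0("layer", seq_len(nl) - 1L), rep("fc", nl))
  out <- lapply(seq_len(nl), function(l) {
    v <- valuesByLayer[[l]]
    ok <- v[!is.na(v)]
    n <- length(ok)
    data.frame(layer = layers$index[l], name = layers$name[l],
               kind = layers$kind[l],
               mean = if (n) mean(ok) else NA_real_,
               sem = if (n > 1) sd(ok) / sqrt(n) else if (n == 1) 0 else NA_real_,
               n = n, excluded = length(v) - n, defined = n > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Select visually active units
#'
#' A unit is kept when its response variance exceeds \code{tol} (relative to
#' the unit's mean-square response) on every required stimulus subset.  With
#' a single subset this is the non-zero-variance rule; with several (e.g.
#' the three singleton locations of the multiple-object analysis) the unit
#' must vary within each subset.
#'
#' @param acts stimuli-by-unit activation matrix
#' @param subsets list of row-index vectors, one per required subset
#' @param tol relative variance tolerance
#' @return logical unit mask
#' @export
selectVisuallyActive <- function(acts, subsets, tol = 1e-12) {
  stopifnot(length(subsets) >= 1, all(lengths(subsets) > 0))
  keep <- rep(TRUE, ncol(acts))
  for (idx in subsets) {
    sub <- acts[idx, , drop = FALSE]
    v <- apply(sub, 2, var)
    msq <- colMeans(sub^2)
    keep <- keep & v > tol * pmax(msq, .Machine$double.eps)
  }
  keep
}

#' Min-max normalize a unit's responses to [0, 1]
#'
#' @param responses numeric vector, non-constant
#' @return affinely rescaled vector with min 0 and max 1
#' @export
normalizeUnit <- function(responses) {
  rng <- range(responses)
  if (diff(rng) == 0)
    stop("constant unit: pre-filter with selectVisuallyActive")
  (responses - rng[1]) / diff(rng)
}

#' Response sparseness
#'
#' \code{S = (1 - (sum(r)/n)^2 / sum(r^2/n)) / (1 - 1/n)} for nonnegative
#' responses \code{r_1..r_n}: 0 for uniform responses, 1 for a one-hot
#' response, invariant to positive rescaling.  An all-zero vector is
#' undefined and returns \code{NA} (the unit is excluded upstream).
#'
#' @param responses nonnegative numeric vector
#' @param n number of stimuli (defaults to \code{length(responses)})
#' @return sparseness in \code{[0, 1]}, or \code{NA}
#' @export
sparseness <- function(responses, n = length(responses)) {
  stopifnot(n >= 2, all(responses >= 0))
  s2 <- sum(responses^2) / n
  if (s2 == 0) return(NA_real_)
  (1 - (sum(responses) / n)^2 / s2) / (1 - 1 / n)
}

#' Correlation of unit sparseness between two stimulus subsets
#'
#' @param sA,sB sparseness per unit on subsets A and B (aligned; \code{NA}
#'   entries are dropped pairwise)
#' @return Pearson correlation across units, or \code{NA} when fewer than 3
#'   units remain or a subset has degenerate variance
#' @export
sparsenessCorrelation <- function(sA, sB) {
  ok <- !is.na(sA) & !is.na(sB)
  if (sum(ok) < 3) return(NA_real_)
  if (sd(sA[ok]) == 0 || sd(sB[ok]) == 0) return(NA_real_)
  cor(sA[ok], sB[ok])
}

#' Ordinary least-squares slope with free intercept
#'
#' @param x,y numeric vectors; \code{var(x)} must be positive
#' @return the fitted slope
#' @export
fitSlope <- function(x, y) {
  if (length(x) < 2 || var(x) == 0) stop("need >= 2 points with var(x) > 0")
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Correlations of pairwise dissimilarity with absolute and relative length
#' differences
#'
#' Over all unordered pairs (i, j): the absolute difference \code{|Li - Lj|}
#' and the relative difference \code{|Li - Lj| / (0.5 (Li + Lj))}.  Reports
#' the Pearson correlations \code{r_abs} and \code{r_rel} of the supplied
#' dissimilarities with each predictor, and their difference: positive
#' \code{r_rel - r_abs} indicates Weber's-law-like coding.
#'
#' @param lengths bar lengths (>= 4 values so the predictors decorrelate)
#' @param distances pairwise dissimilarities in \code{dist} order (columnwise
#'   lower triangle), length \code{choose(length(lengths), 2)}
#' @return one-row \code{data.frame} with \code{r_abs}, \code{r_rel},
#'   \code{difference}
#' @export
weberCorrelations <- function(lengths, distances) {
  if (length(lengths) < 4)
    stop("need >= 4 lengths: with fewer the predictors are collinear")
  pr <- combn(length(lengths), 2)
  dAbs <- abs(lengths[pr[1, ]] - lengths[pr[2, ]])
  dRel <- dAbs / (0.5 * (lengths[pr[1, ]] + lengths[pr[2, ]]))
  ## dist order is columnwise over i > j, matching combn order
  if (length(distances) != ncol(pr)) stop("distances length mismatch")
  data.frame(r_abs = cor(dAbs, distances), r_rel = cor(dRel, distances),
             difference = cor(dRel, distances) - cor(dAbs, distances))
}

#' Convert a search time or slope into a perceptual distance
#'
#' @param t positive search time (seconds) or search slope
#' @return \code{1 / t}
#' @export
reciprocalDistance <- function(t) {
  if (any(t <= 0)) stop("search time/slope must be positive")
  1 / t
}
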