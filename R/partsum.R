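#' Build the part-sum model design matrix
#'
#' For two-part objects labelled \code{(part at location 1, part at location
#' 2)}, each unordered object pair (AB, CD) contributes one equation
#' \deqn{d(AB, CD) = C_{AC} + C_{BD} + X_{AD} + X_{BC} + W_{AB} + W_{CD} +
#' constant,} where C terms relate corresponding parts, X terms parts at
#' opposite locations, and W terms the two parts within one object.  Each
#' family has one column per unordered pair of distinct parts
#' (\code{choose(p, 2)} columns, canonical order i < j); a relation between
#' two copies of the same part contributes nothing (the declared convention
#' that keeps exactly 21 columns per family for 7 parts).  For 49 objects
#' from 7 parts the design is 1176 x 64.
#'
#' @param objects integer matrix (or 2-column data.frame) of part labels,
#'   one row per object; labels in \code{1..partCount}; duplicate objects
#'   are an error
#' @param partCount number of distinct parts
#' @return a \linkS4class{PartSumDesign}
#' @export
buildPartSumDesign <- function(objects, partCount = max(objects)) {
  objects <- as.matrix(objects)
  stopifnot(ncol(objects) == 2, all(objects >= 1), all(objects <= partCount))
  storage.mode(objects) <- "integer"
  if (anyDuplicated(objects))
    stop("duplicate objects: zero self-distance rows are excluded")
  nObj <- nrow(objects)
  nRel <- choose(partCount, 2)
  ## canonical column for unordered part pair (i, j), i < j, else 0
  colOf <- matrix(0L, partCount, partCount)
  k <- 0L
  for (i in seq_len(partCount - 1)) for (j in (i + 1):partCount) {
    k <- k + 1L
    colOf[i, j] <- k; colOf[j, i] <- k
  }
  relNames <- character(nRel)
  k <- 0L
  for (i in seq_len(partCount - 1)) for (j in (i + 1):partCount) {
    k <- k + 1L
    relNames[k] <- sprintf("%d_%d", i, j)
  }
  pairIdx <- combn(nObj, 2)
  nPairs <- ncol(pairIdx)
  X <- matrix(0, nPairs, 3L * nRel + 1L)
  colnames(X) <- c(paste0("C_", relNames), paste0("X_", relNames),
                   paste0("W_", relNames), "const")
  bump <- function(row, offset, a, b) {
    cl <- colOf[a, b]
    if (cl > 0L) X[row, offset + cl] <<- X[row, offset + cl] + 1
  }
  for (r in seq_len(nPairs)) {
    o1 <- objects[pairIdx[1, r], ]; o2 <- objects[pairIdx[2, r], ]
    bump(r, 0L, o1[1], o2[1])          # C_AC
    bump(r, 0L, o1[2], o2[2])          # C_BD
    bump(r, nRel, o1[1], o2[2])        # X_AD
    bump(r, nRel, o1[2], o2[1])        # X_BC
    bump(r, 2L * nRel, o1[1], o1[2])   # W_AB
    bump(r, 2L * nRel, o2[1], o2[2])   # W_CD
    X[r, 3L * nRel + 1L] <- 1
  }
  pairs <- data.frame(obj1 = pairIdx[1, ], obj2 = pairIdx[2, ])
  new("PartSumDesign", design = X, pairs = pairs, objects = objects,
      partCount = as.integer(partCount))
}

#' Fit the part-sum model by least squares
#'
#' Solves the linear system by singular value decomposition; when the design
#' is rank-deficient the minimum-norm solution is returned and flagged (with
#' a warning).
#'
#' @param design a \linkS4class{PartSumDesign}
#' @param distances observed dissimilarity per design row
#' @return a \linkS4class{PartSumFit}
#' @export
fitPartSum <- function(design, distances) {
  X <- design@design
  if (length(distances) != nrow(X))
    stop("distances length does not match design rows")
  if (any(!is.finite(distances))) stop("distances must be finite")
  if (nrow(X) < ncol(X)) stop("fewer equations than unknowns")
  sv <- svd(X)
  tolr <- max(dim(X)) * max(sv$d) * .Machine$double.eps
  r <- sum(sv$d > tolr)
  rankDeficient <- r < ncol(X)
  if (rankDeficient)
    warning("rank-deficient part-sum design; returning minimum-norm solution")
  coefs <- drop(sv$v[, seq_len(r), drop = FALSE] %*%
                  ((t(sv$u[, seq_len(r), drop = FALSE]) %*% distances) /
                     sv$d[seq_len(r)]))
  names(coefs) <- colnames(X)
  pred <- drop(X %*% coefs)
  new("PartSumFit", coefficients = coefs, predicted = pred,
      residuals = distances - pred, rankDeficient = rankDeficient)
}

#' Evaluate a part-sum fit on a designated pair subset
#'
#' @param fit a \linkS4class{PartSumFit}
#' @param evalIdx design-row indices of the evaluation pairs (>= 3)
#' @param observed observed dissimilarities for all design rows
#' @return Pearson correlation of observed vs predicted on the evaluation
#'   pairs
#' @export
evaluatePartSum <- function(fit, evalIdx, observed) {
  if (length(evalIdx) < 3) stop("need at least 3 evaluation pairs")
  if (max(evalIdx) > length(fit@predicted)) stop("evalIdx outside design rows")
  cor(observed[evalIdx], fit@predicted[evalIdx])
}

#' Design-row indices of pairs between common objects
#'
#' Common objects are those whose two part labels are equal (the diagonal of
#' a part-recombination set, reproducing the original whole objects).
#'
#' @param design a \linkS4class{PartSumDesign}
#' @return integer vector of design-row indices
#' @export
commonPairIndices <- function(design) {
  isCommon <- design@objects[, 1] == design@objects[, 2]
  which(isCommon[design@pairs$obj1] & isCommon[design@pairs$obj2])
}

#' Generate dissimilarities from known part-sum coefficients
#'
#' The generative counterpart of [fitPartSum()]: distances are
#' \code{design \%*\% coefficients} plus optional Gaussian noise, shifted to
#' remain nonnegative.
#'
#' @param design a \linkS4class{PartSumDesign}
#' @param coefficients coefficient vector (length \code{ncol(design)});
#'   \code{NULL} draws positive coefficients from the seed
#' @param noiseSd Gaussian noise standard deviation
#' @param seed integer seed
#' @return list with \code{distances} and the \code{coefficients} used
#' @export
partSumGenerativeDistances <- function(design, coefficients = NULL,
                                       noiseSd = 0, seed = 1L) {
  X <- design@design
  withr::with_seed(seed, {
    if (is.null(coefficients))
      coefficients <- c(runif(ncol(X) - 1L, 0.2, 1), 0.5)
    d <- drop(X %*% coefficients)
    if (noiseSd > 0) d <- d + rnorm(length(d), sd = noiseSd)
  })
  list(distances = d, coefficients = setNames(coefficients, colnames(X)))
}
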