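#' Paired sign-flip permutation test
#'
#' Tests whether fold-level performance differs between two alignment
#' conditions. The observed statistic is the mean paired difference
#' \code{mean(a - b)}. Under the null the pairing carries no information, so
#' each permutation independently flips the sign of every pair's difference
#' with probability 1/2 (resampling the sign assignments with replacement).
#' The two-sided Monte-Carlo p uses add-one smoothing,
#' \code{(1 + #\{|T*| >= |T|\}) / (1 + nPerm)}, so it is never zero. For
#' \code{exact = TRUE} (n <= 20 pairs) all \code{2^n} sign patterns are
#' enumerated instead and \code{p = #\{|T*| >= |T|\} / 2^n}, which includes
#' the identity pattern and is therefore also positive.
#'
#' @param a,b paired per-fold values (e.g. Dice per left-out subject under
#'   two templates); equal length >= 2.
#' @param nPerm number of Monte-Carlo permutations (default 10000).
#' @param seed RNG seed; required for reproducibility of the Monte-Carlo
#'   path.
#' @param exact enumerate all sign patterns instead of sampling.
#' @return a [PermutationResult-class].
#' @examples
#' r <- pairedPermutationTest(c(.5, .6, .7), c(.4, .5, .6), nPerm = 1000, seed = 1)
#' pValue(r)
#' @export
pairedPermutationTest <- function(a, b, nPerm = 10000L, seed = 1L,
                                  exact = FALSE) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)", call. = FALSE)
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  tObs <- mean(d)
  tol <- 1e-12
  if (exact) {
    if (n > 20L) stop("exact enumeration limited to 20 pairs", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tStar <- as.vector(signs %*% d) / n
    p <- sum(abs(tStar) >= abs(tObs) - tol) / length(tStar)
    return(new("PermutationResult", observed = tObs, pValue = p,
               nPerm = as.integer(length(tStar)), null = tStar,
               exact = TRUE, seed = NA_integer_))
  }
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1", call. = FALSE)
  tStar <- withSeed(seed, {
    signs <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nrow = nPerm)
    as.vector(signs %*% d) / n
  })
  p <- (1 + sum(abs(tStar) >= abs(tObs) - tol)) / (1 + nPerm)
  new("PermutationResult", observed = tObs, pValue = p, nPerm = nPerm,
      null = tStar, exact = FALSE, seed = as.integer(seed))
}

#' Resampled chance level for parcellation overlap
#'
#' Distribution of the overlap between a fixed region and a label drawn
#' uniformly with replacement from a pool of (subject, region) labels: each
#' of \code{nIter} iterations draws one pool element and records
#' \code{overlapFn(mroi, draw)}. The null's mean is the chance level; its
#' 2.5 and 97.5 percentiles give the 95% CI. The overlap of each pool
#' element is computed once and indexed, so the result is exactly the
#' resampled single-draw distribution.
#'
#' @param mroi the fixed [RoiLabel-class] (group-level region).
#' @param pool list of [RoiLabel-class] (all subjects x all regions of one
#'   hemisphere).
#' @param overlapFn function(mroi, label) -> overlap in [0, 1]; defaults to
#'   [overlapProportion()].
#' @param nIter number of resampling iterations (default 1000).
#' @param seed RNG seed.
#' @param batchSize draws averaged within each iteration. The default 1
#'   records the raw single-draw overlaps. When the observed statistic the
#'   null will be compared against is itself a mean over N subjects, set
#'   \code{batchSize = N} so each iteration records the mean of N
#'   independent draws — the null of the same statistic
#'   ([compareAtlases()] does this).
#' @return a [ChanceNull-class].
#' @export
chanceOverlapNull <- function(mroi, pool, overlapFn = overlapProportion,
                              nIter = 1000L, seed = 1L, batchSize = 1L) {
  if (length(pool) == 0L) stop("empty label pool", call. = FALSE)
  nIter <- as.integer(nIter)
  batchSize <- as.integer(batchSize)
  if (nIter < 1L) stop("nIter must be >= 1", call. = FALSE)
  if (batchSize < 1L) stop("batchSize must be >= 1", call. = FALSE)
  perElement <- vapply(pool, function(lab) overlapFn(mroi, lab), numeric(1))
  draws <- withSeed(seed,
    sample.int(length(pool), nIter * batchSize, replace = TRUE))
  vals <- if (batchSize == 1L) {
    perElement[draws]
  } else {
    rowMeans(matrix(perElement[draws], nrow = nIter))
  }
  ci <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  mroiId <- if (is(mroi, "RoiLabel")) roiId(mroi) else "mroi"
  hemi <- if (is(mroi, "RoiLabel")) hemisphere(mroi) else "left"
  new("ChanceNull", mroi = mroiId, hemisphere = hemi, values = vals,
      mean = mean(vals), ciLow = ci[1L], ciHigh = ci[2L], nIter = nIter,
      seed = as.integer(seed))
}

#' One-sided exceedance p against a resampled null
#'
#' \code{p = (1 + #\{null >= observed\}) / (1 + nIter)}: the probability,
#' under the chance distribution, of an overlap at least as large as the
#' one observed, with add-one smoothing.
#'
#' @param observed observed mean overlap.
#' @param null a [ChanceNull-class].
#' @return the p-value, in (0, 1].
#' @export
chanceExceedanceP <- function(observed, null) {
  (1 + sum(null@values >= observed)) / (1 + null@nIter)
}

#' Bonferroni correction
#'
#' \code{min(1, p * m)}: controls the family-wise error over \code{m}
#' comparisons (here, the regions of the first parcellation compared with
#' each region of the second).
#'
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @return corrected p-value(s), capped at 1.
#' @export
bonferroniCorrect <- function(p, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  vapply(p, function(pi) stats::p.adjust(pi, method = "bonferroni", n = m),
         numeric(1))
}

#' Friedman rank test with tie correction
#'
#' Nonparametric test for a treatment effect in a randomized complete block
#' design (here: a hemisphere main effect across mROI-by-cROI overlap
#' cells). Values are ranked within each block with midranks for ties; the
#' statistic is
#' \deqn{\chi^2 = \left[\frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)\right] / C}
#' with the standard tie correction
#' \eqn{C = 1 - \sum_b \sum_g (t_{bg}^3 - t_{bg}) / (n k (k^2 - 1))}, where
#' \eqn{t_{bg}} are the tie-group sizes of block b. Blocks entirely tied in
#' every row (C = 0) give a statistic of 0 and p = 1. df = k - 1; p comes
#' from the chi-squared distribution.
#'
#' @param x numeric matrix, blocks in rows, treatments in columns; no
#'   missing cells.
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{method}.
#' @export
friedmanTest <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells are not allowed", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L) stop("need at least 2 treatments", call. = FALSE)
  if (n < 2L) stop("need at least 2 blocks", call. = FALSE)
  r <- t(apply(x, 1L, rank))
  Rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- apply(x, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C <= 0) {
    stat <- 0
  } else {
    stat <- stat / C
  }
  df <- k - 1L
  p <- if (stat == 0 && C <= 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p,
       method = "Friedman rank sum test with tie correction")
}
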