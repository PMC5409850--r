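#' Directional overlap proportion
#'
#' The fraction of the first region contained in the second:
#' \code{|mroi \\u2229 croi| / |mroi|}. Directional by design — it answers
#' "how much of this group-level region falls inside that individual
#' region" — so \code{overlapProportion(a, b)} generally differs from
#' \code{overlapProportion(b, a)}.
#'
#' @param mroi the reference [RoiLabel-class] (denominator); non-empty.
#' @param croi the comparison [RoiLabel-class].
#' @return fraction in [0, 1].
#' @export
overlapProportion <- function(mroi, croi) {
  if (!identical(hemisphere(mroi), hemisphere(croi))) {
    stop("hemisphere mismatch: ", hemisphere(mroi), " vs ",
         hemisphere(croi), call. = FALSE)
  }
  if (!identical(meshName(mroi), meshName(croi))) {
    stop("mesh mismatch: labels live on different meshes", call. = FALSE)
  }
  a <- vertexSet(mroi)
  length(intersect(a, vertexSet(croi))) / length(a)
}

#' Compare a group-level parcellation to a multi-subject cohort
#'
#' For every (mROI, cROI, hemisphere) cell: the overlap proportion of the
#' mROI in each subject's cROI, averaged across the subjects possessing
#' that cROI, with its standard error; a chance level resampled from the
#' full (subject x cROI) pool of the same hemisphere (uniform draws with
#' replacement, [chanceOverlapNull()] with one draw averaged per cohort
#' subject, so observed mean and null measure the same statistic); the
#' one-sided exceedance p of the
#' mean against that null; and the Bonferroni correction over the number of
#' cROIs. Hemispheres are processed independently — no computation ever
#' mixes labels across hemispheres.
#'
#' @param mrois list of group-level [RoiLabel-class] (the second
#'   parcellation).
#' @param cohort a [Cohort-class] carrying the per-subject regions.
#' @param alpha significance level applied to the corrected p (default
#'   0.05).
#' @param nIter chance-resampling iterations per mROI (default 1000).
#' @param seed root seed; each mROI's null uses a substream split from it,
#'   so results are independent of mROI ordering.
#' @return a [ComparisonReport-class].
#' @export
compareAtlases <- function(mrois, cohort, alpha = 0.05, nIter = 1000L,
                           seed = 1L) {
  nIter <- as.integer(nIter)
  rows <- list()
  for (hemi in cohort@hemispheres) {
    pool <- list()
    for (s in subjects(cohort)) {
      for (r in roiIds(cohort)) {
        if (hasLabel(cohort, s, r, hemi)) {
          pool[[length(pool) + 1L]] <- getLabel(cohort, s, r, hemi)
        }
      }
    }
    if (length(pool) == 0L) next
    hemiMrois <- Filter(function(m) identical(hemisphere(m), hemi), mrois)
    nComparisons <- length(roiIds(cohort))
    for (mroi in hemiMrois) {
      # null of the observed statistic: each iteration averages one random
      # (subject, cROI) draw per cohort subject
      null <- chanceOverlapNull(
        mroi, pool, overlapFn = overlapProportion, nIter = nIter,
        seed = streamSeed(seed, "chance", roiId(mroi), hemi),
        batchSize = length(subjects(cohort))
      )
      for (croi in roiIds(cohort)) {
        subs <- subjectsWithRoi(cohort, croi, hemi)
        if (length(subs) == 0L) {
          stop("no subject possesses ", croi, "/", hemi, call. = FALSE)
        }
        ov <- vapply(subs, function(s) {
          overlapProportion(mroi, getLabel(cohort, s, croi, hemi))
        }, numeric(1))
        meanOv <- mean(ov)
        seOv <- if (length(ov) > 1L) stats::sd(ov) / sqrt(length(ov)) else NA_real_
        pRaw <- chanceExceedanceP(meanOv, null)
        pBonf <- bonferroniCorrect(pRaw, nComparisons)
        rows[[length(rows) + 1L]] <- data.frame(
          mroi = roiId(mroi), croi = croi, hemisphere = hemi,
          meanOverlap = meanOv, seOverlap = seOv,
          chanceMean = chanceMean(null),
          chanceCiLow = unname(chanceCI(null)["lower"]),
          chanceCiHigh = unname(chanceCI(null)["upper"]),
          pRaw = pRaw, pBonferroni = pBonf,
          significant = pBonf < alpha, nSubjects = length(ov),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ComparisonReport", table = tab, alpha = alpha, nIter = nIter,
      seed = as.integer(seed))
}
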