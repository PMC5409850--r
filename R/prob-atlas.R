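#' Dice coefficient between two vertex sets
#'
#' \deqn{dc = 2 |I \cap G| / (|I| + |G|)}
#'
#' 0 means the sets are disjoint (no predictability when G is a group map
#' predicting an individual region I); 1 means they coincide. Symmetric in
#' its arguments. Vertices are counted unweighted, matching the
#' set-cardinality definition; pass per-vertex \code{weights} (e.g.
#' [vertexAreas()]) for an area-weighted variant — an extension, off by
#' default.
#'
#' @param I,G vertex index sets (integer vectors) or [RoiLabel-class]
#'   objects.
#' @param weights optional numeric vector over all mesh vertices; when
#'   supplied, cardinalities become sums of weights (indices 0-based).
#' @return the coefficient, in [0, 1].
#' @examples
#' diceCoefficient(c(1L, 2L, 3L), c(2L, 3L, 4L))  # 2/3
#' @export
diceCoefficient <- function(I, G, weights = NULL) {
  if (is(I, "RoiLabel")) I <- vertexSet(I)
  if (is(G, "RoiLabel")) G <- vertexSet(G)
  if (length(I) == 0L && length(G) == 0L) {
    stop("dice coefficient undefined for two empty sets", call. = FALSE)
  }
  if (is.null(weights)) {
    2 * length(intersect(I, G)) / (length(I) + length(G))
  } else {
    wI <- sum(weights[I + 1L])
    wG <- sum(weights[G + 1L])
    2 * sum(weights[intersect(I, G) + 1L]) / (wI + wG)
  }
}

#' Threshold grid for a group of n subjects
#'
#' The probability levels attainable by an n-subject group map:
#' \code{0, 1/n, ..., 1}, i.e. steps of 1/n (steps of .125 for n = 8, where
#' the level .375 keeps vertices shared by more than two subjects).
#'
#' @param n group size.
#' @return a [ThresholdGrid-class].
#' @export
thresholdGrid <- function(n) {
  n <- as.integer(n)
  new("ThresholdGrid", n = n, levels = (0:n) / n)
}

#' Build a group probabilistic map
#'
#' Per-vertex count of subjects whose label contains the vertex, over the
#' given subject subset (all subjects by default), and the fraction
#' counts / n. Subjects lacking the region are excluded with a message.
#'
#' @param cohort a [Cohort-class].
#' @param roi,hemi region and hemisphere.
#' @param subjects subjects to include; default all cohort subjects.
#' @return a [ProbabilisticMap-class].
#' @export
buildProbMap <- function(cohort, roi, hemi, subjects = NULL) {
  if (is.null(subjects)) subjects <- subjects(cohort)
  have <- vapply(subjects, function(s) hasLabel(cohort, s, roi, hemi), logical(1))
  if (any(!have)) {
    message("excluding ", sum(!have), " subject(s) lacking ", roi, "/", hemi,
            ": ", paste(subjects[!have], collapse = ", "))
    subjects <- subjects[have]
  }
  if (length(subjects) == 0L) {
    stop("no subject possesses ", roi, "/", hemi, call. = FALSE)
  }
  counts <- integer(nVertices(cohort@mesh))
  for (s in subjects) {
    v <- vertexSet(getLabel(cohort, s, roi, hemi)) + 1L
    counts[v] <- counts[v] + 1L
  }
  n <- length(subjects)
  new("ProbabilisticMap", roi = roi, hemisphere = hemi,
      condition = conditionTag(cohort), nSubjects = as.integer(n),
      counts = counts, values = counts / n, meshName = meshName(cohort))
}

#' Threshold a probabilistic map
#'
#' Inclusive comparison: vertices with \code{values >= t} survive, so with
#' a group of 8 the level .375 keeps vertices present in at least three
#' subjects. \code{t = 0} means the unthresholded map, read as the map's
#' support (counts >= 1), not the whole mesh.
#'
#' @param pmap a [ProbabilisticMap-class].
#' @param t threshold fraction in [0, 1].
#' @return sorted 0-based vertex indices.
#' @export
thresholdMap <- function(pmap, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]", call. = FALSE)
  if (t == 0) {
    which(pmap@counts >= 1L) - 1L
  } else {
    # counts >= t * n with a tolerance guarding the binary representation
    which(pmap@counts >= t * pmap@nSubjects - 1e-9) - 1L
  }
}

#' Maximum probability map
#'
#' Assigns every vertex whose best map value reaches \code{minProb} (and is
#' positive) to the region with the highest probabilistic-map value.
#' Ties go to the region earliest in the canonical ordering (the sorted
#' order of the region ids), so the result does not depend on the input
#' order of \code{pmaps}. Unassigned vertices carry the explicit level
#' \code{"background"}.
#'
#' @param pmaps list of [ProbabilisticMap-class] on one mesh and
#'   hemisphere.
#' @param minProb minimum winning probability for assignment; default 0
#'   (every supported vertex is assigned).
#' @return factor of length nVertices with levels = sorted region ids plus
#'   \code{"background"}.
#' @export
buildMpm <- function(pmaps, minProb = 0) {
  if (length(pmaps) == 0L) stop("empty map list", call. = FALSE)
  rois <- vapply(pmaps, roiId, "")
  if (anyDuplicated(rois)) stop("duplicate region ids in pmaps", call. = FALSE)
  hemi <- unique(vapply(pmaps, hemisphere, ""))
  mnames <- unique(vapply(pmaps, function(p) p@meshName, ""))
  if (length(hemi) != 1L || length(mnames) != 1L) {
    stop("all maps must share one hemisphere and one mesh", call. = FALSE)
  }
  ord <- order(rois)
  pmaps <- pmaps[ord]
  rois <- rois[ord]
  vals <- matrix(unlist(lapply(pmaps, probValues)), ncol = length(pmaps))
  best <- max.col(vals, ties.method = "first")
  bestVal <- vals[cbind(seq_len(nrow(vals)), best)]
  assigned <- bestVal > 0 & bestVal >= minProb
  out <- rep("background", nrow(vals))
  out[assigned] <- rois[best[assigned]]
  factor(out, levels = c(rois, "background"))
}

#' Leave-one-out cross-validated Dice across a threshold sweep
#'
#' Exhaustive leave-one-out cross-validation of a region's group map: each
#' subject possessing the region is left out once; the group probabilistic
#' map built from the remaining subjects is thresholded at every level of
#' the grid and compared to the left-out subject's region with the Dice
#' coefficient. Per-threshold mean and standard error
#' (sample SD / sqrt(n folds)) across folds summarise predictability.
#'
#' @param cohort a [Cohort-class].
#' @param roi,hemi region and hemisphere.
#' @param grid a [ThresholdGrid-class]; defaults to the grid of the group
#'   size (number of possessing subjects minus one).
#' @return a [CvResult-class].
#' @export
loocvDice <- function(cohort, roi, hemi, grid = NULL) {
  subs <- subjectsWithRoi(cohort, roi, hemi)
  if (length(subs) < 3L) {
    stop("leave-one-out evaluation needs at least 3 subjects with ", roi,
         "/", hemi, " (found ", length(subs), ")", call. = FALSE)
  }
  if (is.null(grid)) grid <- thresholdGrid(length(subs) - 1L)
  levels <- thresholdLevels(grid)
  dice <- matrix(NA_real_, nrow = length(subs), ncol = length(levels))
  for (i in seq_along(subs)) {
    heldOut <- vertexSet(getLabel(cohort, subs[i], roi, hemi))
    gmap <- buildProbMap(cohort, roi, hemi, subjects = setdiff(subs, subs[i]))
    for (j in seq_along(levels)) {
      G <- thresholdMap(gmap, levels[j])
      dice[i, j] <- if (length(G) == 0L && length(heldOut) == 0L) {
        NA_real_
      } else {
        diceCoefficient(heldOut, G)
      }
    }
  }
  m <- colMeans(dice)
  se <- apply(dice, 2L, stats::sd) / sqrt(nrow(dice))
  new("CvResult", condition = conditionTag(cohort), roi = roi,
      hemisphere = hemi, folds = subs, thresholds = levels, dice = dice,
      diceMean = m, diceSE = se)
}
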