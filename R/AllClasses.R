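#' @import methods
NULL

# Vertex indices are 0-based throughout the package, matching the native
# convention of FreeSurfer label files. Faces of a TriangleMesh and the
# vertex sets of RoiLabel objects therefore run from 0 to nVertices - 1;
# conversion to R's 1-based indexing happens only at the point of matrix
# subsetting, never at the API surface.

#' TriangleMesh: a triangulated surface
#'
#' Shared surface geometry on which all region labels live. Vertices are 3-D
#' coordinates in millimetres; faces are triples of 0-based vertex indices.
#'
#' @slot vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @slot faces integer matrix, one row per triangle, 0-based vertex indices.
#' @slot name character tag, e.g. \code{"lh.sphere"}.
#'
#' @seealso [TriangleMesh()], [readMesh()], [vertexNeighbors()]
#' @export
setClass("TriangleMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    name = "character"
  )
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msgs <- character()
  if (!is.numeric(v) || ncol(v) != 3L) {
    msgs <- c(msgs, "vertices must be a numeric matrix with 3 columns")
  }
  if (!is.numeric(f) || ncol(f) != 3L) {
    msgs <- c(msgs, "faces must be an integer matrix with 3 columns")
  }
  if (length(msgs) == 0L && nrow(f) > 0L) {
    if (any(f < 0L) || any(f >= nrow(v))) {
      msgs <- c(msgs, "face indices must lie in [0, nVertices - 1]")
    }
    degen <- f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]
    if (any(degen)) {
      msgs <- c(msgs, sprintf(
        "faces must have 3 distinct vertices (first violation: face %d)",
        which(degen)[1L] - 1L
      ))
    }
  }
  if (length(object@name) != 1L) {
    msgs <- c(msgs, "name must be a single string")
  }
  if (length(msgs)) msgs else TRUE
})

#' RoiLabel: one subject's region as a vertex set
#'
#' A region of interest belonging to one subject and one hemisphere,
#' represented purely as a set of 0-based vertex indices on a named mesh.
#' Coordinates written to label files are taken from the mesh; set
#' arithmetic (overlap, Dice) is index-based only, because all subjects
#' share one template mesh after surface alignment.
#'
#' @slot subject subject identifier.
#' @slot roi region identifier (e.g. \code{"hOc1"}, \code{"FG2"}, or a
#'   second-parcellation name such as \code{"V1"}).
#' @slot hemisphere \code{"left"} or \code{"right"}.
#' @slot vertices sorted unique 0-based vertex indices; never empty.
#' @slot meshName name of the mesh the indices refer to.
#'
#' @seealso [RoiLabel()], [readLabel()], [diceCoefficient()]
#' @export
setClass("RoiLabel",
  representation(
    subject = "character",
    roi = "character",
    hemisphere = "character",
    vertices = "integer",
    meshName = "character"
  )
)

setValidity("RoiLabel", function(object) {
  msgs <- character()
  if (length(object@subject) != 1L) msgs <- c(msgs, "subject must be a single string")
  if (length(object@roi) != 1L) msgs <- c(msgs, "roi must be a single string")
  if (!identical(length(object@hemisphere), 1L) ||
      !(object@hemisphere %in% c("left", "right"))) {
    msgs <- c(msgs, "hemisphere must be \"left\" or \"right\"")
  }
  v <- object@vertices
  if (length(v) == 0L) msgs <- c(msgs, "vertex set must be non-empty")
  if (anyNA(v) || any(v < 0L)) msgs <- c(msgs, "vertex indices must be non-negative")
  if (anyDuplicated(v)) msgs <- c(msgs, "vertex indices must be unique")
  if (is.unsorted(v)) msgs <- c(msgs, "vertex indices must be sorted")
  if (length(msgs)) msgs else TRUE
})

#' Cohort: a multi-subject label collection under one alignment condition
#'
#' The full study design for one alignment condition: an ordered subject
#' list, an ordered ROI list, the hemispheres analysed, and a label for
#' every (subject, roi, hemisphere) combination that exists. Combinations a
#' subject lacks (e.g. a brain whose histology did not permit identifying
#' some regions) are recorded explicitly in \code{missing}, never silently
#' dropped.
#'
#' @slot mesh the shared [TriangleMesh-class].
#' @slot subjects ordered subject identifiers.
#' @slot rois ordered region identifiers (the canonical ROI ordering used
#'   for deterministic tie-breaking downstream).
#' @slot hemispheres subset of \code{c("left", "right")}.
#' @slot condition alignment-condition tag (e.g. \code{"CBApm"}).
#' @slot labels named list of [RoiLabel-class]; names are
#'   \code{"subject|roi|hemisphere"}.
#' @slot missing data.frame with columns subject/roi/hemisphere listing
#'   absent combinations.
#'
#' @seealso [Cohort()], [generateCohort()], [loocvDice()]
#' @export
setClass("Cohort",
  representation(
    mesh = "TriangleMesh",
    subjects = "character",
    rois = "character",
    hemispheres = "character",
    condition = "character",
    labels = "list",
    missing = "data.frame"
  )
)

setValidity("Cohort", function(object) {
  msgs <- character()
  if (!all(object@hemispheres %in% c("left", "right"))) {
    msgs <- c(msgs, "hemispheres must be a subset of c(\"left\", \"right\")")
  }
  if (length(object@condition) != 1L) msgs <- c(msgs, "condition must be a single string")
  for (lab in object@labels) {
    if (!is(lab, "RoiLabel")) {
      msgs <- c(msgs, "labels must all be RoiLabel objects")
      break
    }
    if (!(lab@subject %in% object@subjects) || !(lab@roi %in% object@rois) ||
        !(lab@hemisphere %in% object@hemispheres)) {
      msgs <- c(msgs, sprintf(
        "label %s|%s|%s not covered by the cohort's subject/roi/hemisphere lists",
        lab@subject, lab@roi, lab@hemisphere
      ))
      break
    }
    if (!identical(lab@meshName, object@mesh@name)) {
      msgs <- c(msgs, "all labels must reference the cohort mesh")
      break
    }
    if (length(lab@vertices) && max(lab@vertices) >= nrow(object@mesh@vertices)) {
      msgs <- c(msgs, "label vertex indices exceed the cohort mesh")
      break
    }
  }
  need <- c("subject", "roi", "hemisphere")
  if (!all(need %in% names(object@missing))) {
    msgs <- c(msgs, "missing must have subject/roi/hemisphere columns")
  }
  if (length(msgs)) msgs else TRUE
})

#' ProbabilisticMap: per-vertex subject fraction for one region
#'
#' For one ROI, hemisphere and alignment condition, the number of subjects
#' whose label contains each vertex (\code{counts}) and the corresponding
#' fraction \code{values = counts / nSubjects}.
#'
#' @slot roi,hemisphere,condition identifiers inherited from the cohort.
#' @slot nSubjects number of subjects that entered the map.
#' @slot counts integer vector over all mesh vertices.
#' @slot values numeric vector, exactly \code{counts / nSubjects}.
#' @slot meshName mesh the map lives on.
#'
#' @seealso [buildProbMap()], [thresholdMap()], [buildMpm()]
#' @export
setClass("ProbabilisticMap",
  representation(
    roi = "character",
    hemisphere = "character",
    condition = "character",
    nSubjects = "integer",
    counts = "integer",
    values = "numeric",
    meshName = "character"
  )
)

setValidity("ProbabilisticMap", function(object) {
  msgs <- character()
  n <- object@nSubjects
  if (length(n) != 1L || is.na(n) || n < 1L) msgs <- c(msgs, "nSubjects must be a positive integer")
  if (length(object@counts) != length(object@values)) {
    msgs <- c(msgs, "counts and values must have equal length")
  } else if (length(n) == 1L && !is.na(n) && n >= 1L) {
    if (any(object@counts < 0L) || any(object@counts > n)) {
      msgs <- c(msgs, "counts must lie in [0, nSubjects]")
    }
    if (!identical(object@values, object@counts / n)) {
      msgs <- c(msgs, "values must equal counts / nSubjects exactly")
    }
    if (!any(object@counts > 0L)) msgs <- c(msgs, "map support must be non-empty")
  }
  if (length(msgs)) msgs else TRUE
})

#' ThresholdGrid: the probability levels of a leave-one-out sweep
#'
#' For a group map built from \code{n} subjects the attainable probability
#' values are multiples of \code{1/n}; the grid is exactly
#' \code{0, 1/n, 2/n, ..., 1}. With \code{n = 8} the step is .125 and the
#' grid contains .375 (vertices shared by at least three subjects).
#'
#' @slot n group size.
#' @slot levels the fractions \code{(0:n)/n}.
#'
#' @seealso [thresholdGrid()], [loocvDice()]
#' @export
setClass("ThresholdGrid",
  representation(n = "integer", levels = "numeric")
)

setValidity("ThresholdGrid", function(object) {
  msgs <- character()
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 1L) {
    msgs <- c(msgs, "n must be a positive integer")
  } else if (!identical(object@levels, (0:n) / n)) {
    msgs <- c(msgs, "levels must be exactly (0:n)/n")
  }
  if (length(msgs)) msgs else TRUE
})

#' CvResult: leave-one-out cross-validated Dice across a threshold sweep
#'
#' One row of \code{dice} per fold (left-out subject), one column per
#' threshold level; per-threshold mean and standard error
#' (sample SD / sqrt(number of folds)) across folds.
#'
#' @slot condition,roi,hemisphere identifiers.
#' @slot folds left-out subject ids, one per fold.
#' @slot thresholds the grid levels.
#' @slot dice numeric matrix folds x thresholds, entries in [0, 1].
#' @slot diceMean,diceSE per-threshold summaries across folds.
#'
#' @seealso [loocvDice()], [as.data.frame,CvResult-method]
#' @export
setClass("CvResult",
  representation(
    condition = "character",
    roi = "character",
    hemisphere = "character",
    folds = "character",
    thresholds = "numeric",
    dice = "matrix",
    diceMean = "numeric",
    diceSE = "numeric"
  )
)

setValidity("CvResult", function(object) {
  msgs <- character()
  d <- object@dice
  if (nrow(d) != length(object@folds)) msgs <- c(msgs, "one dice row per fold required")
  if (ncol(d) != length(object@thresholds)) msgs <- c(msgs, "one dice column per threshold required")
  if (length(d) && (any(d < 0) || any(d > 1))) msgs <- c(msgs, "dice values must lie in [0, 1]")
  if (length(object@diceMean) != ncol(d) || length(object@diceSE) != ncol(d)) {
    msgs <- c(msgs, "diceMean and diceSE must have one entry per threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' PermutationResult: paired sign-flip permutation test outcome
#'
#' @slot observed observed statistic (mean paired difference).
#' @slot pValue two-sided Monte-Carlo p with add-one smoothing, or the exact
#'   enumeration p when \code{exact} is TRUE; never zero.
#' @slot nPerm number of permutations drawn (or enumerated).
#' @slot null the permutation null distribution.
#' @slot exact TRUE when all sign patterns were enumerated.
#' @slot seed RNG seed used (NA for exact enumeration).
#'
#' @seealso [pairedPermutationTest()]
#' @export
setClass("PermutationResult",
  representation(
    observed = "numeric",
    pValue = "numeric",
    nPerm = "integer",
    null = "numeric",
    exact = "logical",
    seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msgs <- character()
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1) {
    msgs <- c(msgs, "pValue must lie in (0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' ChanceNull: resampled chance distribution for parcellation overlap
#'
#' The distribution of overlap between a fixed region and a uniformly
#' resampled (subject, ROI) label from a pool, drawn with replacement. The
#' null's mean is reported as the chance level; its 2.5/97.5 percentiles
#' form the 95% confidence interval.
#'
#' @slot mroi,hemisphere identifiers of the fixed region.
#' @slot values the resampled overlaps (length \code{nIter}), each in [0, 1].
#' @slot mean,ciLow,ciHigh summaries of \code{values}.
#' @slot nIter,seed resampling settings.
#'
#' @seealso [chanceOverlapNull()], [chanceExceedanceP()]
#' @export
setClass("ChanceNull",
  representation(
    mroi = "character",
    hemisphere = "character",
    values = "numeric",
    mean = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    nIter = "integer",
    seed = "integer"
  )
)

setValidity("ChanceNull", function(object) {
  msgs <- character()
  v <- object@values
  if (length(v) != object@nIter) msgs <- c(msgs, "values must have length nIter")
  if (length(v) && (any(v < 0) || any(v > 1))) msgs <- c(msgs, "null values must lie in [0, 1]")
  if (length(v)) {
    if (object@ciLow < min(v) - 1e-12 || object@ciHigh > max(v) + 1e-12) {
      msgs <- c(msgs, "CI bounds must lie within the null's range")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ComparisonReport: parcellation-correspondence table
#'
#' Long-format table with one row per (mROI, cROI, hemisphere): mean overlap
#' proportion across subjects, its standard error, the chance level with 95%
#' CI, the raw and Bonferroni-corrected exceedance p, a significance flag,
#' and the number of subjects contributing.
#'
#' @slot table the data.frame described above.
#' @slot alpha significance level applied to the corrected p.
#' @slot nIter,seed chance-resampling settings.
#'
#' @seealso [compareAtlases()]
#' @export
setClass("ComparisonReport",
  representation(
    table = "data.frame",
    alpha = "numeric",
    nIter = "integer",
    seed = "integer"
  )
)

setValidity("ComparisonReport", function(object) {
  msgs <- character()
  need <- c(
    "mroi", "croi", "hemisphere", "meanOverlap", "seOverlap",
    "chanceMean", "chanceCiLow", "chanceCiHigh", "pRaw", "pBonferroni",
    "significant", "nSubjects"
  )
  if (!all(need %in% names(object@table))) {
    msgs <- c(msgs, paste(
      "table must contain columns:", paste(need, collapse = ", ")
    ))
  } else {
    ov <- object@table$meanOverlap
    if (length(ov) && (any(ov < 0) || any(ov > 1))) {
      msgs <- c(msgs, "mean overlaps must lie in [0, 1]")
    }
    sig <- object@table$significant
    expect <- object@table$pBonferroni < object@alpha
    if (!identical(as.logical(sig), expect)) {
      msgs <- c(msgs, "significant flag must equal pBonferroni < alpha")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' CohortConfig: full specification of a synthetic cohort
#'
#' Everything needed to regenerate a synthetic study deterministically: the
#' icosphere resolution, the subject count, the ROI templates (center
#' direction and geodesic radius), the per-condition center jitter, the
#' shared radius jitter, explicitly absent (subject, roi) combinations, and
#' the root seed. Any output of the generator is a pure function of this
#' object.
#'
#' @slot subdiv icosphere subdivision level (vertex count 10 * 4^subdiv + 2).
#' @slot nSubjects number of synthetic subjects.
#' @slot roiSpecs named list; each element has \code{center} (unit 3-vector)
#'   and \code{radius} (geodesic radius, radians).
#' @slot conditions alignment-condition tags, in order.
#' @slot centerJitterSD named numeric, one tangent-plane Gaussian SD
#'   (radians) per condition.
#' @slot radiusJitterSD Gaussian SD of the radius perturbation (radians).
#' @slot hemisphere hemisphere tag for every generated label.
#' @slot missing data.frame (subject, roi) combinations to mark absent.
#' @slot seed root RNG seed; per-label streams are split from it.
#'
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    subdiv = "integer",
    nSubjects = "integer",
    roiSpecs = "list",
    conditions = "character",
    centerJitterSD = "numeric",
    radiusJitterSD = "numeric",
    hemisphere = "character",
    missing = "data.frame",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (object@subdiv < 0L) msgs <- c(msgs, "subdiv must be >= 0")
  if (object@nSubjects < 1L) msgs <- c(msgs, "nSubjects must be >= 1")
  if (length(object@roiSpecs) == 0L || is.null(names(object@roiSpecs)) ||
      any(!nzchar(names(object@roiSpecs)))) {
    msgs <- c(msgs, "roiSpecs must be a non-empty named list")
  } else {
    for (nm in names(object@roiSpecs)) {
      sp <- object@roiSpecs[[nm]]
      if (!is.list(sp) || !all(c("center", "radius") %in% names(sp))) {
        msgs <- c(msgs, sprintf("roiSpec '%s' must have center and radius", nm))
        next
      }
      if (length(sp$center) != 3L ||
          abs(sqrt(sum(sp$center^2)) - 1) > 1e-8) {
        msgs <- c(msgs, sprintf("roiSpec '%s' center must be a unit 3-vector", nm))
      }
      if (sp$radius <= 0 || sp$radius >= pi) {
        msgs <- c(msgs, sprintf("roiSpec '%s' radius must lie in (0, pi)", nm))
      }
    }
  }
  if (!identical(sort(names(object@centerJitterSD)), sort(object@conditions))) {
    msgs <- c(msgs, "centerJitterSD must be named by the conditions")
  }
  if (any(object@centerJitterSD < 0)) msgs <- c(msgs, "centerJitterSD must be >= 0")
  if (length(object@radiusJitterSD) != 1L || object@radiusJitterSD < 0) {
    msgs <- c(msgs, "radiusJitterSD must be a single non-negative number")
  }
  if (!(object@hemisphere %in% c("left", "right"))) {
    msgs <- c(msgs, "hemisphere must be \"left\" or \"right\"")
  }
  if (!all(c("subject", "roi") %in% names(object@missing))) {
    msgs <- c(msgs, "missing must have subject and roi columns")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msgs <- c(msgs, "seed must be a single integer")
  }
  if (length(msgs)) msgs else TRUE
})
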