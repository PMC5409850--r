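#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))

#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

#' @rdname TriangleMesh-class
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' @rdname TriangleMesh-class
#' @export
setMethod("meshName", "TriangleMesh", function(x) x@name)

#' @rdname RoiLabel-class
#' @export
setMethod("vertexSet", "RoiLabel", function(x) x@vertices)

#' @rdname RoiLabel-class
#' @export
setMethod("subjectId", "RoiLabel", function(x) x@subject)

#' @rdname RoiLabel-class
#' @export
setMethod("roiId", "RoiLabel", function(x) x@roi)

#' @rdname RoiLabel-class
#' @export
setMethod("hemisphere", "RoiLabel", function(x) x@hemisphere)

#' @rdname RoiLabel-class
#' @export
setMethod("meshName", "RoiLabel", function(x) x@meshName)

#' @rdname Cohort-class
#' @export
setMethod("subjects", "Cohort", function(x) x@subjects)

#' @rdname Cohort-class
#' @export
setMethod("roiIds", "Cohort", function(x) x@rois)

#' @rdname Cohort-class
#' @export
setMethod("conditionTag", "Cohort", function(x) x@condition)

#' @rdname Cohort-class
#' @export
setMethod("meshName", "Cohort", function(x) x@mesh@name)

labelKey <- function(subject, roi, hemi) paste(subject, roi, hemi, sep = "|")

#' @rdname Cohort-class
#' @export
setMethod("getLabel", "Cohort", function(x, subject, roi, hemi) {
  key <- labelKey(subject, roi, hemi)
  lab <- x@labels[[key]]
  if (is.null(lab)) {
    stop("no label for (", subject, ", ", roi, ", ", hemi, ") in cohort '",
         x@condition, "'", call. = FALSE)
  }
  lab
})

#' @rdname Cohort-class
#' @export
setMethod("hasLabel", "Cohort", function(x, subject, roi, hemi) {
  !is.null(x@labels[[labelKey(subject, roi, hemi)]])
})

#' @rdname Cohort-class
#' @export
setMethod("missingCombos", "Cohort", function(x) x@missing)

#' @rdname ProbabilisticMap-class
#' @export
setMethod("probValues", "ProbabilisticMap", function(x) x@values)

#' @rdname ProbabilisticMap-class
#' @export
setMethod("probCounts", "ProbabilisticMap", function(x) x@counts)

#' @rdname ProbabilisticMap-class
#' @export
setMethod("nSubjects", "ProbabilisticMap", function(x) x@nSubjects)

#' @rdname ProbabilisticMap-class
#' @export
setMethod("roiId", "ProbabilisticMap", function(x) x@roi)

#' @rdname ProbabilisticMap-class
#' @export
setMethod("hemisphere", "ProbabilisticMap", function(x) x@hemisphere)

#' @rdname ThresholdGrid-class
#' @export
setMethod("thresholdLevels", "ThresholdGrid", function(x) x@levels)

#' @rdname CvResult-class
#' @export
setMethod("thresholdLevels", "CvResult", function(x) x@thresholds)

#' @rdname CvResult-class
#' @export
setMethod("diceMatrix", "CvResult", function(x) x@dice)

#' @rdname CvResult-class
#' @export
setMethod("diceMean", "CvResult", function(x) x@diceMean)

#' @rdname CvResult-class
#' @export
setMethod("diceSE", "CvResult", function(x) x@diceSE)

#' @rdname CvResult-class
#' @export
setMethod("foldIds", "CvResult", function(x) x@folds)

#' @rdname CvResult-class
#' @export
setMethod("roiId", "CvResult", function(x) x@roi)

#' Tidy long-format view of a cross-validation result
#'
#' One row per (fold, threshold) with the Dice value, plus the identifying
#' condition/roi/hemisphere columns — the layout written to the pipeline's
#' TSV output.
#'
#' @param x a [CvResult-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns condition, roi, hemisphere, fold,
#'   threshold, dice.
#' @export
setMethod("as.data.frame", "CvResult", function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  nf <- length(x@folds)
  nt <- length(x@thresholds)
  data.frame(
    condition = rep(x@condition, nf * nt),
    roi = rep(x@roi, nf * nt),
    hemisphere = rep(x@hemisphere, nf * nt),
    fold = rep(x@folds, times = nt),
    threshold = rep(x@thresholds, each = nf),
    dice = as.vector(x@dice),
    stringsAsFactors = FALSE
  )
})

#' @rdname PermutationResult-class
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname PermutationResult-class
#' @export
setMethod("observedStat", "PermutationResult", function(x) x@observed)

#' @rdname PermutationResult-class
#' @export
setMethod("nullValues", "PermutationResult", function(x) x@null)

#' @rdname ChanceNull-class
#' @export
setMethod("chanceMean", "ChanceNull", function(x) x@mean)

#' @rdname ChanceNull-class
#' @export
setMethod("chanceCI", "ChanceNull", function(x) c(lower = x@ciLow, upper = x@ciHigh))

#' @rdname ChanceNull-class
#' @export
setMethod("nullValues", "ChanceNull", function(x) x@values)

#' @rdname ComparisonReport-class
#' @export
setMethod("reportTable", "ComparisonReport", function(x) x@table)

#' @rdname ComparisonReport-class
#' @param x a [ComparisonReport-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
setMethod("as.data.frame", "ComparisonReport", function(x, row.names = NULL,
                                                        optional = FALSE, ...) {
  x@table
})
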