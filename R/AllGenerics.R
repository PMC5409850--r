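#' @rdname TriangleMesh-class
#' @param x,object a surfAtlas object.
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("meshName", function(x) standardGeneric("meshName"))

#' @rdname RoiLabel-class
#' @param x a surfAtlas object.
#' @export
setGeneric("vertexSet", function(x) standardGeneric("vertexSet"))

#' @rdname RoiLabel-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname RoiLabel-class
#' @export
setGeneric("roiId", function(x) standardGeneric("roiId"))

#' @rdname RoiLabel-class
#' @export
setGeneric("hemisphere", function(x) standardGeneric("hemisphere"))

#' @rdname Cohort-class
#' @param x a [Cohort-class].
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname Cohort-class
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))

#' @rdname Cohort-class
#' @export
setGeneric("conditionTag", function(x) standardGeneric("conditionTag"))

#' @rdname Cohort-class
#' @param subject,roi,hemi identifiers of one label.
#' @export
setGeneric("getLabel", function(x, subject, roi, hemi) standardGeneric("getLabel"))

#' @rdname Cohort-class
#' @export
setGeneric("hasLabel", function(x, subject, roi, hemi) standardGeneric("hasLabel"))

#' @rdname Cohort-class
#' @export
setGeneric("missingCombos", function(x) standardGeneric("missingCombos"))

#' @rdname ProbabilisticMap-class
#' @param x a [ProbabilisticMap-class].
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @rdname ProbabilisticMap-class
#' @export
setGeneric("probCounts", function(x) standardGeneric("probCounts"))

#' @rdname ProbabilisticMap-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname ThresholdGrid-class
#' @param x a [ThresholdGrid-class] or [CvResult-class].
#' @export
setGeneric("thresholdLevels", function(x) standardGeneric("thresholdLevels"))

#' @rdname CvResult-class
#' @param x a [CvResult-class].
#' @export
setGeneric("diceMatrix", function(x) standardGeneric("diceMatrix"))

#' @rdname CvResult-class
#' @export
setGeneric("diceMean", function(x) standardGeneric("diceMean"))

#' @rdname CvResult-class
#' @export
setGeneric("diceSE", function(x) standardGeneric("diceSE"))

#' @rdname CvResult-class
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))

#' @rdname PermutationResult-class
#' @param x a result object with a p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname PermutationResult-class
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))

#' @rdname PermutationResult-class
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname ChanceNull-class
#' @param x a [ChanceNull-class].
#' @export
setGeneric("chanceMean", function(x) standardGeneric("chanceMean"))

#' @rdname ChanceNull-class
#' @export
setGeneric("chanceCI", function(x) standardGeneric("chanceCI"))

#' @rdname ComparisonReport-class
#' @param x a [ComparisonReport-class].
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
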