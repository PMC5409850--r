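#' @rdname TriangleMesh-class
setMethod("show", "TriangleMesh", function(object) {
  cat("TriangleMesh '", object@name, "': ", nVertices(object), " vertices, ",
      nFaces(object), " faces\n", sep = "")
})

#' @rdname RoiLabel-class
setMethod("show", "RoiLabel", function(object) {
  cat("RoiLabel ", object@roi, " (", object@hemisphere, "), subject ",
      object@subject, ": ", length(object@vertices),
      " vertices on mesh '", object@meshName, "'\n", sep = "")
})

#' @rdname Cohort-class
setMethod("show", "Cohort", function(object) {
  cat("Cohort [", object@condition, "]: ", length(object@subjects),
      " subjects x ", length(object@rois), " ROIs x ",
      length(object@hemispheres), " hemisphere(s); ",
      length(object@labels), " labels", sep = "")
  if (nrow(object@missing)) {
    cat(" (", nrow(object@missing), " combinations absent)", sep = "")
  }
  cat("\n  mesh: ", meshName(object), " (", nVertices(object@mesh),
      " vertices)\n", sep = "")
})

#' @rdname ProbabilisticMap-class
setMethod("show", "ProbabilisticMap", function(object) {
  cat("ProbabilisticMap ", object@roi, " (", object@hemisphere, ", ",
      object@condition, "): n = ", object@nSubjects, ", support ",
      sum(object@counts > 0L), " / ", length(object@counts),
      " vertices\n", sep = "")
})

#' @rdname ThresholdGrid-class
setMethod("show", "ThresholdGrid", function(object) {
  cat("ThresholdGrid: n = ", object@n, ", levels ",
      paste(format(object@levels, digits = 3), collapse = ", "), "\n",
      sep = "")
})

#' @rdname CvResult-class
setMethod("show", "CvResult", function(object) {
  cat("CvResult ", object@roi, " (", object@hemisphere, ", ",
      object@condition, "): ", length(object@folds), "-fold LOOCV over ",
      length(object@thresholds), " thresholds\n", sep = "")
  best <- which.max(object@diceMean)
  cat("  peak mean dice ", format(object@diceMean[best], digits = 3),
      " at threshold ", format(object@thresholds[best], digits = 3),
      "\n", sep = "")
})

#' @rdname PermutationResult-class
setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed ", format(object@observed, digits = 4),
      ", p = ", format(object@pValue, digits = 4), " (",
      if (object@exact) "exact, " else "", object@nPerm,
      " permutations)\n", sep = "")
})

#' @rdname ChanceNull-class
setMethod("show", "ChanceNull", function(object) {
  cat("ChanceNull for ", object@mroi, " (", object@hemisphere, "): mean ",
      format(object@mean, digits = 4), ", 95% CI [",
      format(object@ciLow, digits = 4), ", ",
      format(object@ciHigh, digits = 4), "], ", object@nIter,
      " iterations\n", sep = "")
})

#' @rdname ComparisonReport-class
setMethod("show", "ComparisonReport", function(object) {
  tab <- object@table
  cat("ComparisonReport: ", nrow(tab), " (mROI, cROI, hemisphere) cells, ",
      sum(tab$significant), " significant at alpha = ", object@alpha,
      " (Bonferroni)\n", sep = "")
})

#' @rdname CohortConfig-class
setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: subdiv ", object@subdiv, " (",
      10L * 4L^object@subdiv + 2L, " vertices), ", object@nSubjects,
      " subjects, ", length(object@roiSpecs), " ROIs, conditions: ",
      paste(sprintf("%s (jitter %.3g rad)", object@conditions,
                    object@centerJitterSD[object@conditions]),
            collapse = ", "),
      ", seed ", object@seed, "\n", sep = "")
})
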