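#' Write a cohort to a directory of label files
#'
#' One FreeSurfer ASCII label per (subject, roi, hemisphere), the shared
#' mesh as a FreeSurfer ASCII surface, and a small JSON manifest (subjects,
#' rois, hemispheres, condition, missing combinations).
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortDirectory <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMesh(cohort@mesh, file.path(dir, "mesh.asc"))
  for (lab in cohort@labels) {
    fname <- sprintf("%s.%s.%s.label", subjectId(lab), hemisphere(lab), roiId(lab))
    writeLabel(lab, cohort@mesh, file.path(dir, fname))
  }
  manifest <- list(
    condition = conditionTag(cohort),
    subjects = subjects(cohort),
    rois = roiIds(cohort),
    hemispheres = cohort@hemispheres,
    mesh = meshName(cohort),
    missing = cohort@missing
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort back from a label directory
#'
#' Inverse of [writeCohortDirectory()].
#'
#' @param dir directory written by [writeCohortDirectory()].
#' @return a [Cohort-class].
#' @export
readCohortDirectory <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mesh <- readMesh(file.path(dir, "mesh.asc"), name = manifest$mesh)
  labels <- list()
  for (s in manifest$subjects) {
    for (r in manifest$rois) {
      for (h in manifest$hemispheres) {
        f <- file.path(dir, sprintf("%s.%s.%s.label", s, h, r))
        if (file.exists(f)) {
          labels[[length(labels) + 1L]] <- readLabel(f, mesh, s, r, h)
        }
      }
    }
  }
  Cohort(mesh, labels, condition = manifest$condition,
         subjects = manifest$subjects, rois = manifest$rois,
         hemispheres = manifest$hemispheres)
}

runStage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full evaluation pipeline on a synthetic configuration
#'
#' End-to-end orchestration: generate the cohorts for every alignment
#' condition; run leave-one-out cross-validation for every region and
#' hemisphere across the full threshold grid; compare the conditions with
#' paired sign-flip permutation tests of the fold-level Dice values at the
#' requested threshold levels (Bonferroni-corrected over regions); derive a
#' displaced second parcellation and quantify its correspondence to the
#' final condition's cohort against resampled chance levels; build the
#' maximum probability map of the final condition; and write everything to
#' \code{outDir}:
#' \itemize{
#'   \item \code{cv_<condition>.tsv} — tidy per-fold, per-threshold Dice;
#'   \item \code{cv_summary.tsv} — per-threshold mean and SE;
#'   \item \code{permtests.json} — one record per (region, threshold);
#'   \item \code{comparison.tsv} — the [ComparisonReport-class] table;
#'   \item \code{mpm.<hemi>.<roi>.label} — the MPM's region patches, value
#'     column carrying the winning probability;
#'   \item \code{manifest.json} — config echo, seeds, package version.
#' }
#' Rerunning with an identical config yields byte-identical outputs.
#'
#' @param config a [CohortConfig-class].
#' @param outDir output directory (created if needed).
#' @param displacement,splitFraction geometry of the derived second
#'   parcellation (see [deriveSecondParcellation()]).
#' @param evalThresholds grid levels at which the conditions are compared
#'   (default: unthresholded and .375).
#' @param nPerm permutations per test (default 10000).
#' @param nIter chance-resampling iterations (default 1000).
#' @param alpha significance level.
#' @param compareCondition condition whose cohort enters the parcellation
#'   comparison and the MPM; default the last condition.
#' @param seed root seed for all resampling; defaults to the config's seed.
#' @return (invisibly) a list with the in-memory results: \code{cohorts},
#'   \code{cvResults}, \code{permTests}, \code{comparison}, \code{mpm},
#'   \code{files}.
#' @export
runFullPipeline <- function(config = cohortConfig(), outDir,
                            displacement = 0.1, splitFraction = 0,
                            evalThresholds = c(0, 0.375),
                            nPerm = 10000L, nIter = 1000L, alpha = 0.05,
                            compareCondition = NULL, seed = NULL) {
  validObject(config)
  if (is.null(seed)) seed <- config@seed
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character()

  mesh <- runStage("mesh", makeIcosphere(config@subdiv))
  cohorts <- runStage("cohort", generateCohort(config, mesh))
  if (is.null(compareCondition)) {
    compareCondition <- config@conditions[length(config@conditions)]
  }

  ## cross-validation sweep, one TSV per condition; a single grid (the full
  ## design's group size) is shared by all regions so that regions with
  ## missing subjects stay comparable at the same levels
  grid <- thresholdGrid(config@nSubjects - 1L)
  cvResults <- list()
  summaryRows <- list()
  for (cond in names(cohorts)) {
    co <- cohorts[[cond]]
    tidy <- list()
    for (hemi in co@hemispheres) {
      for (r in roiIds(co)) {
        cv <- runStage("loocv", loocvDice(co, r, hemi, grid = grid))
        cvResults[[paste(cond, r, hemi, sep = "|")]] <- cv
        tidy[[length(tidy) + 1L]] <- as.data.frame(cv)
        summaryRows[[length(summaryRows) + 1L]] <- data.frame(
          condition = cond, roi = r, hemisphere = hemi,
          threshold = thresholdLevels(cv), diceMean = diceMean(cv),
          diceSE = diceSE(cv), nFolds = length(foldIds(cv)),
          stringsAsFactors = FALSE
        )
      }
    }
    f <- file.path(outDir, sprintf("cv_%s.tsv", cond))
    utils::write.table(do.call(rbind, tidy), f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(outDir, "cv_summary.tsv")
  utils::write.table(do.call(rbind, summaryRows), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  ## permutation tests between the first and last condition
  permTests <- list()
  if (length(config@conditions) >= 2L) {
    condA <- config@conditions[1L]
    condB <- config@conditions[length(config@conditions)]
    nRois <- length(names(config@roiSpecs))
    for (hemi in config@hemisphere) {
      for (r in names(config@roiSpecs)) {
        cvA <- cvResults[[paste(condA, r, hemi, sep = "|")]]
        cvB <- cvResults[[paste(condB, r, hemi, sep = "|")]]
        common <- intersect(foldIds(cvA), foldIds(cvB))
        for (t in evalThresholds) {
          jA <- which(abs(thresholdLevels(cvA) - t) < 1e-9)
          jB <- which(abs(thresholdLevels(cvB) - t) < 1e-9)
          if (length(jA) != 1L || length(jB) != 1L) {
            stop("pipeline stage 'permtest' failed: threshold ", t,
                 " not on the grid", call. = FALSE)
          }
          a <- diceMatrix(cvA)[match(common, foldIds(cvA)), jA]
          b <- diceMatrix(cvB)[match(common, foldIds(cvB)), jB]
          res <- runStage("permtest", pairedPermutationTest(
            a, b, nPerm = nPerm,
            seed = streamSeed(seed, "perm", r, hemi, t)
          ))
          permTests[[length(permTests) + 1L]] <- list(
            roi = r, hemisphere = hemi, threshold = t,
            conditionA = condA, conditionB = condB,
            observedMeanDiff = observedStat(res), pRaw = pValue(res),
            pBonferroni = unname(bonferroniCorrect(pValue(res), nRois)),
            nPerm = res@nPerm, nFolds = length(common),
            seed = res@seed
          )
        }
      }
    }
    f <- file.path(outDir, "permtests.json")
    jsonlite::write_json(permTests, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    files <- c(files, f)
  }

  ## second parcellation and correspondence report
  mrois <- runStage("parcellation", deriveSecondParcellation(
    config, displacement = displacement, splitFraction = splitFraction,
    mesh = mesh
  ))
  comparison <- runStage("comparison", compareAtlases(
    mrois, cohorts[[compareCondition]], alpha = alpha, nIter = nIter,
    seed = streamSeed(seed, "comparison")
  ))
  f <- file.path(outDir, "comparison.tsv")
  utils::write.table(reportTable(comparison), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f)

  ## maximum probability map of the final condition
  co <- cohorts[[compareCondition]]
  mpm <- list()
  for (hemi in co@hemispheres) {
    pmaps <- lapply(roiIds(co), function(r) buildProbMap(co, r, hemi))
    assign <- runStage("mpm", buildMpm(pmaps))
    mpm[[hemi]] <- assign
    for (r in roiIds(co)) {
      vv <- which(assign == r) - 1L
      if (length(vv) == 0L) next
      pm <- pmaps[[match(r, roiIds(co))]]
      lab <- RoiLabel("mpm", r, hemi, vv, co@mesh)
      f <- file.path(outDir, sprintf("mpm.%s.%s.label", hemi, r))
      writeLabel(lab, co@mesh, f, values = probValues(pm)[vv + 1L])
      files <- c(files, f)
    }
  }

  ## manifest: config echo + seeds, no timestamps (reruns are byte-identical)
  cfgFile <- file.path(outDir, "config.yaml")
  writeCohortConfig(config, cfgFile)
  files <- c(files, cfgFile)
  manifest <- list(
    package = "surfAtlas",
    version = as.character(utils::packageVersion("surfAtlas")),
    seed = seed,
    configHash = streamSeed(0L, paste(readLines(cfgFile), collapse = "\n")),
    compareCondition = compareCondition,
    displacement = displacement,
    splitFraction = splitFraction,
    evalThresholds = evalThresholds,
    nPerm = as.integer(nPerm), nIter = as.integer(nIter), alpha = alpha,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohorts = cohorts, cvResults = cvResults,
                 permTests = permTests, comparison = comparison, mpm = mpm,
                 files = c(files, file.path(outDir, "manifest.json"))))
}
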