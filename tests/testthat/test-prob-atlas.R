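test_that("dice coefficient follows its set formula", {
  expect_equal(diceCoefficient(c(1L, 2L, 3L), c(2L, 3L, 4L)), 2 / 3)
  expect_equal(diceCoefficient(0:4, 0:4), 1)
  expect_equal(diceCoefficient(0:4, 10:14), 0)
  # symmetric
  expect_equal(diceCoefficient(0:2, 2:6), diceCoefficient(2:6, 0:2))
  # one empty set is fine, two are an error
  expect_equal(diceCoefficient(integer(), 1:3), 0)
  expect_error(diceCoefficient(integer(), integer()), "undefined")
})

test_that("area-weighted dice honours vertex weights", {
  w <- c(1, 1, 1, 5, 1)  # vertex 3 is heavy
  expect_equal(diceCoefficient(c(0L, 3L), c(3L, 4L), weights = w),
               2 * 5 / (6 + 6))
  # uniform weights reduce to the unweighted value
  expect_equal(diceCoefficient(c(0L, 1L), c(1L, 2L), weights = rep(1, 5)),
               diceCoefficient(c(0L, 1L), c(1L, 2L)))
})

test_that("threshold grids step by 1/n from 0 to 1", {
  g <- thresholdGrid(8)
  expect_equal(thresholdLevels(g), seq(0, 1, by = 0.125))
  expect_error(new("ThresholdGrid", n = 4L, levels = c(0, 0.5, 1)),
               "exactly")
})

test_that("probabilistic maps count subjects per vertex", {
  mesh <- makeStripMesh(12)
  co <- makeToyCohort(list(A = 0:3, B = 2:5), mesh)
  pm <- buildProbMap(co, "roiA", "left")
  expect_equal(nSubjects(pm), 2L)
  expect_equal(probCounts(pm)[1:7], c(1L, 1L, 2L, 2L, 1L, 1L, 0L))
  expect_equal(probValues(pm), probCounts(pm) / 2)

  # single subject: a binary indicator
  pm1 <- buildProbMap(co, "roiA", "left", subjects = "A")
  expect_setequal(which(probValues(pm1) == 1) - 1L, 0:3)
  expect_true(all(probValues(pm1) %in% c(0, 1)))

  # identical labels: values stay binary with full support on the label
  co8 <- makeToyCohort(setNames(rep(list(1:4), 8), paste0("S", 1:8)), mesh)
  pm8 <- buildProbMap(co8, "roiA", "left")
  expect_setequal(which(probValues(pm8) == 1) - 1L, 1:4)
  expect_true(all(probValues(pm8) %in% c(0, 1)))

  expect_error(buildProbMap(co, "roiA", "left", subjects = character()),
               "no subject")
})

test_that("thresholding is inclusive, support-based at 0, and monotone", {
  mesh <- makeStripMesh(20)
  # a 9-subject toy map with counts 0..8 laid out across vertices
  counts <- c(0:8, rep(0L, 11))
  sets <- lapply(1:8, function(s) which(counts >= s) - 1L)
  names(sets) <- paste0("S", 1:8)
  co <- makeToyCohort(sets, mesh)
  pm <- buildProbMap(co, "roiA", "left")
  expect_identical(probCounts(pm), counts)

  # the paper's gloss: .375 of 8 subjects means at least 3 subjects
  expect_setequal(thresholdMap(pm, 0.375), which(counts >= 3L) - 1L)
  # every grid level, checked exhaustively against the count rule
  for (k in 1:8) {
    expect_setequal(thresholdMap(pm, k / 8), which(counts >= k) - 1L)
  }
  # t = 0 is the support, not the whole mesh
  expect_setequal(thresholdMap(pm, 0), which(counts >= 1L) - 1L)
  # t = 1 keeps only full-consensus vertices
  expect_setequal(thresholdMap(pm, 1), which(counts == 8L) - 1L)
  # monotone nesting across the grid
  for (k in 1:7) {
    expect_true(all(thresholdMap(pm, (k + 1) / 8) %in% thresholdMap(pm, k / 8)))
  }
  expect_error(thresholdMap(pm, 1.2), "\\[0, 1\\]")
})

test_that("maximum probability maps assign by argmax with stable ties", {
  mesh <- makeStripMesh(10)
  mkmap <- function(roi, counts, n) {
    new("ProbabilisticMap", roi = roi, hemisphere = "left",
        condition = "c", nSubjects = as.integer(n),
        counts = as.integer(counts), values = counts / n,
        meshName = meshName(mesh))
  }
  # disjoint maps partition the union of supports
  mA <- mkmap("A", c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0), 2)
  mB <- mkmap("B", c(0, 0, 2, 1, 0, 0, 0, 0, 0, 0), 2)
  mpm <- buildMpm(list(mA, mB))
  expect_equal(as.character(mpm[1:5]), c("A", "A", "B", "B", "background"))

  # argmax wins; ties go to the earlier region id; input order irrelevant
  mC <- mkmap("C", c(3, 2, 0, 0, 0, 0, 0, 0, 0, 0), 5)
  mD <- mkmap("D", c(2, 2, 0, 0, 0, 0, 0, 0, 0, 0), 5)
  expect_equal(as.character(buildMpm(list(mC, mD))[1:2]), c("C", "C"))
  expect_identical(buildMpm(list(mD, mC)), buildMpm(list(mC, mD)))

  # minProb masks weak winners
  masked <- buildMpm(list(mC, mD), minProb = 0.5)
  expect_equal(as.character(masked[1:2]), c("C", "background"))

  expect_error(buildMpm(list()), "empty")
})

test_that("loocv dice matches hand-enumerated values on the 6-vertex toy cohort", {
  mesh <- makeStripMesh(6)
  sets <- list(A = 0:2, B = 1:3, C = 2:4)
  co <- makeToyCohort(sets, mesh)
  cv <- loocvDice(co, "roiA", "left")
  expect_identical(foldIds(cv), c("A", "B", "C"))
  expect_equal(thresholdLevels(cv), c(0, 0.5, 1))
  # frozen from hand enumeration of every fold and threshold
  expect_equal(diceMatrix(cv), rbind(
    c(4 / 7, 4 / 7, 0.4),
    c(0.75, 0.75, 0.5),
    c(4 / 7, 4 / 7, 0.4)
  ), ignore_attr = TRUE)
  expect_equal(diceMean(cv), colMeans(diceMatrix(cv)))
  expect_equal(diceSE(cv),
               apply(diceMatrix(cv), 2, sd) / sqrt(3))
})

test_that("loocv dice equals the brute-force oracle on random toy cohorts", {
  mesh <- makeStripMesh(20)
  set.seed(100)
  for (rep in 1:8) {
    nSub <- sample(3:5, 1)
    sets <- lapply(seq_len(nSub), function(i) {
      sort(sample(0:19, sample(3:10, 1)))
    })
    names(sets) <- paste0("S", seq_len(nSub))
    co <- makeToyCohort(sets, mesh)
    cv <- loocvDice(co, "roiA", "left")
    oracle <- bruteLoocvDice(sets, thresholdLevels(cv))
    expect_equal(diceMatrix(cv), oracle, ignore_attr = TRUE)
  }
})

test_that("loocv handles degenerate cohorts per contract", {
  mesh <- makeStripMesh(12)
  # all subjects identical: dice 1 everywhere, SE 0
  same <- makeToyCohort(setNames(rep(list(2:6), 4), paste0("S", 1:4)), mesh)
  cv <- loocvDice(same, "roiA", "left")
  expect_true(all(diceMatrix(cv) == 1))
  expect_true(all(diceSE(cv) == 0))

  # pairwise disjoint subjects: dice 0 everywhere
  disj <- makeToyCohort(list(A = 0:1, B = 3:4, C = 6:7, D = 9:10), mesh)
  cv0 <- loocvDice(disj, "roiA", "left")
  expect_true(all(diceMatrix(cv0) == 0))

  # fewer than 3 subjects is an error
  two <- makeToyCohort(list(A = 0:2, B = 1:3), mesh)
  expect_error(loocvDice(two, "roiA", "left"), "at least 3")
})

test_that("subjects lacking a region are excluded from folds and maps", {
  mesh <- makeStripMesh(12)
  labels <- list(
    RoiLabel("A", "r1", "left", 0:3, mesh),
    RoiLabel("B", "r1", "left", 1:4, mesh),
    RoiLabel("C", "r1", "left", 2:5, mesh),
    RoiLabel("D", "r1", "left", 3:6, mesh),
    RoiLabel("A", "r2", "left", 7:9, mesh),
    RoiLabel("B", "r2", "left", 7:9, mesh),
    RoiLabel("C", "r2", "left", 8:10, mesh)
    # D lacks r2
  )
  co <- Cohort(mesh, labels, condition = "c")
  cv1 <- loocvDice(co, "r1", "left")
  cv2 <- loocvDice(co, "r2", "left")
  expect_length(foldIds(cv1), 4L)
  expect_length(foldIds(cv2), 3L)
  expect_false("D" %in% foldIds(cv2))
  # grid follows the group size (possessing subjects minus one)
  expect_equal(thresholdLevels(cv2), c(0, 0.5, 1))
})
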