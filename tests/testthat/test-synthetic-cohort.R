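test_that("icosphere counts and unit radius follow the subdivision rule", {
  for (s in 0:3) {
    m <- makeIcosphere(s)
    expect_equal(nVertices(m), 10L * 4L^s + 2L)
    expect_equal(nFaces(m), 20L * 4L^s)
    expect_true(all(abs(sqrt(rowSums(meshVertices(m)^2)) - 1) < 1e-12))
  }
  expect_error(makeIcosphere(-1), ">= 0")
})

test_that("geodesic patches are exactly the angular neighborhoods", {
  mesh <- makeIcosphere(3)
  center <- c(0, 0, 1)
  r <- 0.4
  patch <- geodesicPatch(mesh, center, r)
  ang <- acos(pmin(1, meshVertices(mesh) %*% center))
  expect_setequal(patch, which(ang <= r + 1e-12) - 1L)

  # tiny radius: the single nearest vertex
  near <- geodesicPatch(mesh, c(0.1, 0.2, 0.97), 1e-6)
  expect_length(near, 1L)

  # radius pi: everything
  expect_length(geodesicPatch(mesh, center, pi), nVertices(mesh))

  expect_error(geodesicPatch(mesh, center, 0), "radius")
  expect_error(geodesicPatch(mesh, center, 4), "radius")
})

test_that("patch vertex-area sums approximate the spherical cap area", {
  r <- 0.5
  mesh <- makeIcosphere(4)
  patch <- geodesicPatch(mesh, c(0, 0, 1), r)
  va <- vertexAreas(mesh)
  got <- sum(va[patch + 1L])
  # inscribed icosphere slightly under-estimates the sphere; boundary
  # vertices over-count the cap: a few percent at this resolution
  expect_equal(got, capArea(r), tolerance = 0.05)
})

test_that("subject sampling is a pure function of (seed, subject, roi, condition)", {
  cfg <- cohortConfig(subdiv = 2L, nSubjects = 4L, seed = 11L)
  mesh <- makeIcosphere(2L)
  a <- sampleSubjectRoi(cfg, "hOc1", "S02", "CBApm", mesh)
  b <- sampleSubjectRoi(cfg, "hOc1", "S02", "CBApm", mesh)
  expect_identical(vertexSet(a), vertexSet(b))

  # different subject, roi or condition gives a different stream
  c1 <- sampleSubjectRoi(cfg, "hOc1", "S03", "CBApm", mesh)
  c2 <- sampleSubjectRoi(cfg, "hOc2", "S02", "CBApm", mesh)
  expect_false(identical(vertexSet(a), vertexSet(c1)) &&
                 identical(vertexSet(a), vertexSet(c2)))

  # the global RNG stream is left untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(sampleSubjectRoi(cfg, "hOc1", "S01", "CBApm", mesh))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("zero jitter reproduces the noiseless template for every subject", {
  cfg <- cohortConfig(subdiv = 2L, nSubjects = 3L,
                      centerJitterSD = c(CBApm = 0, CBAfs = 0),
                      radiusJitterSD = 0, seed = 5L)
  mesh <- makeIcosphere(2L)
  template <- geodesicPatch(mesh, defaultRoiSpecs()$hOc1$center, 0.25)
  for (s in c("S01", "S02", "S03")) {
    lab <- sampleSubjectRoi(cfg, "hOc1", s, "CBAfs", mesh)
    expect_identical(vertexSet(lab), template)
  }
})

test_that("whole cohorts are deterministic and reflect the design", {
  cfg <- cohortConfig(subdiv = 2L, nSubjects = 9L, seed = 3L,
                      missing = data.frame(subject = "S09",
                                           roi = c("FG1", "FG2")))
  cohorts <- generateCohort(cfg)
  expect_named(cohorts, c("CBApm", "CBAfs"))
  co <- cohorts$CBApm
  # 9 subjects x 4 rois - 2 missing
  expect_length(co@labels, 9L * 4L - 2L)
  expect_equal(nrow(missingCombos(co)), 2L)
  expect_false(hasLabel(co, "S09", "FG1", "left"))
  expect_identical(subjectsWithRoi(co, "FG1", "left"), sprintf("S%02d", 1:8))

  again <- generateCohort(cfg)
  expect_identical(
    lapply(cohorts$CBAfs@labels, vertexSet),
    lapply(again$CBAfs@labels, vertexSet)
  )
})

test_that("mean pairwise dice decreases as center jitter grows", {
  mesh <- makeIcosphere(3L)
  meanPairwiseDice <- function(sd, seed) {
    cfg <- cohortConfig(subdiv = 3L, nSubjects = 6L,
                        roiSpecs = defaultRoiSpecs()["hOc1"],
                        conditions = "only",
                        centerJitterSD = c(only = sd),
                        radiusJitterSD = 0, seed = seed)
    co <- generateCohort(cfg, mesh)$only
    sets <- lapply(subjects(co), function(s) getLabel(co, s, "hOc1", "left"))
    pairs <- utils::combn(length(sets), 2)
    mean(apply(pairs, 2, function(ij) {
      diceCoefficient(sets[[ij[1]]], sets[[ij[2]]])
    }))
  }
  sds <- c(0, 0.05, 0.15, 0.4)
  perSeed <- sapply(1:5, function(seed) {
    sapply(sds, meanPairwiseDice, seed = seed)
  })
  avg <- rowMeans(perSeed)
  expect_true(all(diff(avg) < 0))
  expect_equal(avg[1], 1)  # no jitter: identical patches
})

test_that("derived parcellation has the promised overlap structure", {
  cfg <- cohortConfig(subdiv = 3L, nSubjects = 3L, seed = 2L)
  mesh <- makeIcosphere(3L)

  # displacement 0: identical to the noiseless templates
  mrois <- deriveSecondParcellation(cfg, displacement = 0, mesh = mesh)
  for (m in mrois) {
    spec <- cfg@roiSpecs[[roiId(m)]]
    expect_identical(vertexSet(m),
                     geodesicPatch(mesh, spec$center, spec$radius))
  }

  # displacement >= 2 r: disjoint from the source template
  far <- deriveSecondParcellation(cfg, displacement = 0.6, mesh = mesh)
  for (m in far) {
    spec <- cfg@roiSpecs[[roiId(m)]]
    src <- geodesicPatch(mesh, spec$center, spec$radius)
    expect_length(intersect(vertexSet(m), src), 0L)
  }

  # splitting yields two non-empty pieces partitioning the displaced patch
  halves <- deriveSecondParcellation(cfg, displacement = 0.1,
                                     splitFraction = 0.5, mesh = mesh)
  expect_length(halves, 8L)
  whole <- deriveSecondParcellation(cfg, displacement = 0.1, mesh = mesh)
  a <- vertexSet(halves[[1]]); b <- vertexSet(halves[[2]])
  expect_length(intersect(a, b), 0L)
  expect_setequal(c(a, b), vertexSet(whole[[1]]))
})

test_that("displaced-template overlap matches the spherical lens oracle", {
  r <- 0.25
  d <- r  # displacement equal to the radius
  cfg <- cohortConfig(subdiv = 4L, nSubjects = 3L,
                      roiSpecs = defaultRoiSpecs()["hOc1"],
                      conditions = "only", centerJitterSD = c(only = 0),
                      radiusJitterSD = 0, seed = 1L)
  mesh <- makeIcosphere(4L)
  mroi <- deriveSecondParcellation(cfg, displacement = d, mesh = mesh)[[1]]
  src <- geodesicPatch(mesh, cfg@roiSpecs$hOc1$center, r)
  # area-weighted overlap: icosphere vertex density is not uniform, so raw
  # vertex counts carry a small systematic bias that area weights remove
  va <- vertexAreas(mesh)
  got <- sum(va[intersect(vertexSet(mroi), src) + 1L]) /
    sum(va[vertexSet(mroi) + 1L])
  expected <- capLensArea(r, d) / capArea(r)
  expect_equal(got, expected, tolerance = 0.02)
  # the unweighted proportion agrees more loosely
  gotCount <- overlapProportion(mroi, RoiLabel("t", "hOc1", "left", src, mesh))
  expect_equal(gotCount, expected, tolerance = 0.12)
})

test_that("configs round-trip through YAML", {
  cfg <- cohortConfig(subdiv = 3L, nSubjects = 7L, seed = 77L,
                      missing = data.frame(subject = "S07", roi = "FG2"))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeCohortConfig(cfg, path)
  back <- readCohortConfig(path)
  expect_equal(back@subdiv, cfg@subdiv)
  expect_equal(back@nSubjects, cfg@nSubjects)
  expect_equal(back@centerJitterSD, cfg@centerJitterSD)
  expect_equal(back@roiSpecs, cfg@roiSpecs, tolerance = 1e-12)
  expect_equal(back@missing$roi, "FG2")
  expect_identical(back@seed, cfg@seed)
  # the round-tripped config regenerates the identical cohort
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(back)
  expect_identical(lapply(c1$CBApm@labels, vertexSet),
                   lapply(c2$CBApm@labels, vertexSet))
})
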