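## Deterministic stream splitting: every random label draws from its own
## substream keyed by (root seed, subject, roi, condition), so adding a
## subject or condition never perturbs any other label.

streamSeed <- function(root, ...) {
  s <- paste(root, ..., sep = "|")
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Unit icosphere mesh
#'
#' Repeated 4-way subdivision of a regular icosahedron with re-projection of
#' every vertex onto the unit sphere: the standard desk-scale stand-in for a
#' spherical registration surface. Vertex count is \code{10 * 4^subdiv + 2},
#' face count \code{20 * 4^subdiv}.
#'
#' @param subdiv subdivision level, an integer >= 0.
#' @param name mesh tag.
#' @return a [TriangleMesh-class] with all vertices at unit radius.
#' @examples
#' nVertices(makeIcosphere(2))  # 162
#' @export
makeIcosphere <- function(subdiv, name = sprintf("icosphere%d", subdiv)) {
  subdiv <- as.integer(subdiv)
  if (is.na(subdiv) || subdiv < 0L) stop("subdiv must be >= 0", call. = FALSE)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1)
  )
  for (lev in seq_len(subdiv)) {
    nf <- nrow(f)
    f1 <- f[, 1L]; f2 <- f[, 2L]; f3 <- f[, 3L]
    # one new vertex per unique edge, at the normalized midpoint
    e <- rbind(cbind(pmin(f1, f2), pmax(f1, f2)),
               cbind(pmin(f2, f3), pmax(f2, f3)),
               cbind(pmin(f3, f1), pmax(f3, f1)))
    key <- paste(e[, 1L], e[, 2L])
    firstOfKey <- !duplicated(key)
    mid <- nrow(v) + match(key, key[firstOfKey]) - 1L
    ue <- e[firstOfKey, , drop = FALSE]
    mids <- v[ue[, 1L] + 1L, , drop = FALSE] + v[ue[, 2L] + 1L, , drop = FALSE]
    v <- rbind(v, mids / sqrt(rowSums(mids^2)))
    ab <- mid[seq_len(nf)]
    bc <- mid[nf + seq_len(nf)]
    ca <- mid[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f1, ab, ca), cbind(f2, bc, ab),
               cbind(f3, ca, bc), cbind(ab, bc, ca))
  }
  TriangleMesh(v, f, name = name, checkConnected = FALSE)
}

#' Geodesic patch (spherical cap) on a sphere mesh
#'
#' All vertices whose great-circle angle to \code{center} is at most
#' \code{radius}. The vertex nearest the center is always included, so the
#' patch is never empty.
#'
#' @param mesh a sphere [TriangleMesh-class].
#' @param center unit 3-vector giving the cap's central direction.
#' @param radius geodesic radius in radians, in (0, pi).
#' @return sorted 0-based vertex indices.
#' @export
geodesicPatch <- function(mesh, center, radius) {
  if (radius <= 0 || radius > pi) {
    stop("radius must lie in (0, pi]", call. = FALSE)
  }
  center <- center / sqrt(sum(center^2))
  v <- meshVertices(mesh)
  v <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(1, pmax(-1, as.vector(v %*% center))))
  inside <- which(ang <= radius + 1e-12)
  inside <- union(inside, which.min(ang))
  sort(inside) - 1L
}

tangentBasis <- function(center) {
  axis <- if (abs(center[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(
    center[2L] * axis[3L] - center[3L] * axis[2L],
    center[3L] * axis[1L] - center[1L] * axis[3L],
    center[1L] * axis[2L] - center[2L] * axis[1L]
  )
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    center[2L] * e1[3L] - center[3L] * e1[2L],
    center[3L] * e1[1L] - center[1L] * e1[3L],
    center[1L] * e1[2L] - center[2L] * e1[1L]
  )
  list(e1 = e1, e2 = e2 / sqrt(sum(e2^2)))
}

rotateToward <- function(center, direction, angle) {
  cos(angle) * center + sin(angle) * direction
}

#' Configuration of a synthetic surface cohort
#'
#' The generator emulates N aligned subjects sharing K template regions on a
#' common sphere: each subject's region is a geodesic cap whose center is
#' displaced by a tangent-plane Gaussian (SD in radians, one per alignment
#' condition — residual misalignment after surface registration to that
#' condition's template) and whose radius is perturbed by a Gaussian
#' (inter-individual size variability). Defaults: a 2562-vertex icosphere,
#' 9 subjects, 4 well-separated caps of radius 0.25 rad, and two conditions
#' differing only in center jitter (0.06 vs 0.15 rad).
#'
#' @param subdiv icosphere subdivision level.
#' @param nSubjects number of subjects.
#' @param roiSpecs named list of \code{list(center =, radius =)} templates;
#'   centers are unit 3-vectors, radii geodesic radians.
#' @param conditions alignment-condition tags.
#' @param centerJitterSD per-condition tangent-plane SD (radians), named by
#'   condition.
#' @param radiusJitterSD SD of the radius perturbation (radians).
#' @param hemisphere hemisphere tag for every label.
#' @param missing data.frame with subject/roi columns marking combinations
#'   absent from the cohort (e.g. regions a brain's histology did not allow
#'   identifying).
#' @param seed root seed; all generator output is a pure function of the
#'   config.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(subdiv = 4L,
                         nSubjects = 9L,
                         roiSpecs = defaultRoiSpecs(),
                         conditions = c("CBApm", "CBAfs"),
                         centerJitterSD = c(CBApm = 0.06, CBAfs = 0.15),
                         radiusJitterSD = 0.03,
                         hemisphere = "left",
                         missing = data.frame(subject = character(),
                                              roi = character()),
                         seed = 1234L) {
  new("CohortConfig",
      subdiv = as.integer(subdiv), nSubjects = as.integer(nSubjects),
      roiSpecs = roiSpecs, conditions = conditions,
      centerJitterSD = centerJitterSD[conditions],
      radiusJitterSD = radiusJitterSD, hemisphere = hemisphere,
      missing = missing, seed = as.integer(seed))
}

#' @rdname cohortConfig
#' @export
defaultRoiSpecs <- function() {
  s <- 1 / sqrt(3)
  list(
    hOc1 = list(center = c(s, s, s), radius = 0.25),
    hOc2 = list(center = c(s, -s, -s), radius = 0.25),
    FG1 = list(center = c(-s, s, -s), radius = 0.25),
    FG2 = list(center = c(-s, -s, s), radius = 0.25)
  )
}

cohortSubjects <- function(config) sprintf("S%02d", seq_len(config@nSubjects))

#' Sample one subject's jittered region
#'
#' The template center is displaced in its tangent plane by a bivariate
#' Gaussian with the condition's SD and renormalized to the sphere; the
#' radius gets an additive Gaussian perturbation, resampled (at most 100
#' times) if it leaves (0, pi). The draw is a pure function of
#' (config seed, subject, roi, condition).
#'
#' @param config a [CohortConfig-class].
#' @param roi name of a roi spec in the config.
#' @param subject subject id (as produced by the generator, e.g.
#'   \code{"S03"}).
#' @param condition one of the config's condition tags.
#' @param mesh the icosphere; built from the config when omitted.
#' @return a [RoiLabel-class].
#' @export
sampleSubjectRoi <- function(config, roi, subject, condition, mesh = NULL) {
  validObject(config)
  if (is.null(mesh)) mesh <- makeIcosphere(config@subdiv)
  spec <- config@roiSpecs[[roi]]
  if (is.null(spec)) stop("unknown roi '", roi, "'", call. = FALSE)
  if (!(condition %in% config@conditions)) {
    stop("unknown condition '", condition, "'", call. = FALSE)
  }
  sdC <- unname(config@centerJitterSD[[condition]])
  sdR <- config@radiusJitterSD
  withSeed(streamSeed(config@seed, subject, roi, condition), {
    center <- spec$center
    if (sdC > 0) {
      tb <- tangentBasis(center)
      d <- rnorm(1L, 0, sdC) * tb$e1 + rnorm(1L, 0, sdC) * tb$e2
      center <- center + d
      center <- center / sqrt(sum(center^2))
    }
    radius <- spec$radius
    if (sdR > 0) {
      ok <- FALSE
      for (tryi in 1:100) {
        r <- spec$radius + rnorm(1L, 0, sdR)
        if (r > 0 && r < pi) { radius <- r; ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not sample a radius in (0, pi) for roi '", roi,
             "' after 100 attempts", call. = FALSE)
      }
    }
    RoiLabel(subject, roi, config@hemisphere,
             geodesicPatch(mesh, center, radius), mesh)
  })
}

#' Generate the full synthetic study
#'
#' One [Cohort-class] per alignment condition; conditions share the subject
#' list and ROI templates but use condition-specific center jitter, so any
#' downstream difference between them reflects alignment precision alone.
#' Combinations listed in the config's \code{missing} table are omitted
#' from the labels and recorded in each cohort's missing table.
#'
#' @param config a [CohortConfig-class].
#' @param mesh optional pre-built icosphere (saves rebuilding).
#' @return named list of [Cohort-class], one per condition.
#' @examples
#' cfg <- cohortConfig(subdiv = 2L, nSubjects = 4L, seed = 1L)
#' cohorts <- generateCohort(cfg)
#' names(cohorts)
#' @export
generateCohort <- function(config, mesh = NULL) {
  validObject(config)
  if (is.null(mesh)) mesh <- makeIcosphere(config@subdiv)
  subs <- cohortSubjects(config)
  rois <- names(config@roiSpecs)
  missKey <- paste(config@missing$subject, config@missing$roi)
  out <- lapply(config@conditions, function(cond) {
    labels <- list()
    for (s in subs) {
      for (r in rois) {
        if (paste(s, r) %in% missKey) next
        labels[[length(labels) + 1L]] <- sampleSubjectRoi(config, r, s, cond, mesh)
      }
    }
    Cohort(mesh, labels, condition = cond, subjects = subs, rois = rois,
           hemispheres = config@hemisphere)
  })
  names(out) <- config@conditions
  out
}

#' Derive a second, group-level parcellation
#'
#' Builds group-level regions from the config's templates with a known
#' geometric relationship to them: each template center is rotated by
#' \code{displacement} radians along its first tangent direction, and the
#' resulting cap can be cut in two by a plane with normal along the second
#' tangent direction (a great circle when \code{splitFraction = 0.5}). With
#' zero displacement and no split the derived regions coincide with the
#' noiseless templates, which pins down the ground-truth overlap structure
#' for testing.
#'
#' @param config a [CohortConfig-class].
#' @param displacement rotation of each center, radians.
#' @param splitFraction 0 for no split; otherwise the approximate fraction
#'   of each region's vertices assigned to the second piece (suffixes
#'   \code{.a} / \code{.b}).
#' @param subject subject tag for the group-level labels.
#' @param mesh optional pre-built icosphere.
#' @return list of [RoiLabel-class].
#' @export
deriveSecondParcellation <- function(config, displacement = 0,
                                     splitFraction = 0, subject = "atlas",
                                     mesh = NULL) {
  validObject(config)
  if (displacement < 0 || displacement >= pi) {
    stop("displacement must lie in [0, pi)", call. = FALSE)
  }
  if (splitFraction < 0 || splitFraction >= 1) {
    stop("splitFraction must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(mesh)) mesh <- makeIcosphere(config@subdiv)
  v <- meshVertices(mesh)
  out <- list()
  for (r in names(config@roiSpecs)) {
    spec <- config@roiSpecs[[r]]
    tb <- tangentBasis(spec$center)
    center <- rotateToward(spec$center, tb$e1, displacement)
    patch <- geodesicPatch(mesh, center, spec$radius)
    if (splitFraction == 0) {
      out[[length(out) + 1L]] <- RoiLabel(subject, r, config@hemisphere, patch, mesh)
    } else {
      proj <- as.vector(v[patch + 1L, , drop = FALSE] %*% tb$e2)
      cut <- stats::quantile(proj, splitFraction, names = FALSE)
      second <- patch[proj <= cut]
      first <- setdiff(patch, second)
      if (length(first) == 0L || length(second) == 0L) {
        out[[length(out) + 1L]] <- RoiLabel(subject, r, config@hemisphere, patch, mesh)
      } else {
        out[[length(out) + 1L]] <- RoiLabel(subject, paste0(r, ".a"),
                                            config@hemisphere, first, mesh)
        out[[length(out) + 1L]] <- RoiLabel(subject, paste0(r, ".b"),
                                            config@hemisphere, second, mesh)
      }
    }
  }
  out
}

## ---- config (de)serialization ---------------------------------------------

#' Read / write a cohort configuration as YAML
#'
#' @param config a [CohortConfig-class].
#' @param path file path.
#' @return \code{readCohortConfig}: a [CohortConfig-class];
#'   \code{writeCohortConfig}: \code{path}, invisibly.
#' @export
writeCohortConfig <- function(config, path) {
  validObject(config)
  lst <- list(
    subdiv = config@subdiv,
    nSubjects = config@nSubjects,
    roiSpecs = lapply(config@roiSpecs, function(sp) {
      list(center = as.numeric(sp$center), radius = as.numeric(sp$radius))
    }),
    conditions = as.list(config@conditions),
    centerJitterSD = as.list(config@centerJitterSD),
    radiusJitterSD = config@radiusJitterSD,
    hemisphere = config@hemisphere,
    missing = if (nrow(config@missing)) {
      list(subject = config@missing$subject, roi = config@missing$roi)
    } else NULL,
    seed = config@seed
  )
  yaml::write_yaml(lst, path, precision = 15L)
  invisible(path)
}

#' @rdname writeCohortConfig
#' @export
readCohortConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  missing <- if (is.null(lst$missing)) {
    data.frame(subject = character(), roi = character())
  } else {
    data.frame(subject = unlist(lst$missing$subject),
               roi = unlist(lst$missing$roi))
  }
  cohortConfig(
    subdiv = lst$subdiv,
    nSubjects = lst$nSubjects,
    roiSpecs = lapply(lst$roiSpecs, function(sp) {
      list(center = as.numeric(unlist(sp$center)), radius = sp$radius)
    }),
    conditions = unlist(lst$conditions),
    centerJitterSD = unlist(lst$centerJitterSD),
    radiusJitterSD = lst$radiusJitterSD,
    hemisphere = lst$hemisphere,
    missing = missing,
    seed = lst$seed
  )
}
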