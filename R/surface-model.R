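#' Construct a TriangleMesh
#'
#' @param vertices numeric matrix (n x 3) of coordinates in mm.
#' @param faces matrix (m x 3) of 0-based vertex indices.
#' @param name mesh tag carried into labels that reference this mesh.
#' @param checkConnected if TRUE (default) warn when the mesh is not a
#'   single connected component; disconnection is tolerated but suspicious
#'   for a cortical surface.
#' @return a [TriangleMesh-class].
#' @examples
#' mesh <- makeIcosphere(0)
#' nVertices(mesh)  # 12
#' @export
TriangleMesh <- function(vertices, faces, name = "mesh", checkConnected = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  obj <- new("TriangleMesh", vertices = vertices, faces = faces, name = name)
  if (checkConnected && nrow(vertices) > 1L && !isMeshConnected(obj)) {
    warning("mesh '", name, "' is not a single connected component",
            call. = FALSE)
  }
  obj
}

isMeshConnected <- function(mesh) {
  n <- nVertices(mesh)
  if (n <= 1L) return(TRUE)
  adj <- vertexNeighbors(mesh)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    nb <- adj[[cur]] + 1L
    fresh <- nb[!seen[nb]]
    seen[fresh] <- TRUE
    queue <- c(queue, fresh)
  }
  all(seen)
}

#' Construct a RoiLabel
#'
#' @param subject,roi subject and region identifiers.
#' @param hemisphere \code{"left"} or \code{"right"}.
#' @param vertices 0-based vertex indices (deduplicated and sorted).
#' @param mesh the [TriangleMesh-class] the indices refer to, or a mesh
#'   name when index validation against geometry is not wanted.
#' @return a [RoiLabel-class].
#' @examples
#' mesh <- makeIcosphere(0)
#' lab <- RoiLabel("S01", "hOc1", "left", c(0L, 3L, 5L), mesh)
#' vertexSet(lab)
#' @export
RoiLabel <- function(subject, roi, hemisphere, vertices, mesh) {
  v <- sort(unique(as.integer(vertices)))
  if (is(mesh, "TriangleMesh")) {
    if (length(v) && (anyNA(v) || any(v < 0L) || any(v >= nVertices(mesh)))) {
      stop("vertex indices out of range for mesh '", meshName(mesh),
           "' (valid range 0..", nVertices(mesh) - 1L, ")", call. = FALSE)
    }
    mname <- meshName(mesh)
  } else {
    mname <- as.character(mesh)
  }
  new("RoiLabel", subject = subject, roi = roi, hemisphere = hemisphere,
      vertices = v, meshName = mname)
}

#' Assemble a Cohort from labels
#'
#' Builds the study container for one alignment condition. Any
#' (subject, roi, hemisphere) combination without a label is recorded in
#' the cohort's \code{missing} table; such combinations are excluded from
#' group maps and cross-validation folds downstream rather than treated as
#' empty regions.
#'
#' @param mesh shared [TriangleMesh-class].
#' @param labels list of [RoiLabel-class] objects.
#' @param condition alignment-condition tag.
#' @param subjects,rois,hemispheres orderings; derived from the labels when
#'   omitted. The roi ordering is canonical for tie-breaking in
#'   [buildMpm()].
#' @return a [Cohort-class].
#' @export
Cohort <- function(mesh, labels, condition = "default",
                   subjects = NULL, rois = NULL, hemispheres = NULL) {
  if (is.null(subjects)) subjects <- unique(vapply(labels, subjectId, ""))
  if (is.null(rois)) rois <- unique(vapply(labels, roiId, ""))
  if (is.null(hemispheres)) hemispheres <- unique(vapply(labels, hemisphere, ""))
  names(labels) <- vapply(
    labels, function(l) labelKey(subjectId(l), roiId(l), hemisphere(l)), ""
  )
  if (anyDuplicated(names(labels))) {
    stop("duplicate (subject, roi, hemisphere) labels", call. = FALSE)
  }
  grid <- expand.grid(
    subject = subjects, roi = rois, hemisphere = hemispheres,
    stringsAsFactors = FALSE
  )
  absent <- !(labelKey(grid$subject, grid$roi, grid$hemisphere) %in% names(labels))
  missing <- grid[absent, , drop = FALSE]
  rownames(missing) <- NULL
  new("Cohort", mesh = mesh, subjects = subjects, rois = rois,
      hemispheres = hemispheres, condition = condition, labels = labels,
      missing = missing)
}

#' Subjects of a cohort that possess a given region
#'
#' @param cohort a [Cohort-class].
#' @param roi,hemi region and hemisphere identifiers.
#' @return character vector of subject ids, in cohort order.
#' @export
subjectsWithRoi <- function(cohort, roi, hemi) {
  keep <- vapply(subjects(cohort), function(s) hasLabel(cohort, s, roi, hemi),
                 logical(1))
  subjects(cohort)[keep]
}

#' Edge adjacency of a mesh
#'
#' @param mesh a [TriangleMesh-class].
#' @return list of length \code{nVertices(mesh)}; element \code{i} holds the
#'   sorted 0-based indices of the vertices sharing an edge with vertex
#'   \code{i - 1}. Symmetric and free of self-loops by construction.
#' @export
vertexNeighbors <- function(mesh) {
  f <- meshFaces(mesh)
  n <- nVertices(mesh)
  from <- c(f[, 1L], f[, 2L], f[, 3L], f[, 2L], f[, 3L], f[, 1L]) + 1L
  to <- c(f[, 2L], f[, 3L], f[, 1L], f[, 1L], f[, 2L], f[, 3L])
  adj <- split(to, factor(from, levels = seq_len(n)))
  lapply(adj, function(x) sort(unique(x)))
}

#' Triangle and per-vertex areas
#'
#' \code{faceAreas} returns the Euclidean area of each triangle;
#' \code{vertexAreas} distributes each triangle's area equally to its three
#' corners (the barycentric lumped vertex area), so the areas of a vertex
#' set sum to the surface area of its patch up to boundary effects.
#'
#' @param mesh a [TriangleMesh-class].
#' @return numeric vector (per face, resp. per vertex).
#' @export
faceAreas <- function(mesh) {
  v <- meshVertices(mesh)
  f <- meshFaces(mesh) + 1L
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname faceAreas
#' @export
vertexAreas <- function(mesh) {
  fa <- faceAreas(mesh)
  f <- meshFaces(mesh)
  va <- numeric(nVertices(mesh))
  for (col in 1:3) {
    s <- rowsum(fa, group = f[, col])
    va[as.integer(rownames(s)) + 1L] <- va[as.integer(rownames(s)) + 1L] + s[, 1L] / 3
  }
  va
}

## ---- FreeSurfer ASCII label I/O -------------------------------------------

#' Read a FreeSurfer ASCII label file
#'
#' The format is: one comment line, one line with the vertex count, then one
#' row per vertex: \code{index x y z value}. Indices are 0-based, as in the
#' file. The coordinate and value columns are carried along but ignored by
#' all set arithmetic.
#'
#' @param path file to read.
#' @param mesh the [TriangleMesh-class] the label lives on; indices are
#'   validated against it.
#' @param subject,roi,hemisphere identity tags for the resulting label.
#' @return a [RoiLabel-class].
#' @export
readLabel <- function(path, mesh, subject, roi, hemisphere) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("label file '", path, "': fewer than 2 lines", call. = FALSE)
  }
  start <- if (startsWith(trimws(lines[1L]), "#")) 2L else 1L
  count <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(count) || count < 0L) {
    stop("label file '", path, "', line ", start,
         ": expected a vertex count", call. = FALSE)
  }
  body <- lines[seq.int(start + 1L, length.out = length(lines) - start)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != count) {
    stop("label file '", path, "': count line says ", count,
         " vertices but ", length(body), " data rows found", call. = FALSE)
  }
  idx <- integer(count)
  for (i in seq_len(count)) {
    fields <- strsplit(trimws(body[i]), "[[:space:]]+")[[1L]]
    val <- suppressWarnings(as.integer(fields[1L]))
    if (length(fields) < 5L || is.na(val)) {
      stop("label file '", path, "', line ", start + i,
           ": malformed row (expected 'index x y z value')", call. = FALSE)
    }
    idx[i] <- val
  }
  RoiLabel(subject, roi, hemisphere, idx, mesh)
}

#' Write a FreeSurfer ASCII label file
#'
#' Coordinates are taken from the mesh; the value column carries the
#' supplied per-vertex values (e.g. probabilistic-map values) or 0.
#'
#' @param label a [RoiLabel-class].
#' @param mesh the mesh supplying coordinates.
#' @param path output file.
#' @param values optional numeric, one value per label vertex (in the order
#'   of \code{vertexSet(label)}).
#' @return \code{path}, invisibly.
#' @export
writeLabel <- function(label, mesh, path, values = NULL) {
  validObject(label)
  v <- vertexSet(label)
  if (any(v >= nVertices(mesh))) {
    stop("label indices exceed mesh '", meshName(mesh), "'", call. = FALSE)
  }
  if (is.null(values)) values <- numeric(length(v))
  if (length(values) != length(v)) {
    stop("values must have one entry per label vertex", call. = FALSE)
  }
  coords <- meshVertices(mesh)[v + 1L, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#!ascii label, subject %s, roi %s, hemisphere %s",
                     subjectId(label), roiId(label), hemisphere(label)), con)
  writeLines(as.character(length(v)), con)
  writeLines(sprintf("%d  %.6f  %.6f  %.6f %.10f",
                     v, coords[, 1L], coords[, 2L], coords[, 3L], values), con)
  invisible(path)
}

## ---- mesh I/O (OFF and FreeSurfer ASCII surface) ---------------------------

meshFormatFromPath <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    off = "off",
    asc = "fsascii",
    stop("cannot infer mesh format from extension '.", ext,
         "'; pass format = \"off\" or \"fsascii\"", call. = FALSE)
  )
}

#' Read / write triangle meshes
#'
#' Supports the OFF format and the FreeSurfer ASCII surface format (the
#' \code{.asc} output of \code{mris_convert}). The dialect is inferred from
#' the file extension (\code{.off} / \code{.asc}) unless given explicitly.
#' Round-trips preserve connectivity bit-exactly; coordinates are written
#' with 6 decimals.
#'
#' @param path file to read or write.
#' @param format \code{"auto"}, \code{"off"} or \code{"fsascii"}.
#' @param name mesh tag; defaults to the file name without extension.
#' @return \code{readMesh}: a [TriangleMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "off", "fsascii"), name = NULL) {
  format <- meshFormatFromPath(path, match.arg(format))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "off") {
    if (toupper(trimws(lines[1L])) != "OFF") {
      stop("'", path, "' is not an OFF file (missing OFF header)", call. = FALSE)
    }
    counts <- as.integer(strsplit(trimws(lines[2L]), "[[:space:]]+")[[1L]])
    nv <- counts[1L]; nf <- counts[2L]
    vrows <- lines[3:(2L + nv)]
    frows <- lines[(3L + nv):(2L + nv + nf)]
    verts <- do.call(rbind, lapply(vrows, function(l) {
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])
    }))
    faces <- do.call(rbind, lapply(seq_along(frows), function(i) {
      fields <- as.integer(strsplit(trimws(frows[i]), "[[:space:]]+")[[1L]])
      if (fields[1L] != 3L) {
        stop("'", path, "': face ", i - 1L, " has ", fields[1L],
             " vertices; only triangles are supported", call. = FALSE)
      }
      fields[2:4]
    }))
  } else {
    start <- if (startsWith(trimws(lines[1L]), "#")) 2L else 1L
    counts <- as.integer(strsplit(trimws(lines[start]), "[[:space:]]+")[[1L]])
    nv <- counts[1L]; nf <- counts[2L]
    vrows <- lines[(start + 1L):(start + nv)]
    frows <- lines[(start + nv + 1L):(start + nv + nf)]
    verts <- do.call(rbind, lapply(vrows, function(l) {
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])
    }))
    faces <- do.call(rbind, lapply(frows, function(l) {
      as.integer(strsplit(trimws(l), "[[:space:]]+")[[1L]][1:3])
    }))
  }
  TriangleMesh(verts, faces, name = name, checkConnected = FALSE)
}

#' @rdname readMesh
#' @param mesh a [TriangleMesh-class] to write.
#' @return \code{writeMesh}: \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, format = c("auto", "off", "fsascii")) {
  format <- meshFormatFromPath(path, match.arg(format))
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.6f %.6f %.6f", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  } else {
    writeLines(sprintf("#!ascii version of %s", meshName(mesh)), con)
    writeLines(sprintf("%d %d", nrow(v), nrow(f)), con)
    writeLines(sprintf("%.6f  %.6f  %.6f  0", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("%d %d %d 0", f[, 1L], f[, 2L], f[, 3L]), con)
  }
  invisible(path)
}
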