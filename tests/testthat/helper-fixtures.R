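# Fixtures built in code, plus independent oracles used by the tests. The
# oracles deliberately share no code with the package internals.

## regular tetrahedron inscribed in the unit sphere
makeTetrahedron <- function() {
  s <- 1 / sqrt(3)
  v <- rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s))
  f <- rbind(c(0, 1, 2), c(0, 3, 1), c(0, 2, 3), c(1, 3, 2))
  TriangleMesh(v, f, name = "tetra")
}

## planar zig-zag strip with n >= 3 vertices: connected, all faces triangles
makeStripMesh <- function(n, name = sprintf("strip%d", n)) {
  v <- cbind(seq_len(n) - 1, seq_len(n) %% 2, 0)
  f <- cbind(0:(n - 3L), 1:(n - 2L), 2:(n - 1L))
  TriangleMesh(v, f, name = name)
}

## cohort on a toy mesh from a named list of 0-based vertex sets
makeToyCohort <- function(vertexSets, mesh, roi = "roiA", hemi = "left",
                          condition = "toy") {
  labels <- lapply(names(vertexSets), function(s) {
    RoiLabel(s, roi, hemi, vertexSets[[s]], mesh)
  })
  Cohort(mesh, labels, condition = condition)
}

## ---- oracle: brute-force LOOCV dice (independent nested loops) ------------
bruteLoocvDice <- function(vertexSets, thresholds) {
  subs <- names(vertexSets)
  out <- matrix(NA_real_, nrow = length(subs), ncol = length(thresholds),
                dimnames = list(subs, NULL))
  for (s in subs) {
    held <- vertexSets[[s]]
    others <- vertexSets[setdiff(subs, s)]
    n <- length(others)
    cnt <- table(unlist(others))
    for (j in seq_along(thresholds)) {
      t <- thresholds[j]
      keep <- if (t == 0) {
        as.integer(names(cnt))
      } else {
        as.integer(names(cnt)[as.vector(cnt) / n >= t - 1e-12])
      }
      inter <- sum(held %in% keep)
      out[s, j] <- 2 * inter / (length(held) + length(keep))
    }
  }
  out
}

## ---- oracle: exact sign-flip p by bit-mask enumeration --------------------
exactSignFlipP <- function(d) {
  n <- length(d)
  tObs <- abs(mean(d))
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(0:(n - 1))) > 0, 1, -1)
    if (abs(mean(signs * d)) >= tObs - 1e-12) hits <- hits + 1L
  }
  hits / 2^n
}

## ---- oracle: spherical cap and cap-intersection (lens) areas --------------
capArea <- function(r) 2 * pi * (1 - cos(r))

# area of the intersection of two caps of equal angular radius r whose
# centers are separated by angle d, via 1-D quadrature in colatitude
# around the first center
capLensArea <- function(r, d) {
  if (d >= 2 * r) return(0)
  if (d <= 0) return(capArea(r))
  f <- function(theta) {
    u <- (cos(r) - cos(theta) * cos(d)) / (sin(theta) * sin(d))
    phi <- acos(pmin(1, pmax(-1, u)))
    2 * phi * sin(theta)
  }
  stats::integrate(f, 0, r, rel.tol = 1e-10)$value
}

## ---- oracle: Friedman p by permutation of treatment labels ---------------
friedmanPermP <- function(x, nPerm = 2000, seed = 99) {
  stat <- function(m) {
    r <- t(apply(m, 1, rank))
    n <- nrow(m); k <- ncol(m)
    s <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
    ties <- sum(apply(m, 1, function(row) { tt <- table(row); sum(tt^3 - tt) }))
    C <- 1 - ties / (n * k * (k^2 - 1))
    if (C <= 0) 0 else s / C
  }
  obs <- stat(x)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    perm <- t(apply(x, 1, sample))
    if (stat(perm) >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + nPerm)
}

## small deterministic label-pool builder for chance-null tests: labels on a
## strip mesh whose overlap with a fixed reference is set by construction
makeOverlapPool <- function(mesh, ref, overlaps) {
  # ref: 0-based vertex set of size L; overlaps: desired |ref n lab| / |ref|
  L <- length(ref)
  total <- nVertices(mesh)
  lapply(seq_along(overlaps), function(i) {
    kIn <- round(overlaps[i] * L)
    inside <- if (kIn > 0) ref[seq_len(kIn)] else integer()
    outPool <- setdiff(0:(total - 1L), ref)
    outside <- outPool[seq_len(L - kIn)]
    RoiLabel(sprintf("P%03d", i), sprintf("r%03d", i), "left",
             c(inside, outside), mesh)
  })
}
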