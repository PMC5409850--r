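---
title: "Evaluating probabilistic surface atlases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating probabilistic surface atlases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfAtlas)
```

## The problem

When a region of interest (ROI) — for instance a cytoarchitectonically
defined visual area — has been delineated in each of N individual brains and
all N cortical surfaces have been registered to a common template, the
group-level summary is a *probabilistic map*: for every vertex of the shared
surface, the fraction of subjects whose ROI contains that vertex. Two
questions follow immediately:

1. **Predictability.** How well does the group map predict the ROI of a new
   individual, and at which probability threshold is the prediction best?
   This also measures the quality of the surface registration: a template
   that aligns the relevant anatomy well concentrates the individual ROIs,
   and the group map predicts better.
2. **Correspondence.** How does the resulting parcellation relate to a
   second parcellation of the same cortex, obtained with different criteria?

surfAtlas implements both analyses, together with a synthetic cohort
generator that reproduces their statistical structure on a sphere, so every
stage can be exercised and tested without any imaging data.

## Cross-validated predictability

Predictability is scored by exhaustive leave-one-out cross-validation. For
each subject in turn, the group probabilistic map *G* is built from the
remaining subjects, thresholded at a level *t*, and compared with the
left-out subject's ROI *I* using the Dice coefficient

$$dc = \frac{2\,|I \cap G|}{|I| + |G|},$$

which is 0 for disjoint sets and 1 for coincident ones. Thresholds sweep
the full grid attainable by an n-subject group map, $t \in \{0, 1/n,
\dots, 1\}$ — steps of .125 when n = 8. Per-threshold means and standard
errors (sample SD divided by $\sqrt{\text{folds}}$; the n−1 denominator
convention is stated because it matters at 9 folds) across folds give the
familiar rising-then-falling predictability curve: very low thresholds
admit noise vertices, very high ones keep only the consensus core.

Three semantic choices deserve a note:

* **Thresholding is inclusive** (`values >= t`), because a level of .375
  on an 8-subject map must keep vertices shared by *at least three*
  subjects. The comparison is implemented on integer counts
  (`counts >= t * n` with a 1e-9 guard) so binary floating point cannot
  flip a boundary vertex.
* **t = 0 means the map's support** (counts ≥ 1), not the whole mesh;
  otherwise the unthresholded entry of the sweep would be dominated by the
  size of the template sphere rather than by the data.
* **Grid levels are group-size specific.** Levels often quoted for such
  sweeps (.33, .375, …) are count cutoffs only for particular group sizes
  (3 of 9, 3 of 8). `loocvDice()` therefore takes an explicit
  `ThresholdGrid`, and the pipeline refuses an evaluation level that is not
  on the grid rather than silently rounding it.

Subjects missing an ROI (a real feature of histological cohorts, where
processing artifacts can make individual areas unidentifiable) are
excluded from that ROI's folds and group maps, and recorded explicitly in
the cohort's `missing` table. The pipeline shares one grid — the full
design's group size — across ROIs so that complete and incomplete ROIs are
compared at the same levels.

## Comparing two alignment conditions

Whether one template aligns the anatomy better than another is decided on
the fold-level Dice values, paired by left-out subject. The test is a
paired sign-flip permutation test: under the null hypothesis the sign of
each pair's difference is arbitrary, so each of `nPerm` permutations
(default 10,000) independently flips every difference with probability 1/2
(resampling the sign assignments with replacement), and the two-sided
Monte-Carlo p-value uses add-one smoothing, $(1 + \#\{|T^*| \ge
|T|\})/(1 + n_{perm})$, so it is never exactly zero. For up to 20 pairs an
exact mode enumerates all $2^n$ sign patterns instead. Testing is per-ROI
(with Bonferroni correction across ROIs) by default, matching how such
comparisons are reported region by region; pooling fold differences across
ROIs is possible by concatenation but mixes regions of different
difficulty.

## Correspondence between two parcellations

For a group-level region *m* of a second parcellation and each subject's
region *c* of the first, the directional overlap proportion is
$|m \cap c| / |m|$ — the fraction of *m* inside *c* — averaged across the
subjects possessing *c*. Chance is estimated by resampling: draw a
(subject, region) label uniformly with replacement from the full pool of
the hemisphere and record the overlap with *m*.

`chanceOverlapNull()` records the raw single-draw overlaps by default. For
significance testing, however, the observed statistic is a *mean over N
subjects*, and comparing a mean against a distribution of single draws is
incoherent: with K regions in the pool, a draw matches the tested region
with probability 1/K, so even a perfectly overlapping parcellation could
never beat "chance". `compareAtlases()` therefore resamples the null of
the same statistic — each iteration averages one draw per cohort subject
(`batchSize = N`) — and reports the null's mean as the chance level with
its 2.5–97.5 percentile interval, the one-sided exceedance p (add-one
smoothed), and the Bonferroni correction over the number of regions.
Hemispheres never mix: pools, means and corrections are all per-hemisphere.
When both hemispheres are analysed, a hemisphere main effect can be
assessed with `friedmanTest()` across the (m, c) cells; the implementation
uses within-block midranks and the standard tie correction (fully tied
blocks give a statistic of 0 and p = 1, a case the base-R implementation
leaves undefined, which is why the statistic is authored here).

## The maximum probability map

`buildMpm()` assigns every vertex whose best map value is positive (and at
least `minProb`, default 0) to the ROI with the highest probabilistic-map
value. Ties are broken toward the earliest region id in sorted order, so
the assignment is deterministic and invariant to the input order of the
maps; unassigned vertices carry the explicit `"background"` level.

## What the synthetic cohort emulates

The generator models exactly the statistical structure the analyses
consume and nothing else:

* **Geometry.** A unit icosphere (`makeIcosphere()`): 10·4^s + 2 vertices
  at subdivision s. ROI templates are geodesic caps — all vertices within a
  great-circle angle r of a center direction.
* **Inter-subject variability.** Each subject's ROI is the template cap
  with its center displaced by a tangent-plane Gaussian (SD in radians,
  renormalized to the sphere; a transparent small-angle approximation of a
  von Mises–Fisher perturbation) and its radius perturbed by a Gaussian,
  truncated to (0, π) by bounded resampling. Center jitter stands in for
  residual misalignment after curvature-driven surface registration;
  radius jitter for inter-individual size differences.
* **Two alignment conditions** differ *only* in center-jitter SD. This
  encodes the hypothesis under test — template choice changes alignment
  precision — without modelling registration itself.
* **Determinism.** Every label draws from an RNG substream keyed by
  (root seed, subject, roi, condition), so any output is a pure function
  of the `CohortConfig`, and adding a subject or condition never perturbs
  existing labels.

Defaults, chosen once as a realistic desk-scale design: subdivision 4
(2,562 vertices), 9 subjects, 4 caps of radius 0.25 rad, center jitter
0.06 rad for the precise-template condition versus 0.15 rad for the
generic one, radius jitter 0.03 rad, both hemispheres' machinery exercised
on the left. On a cortical sphere of ~70 mm radius these correspond to
roughly 4 mm vs 10 mm residual misalignment and ±2 mm size variability —
small-to-moderate versus clearly degraded alignment. The derived second
parcellation (`deriveSecondParcellation()`) rotates each template center
by a controllable angle and can cut the cap in two, giving a ground-truth
overlap structure (closed-form spherical cap and cap-intersection areas)
against which the comparison stage is tested.

What the generator does **not** emulate: cortical folding and
curvature-driven registration error structure (jitter is isotropic and
independent across subjects), between-ROI spatial correlation, ROI shapes
other than caps, and vertex densities of full-resolution templates
(~160k vertices). Passing tests therefore demonstrate the correctness and
calibration of the *estimators and tests*, not the anatomical realism of
any particular atlas.

## Numerical choices and degenerate inputs

* Vertex indices are 0-based everywhere at the API surface, matching the
  label-file convention; conversion to R's 1-based indexing happens only
  at matrix subsetting.
* Dice of two empty sets is an explicit error, never a silent 0; an empty
  thresholded group set against a non-empty ROI is a legitimate 0.
* Dice counts vertices unweighted, as the set-cardinality definition
  prescribes. Icosphere vertex density is not uniform, so count-based
  ratios carry a small resolution-independent bias relative to surface
  areas; `diceCoefficient(..., weights = vertexAreas(mesh))` provides the
  area-weighted variant (the test suite shows the weighted overlap of
  displaced caps matching the closed-form lens-to-cap area ratio to ~1%
  at subdivision 4, where raw counts sit several percent off).
* Percentile CIs use the empirical 2.5/97.5 quantiles of the resampled
  null (type-7 interpolation); CI bounds always lie within the null's
  range.
* Monte-Carlo p-values are add-one smoothed and compared with a 1e-12
  tolerance on the statistic so that exact ties (e.g. identical
  conditions) count as exceedances.
* Mesh connectivity is checked at construction; a disconnected mesh is a
  warning, not an error, since labels restricted to one component remain
  meaningful.

## Problem sizes

The test suite runs toy meshes (≤ 20 vertices, where leave-one-out results
are checked *exactly* against an independently coded brute-force
enumerator), subdivision-3 spheres (642 vertices) for cohort-level
behaviour, and subdivision-4/5 spheres (2,562 / 10,242 vertices) for
geometric convergence and parameter-recovery checks; permutation
calibration uses 500 null simulations of 9 pairs at 2,000 permutations.
These sizes keep the full suite under half a minute while leaving every
statistical property measurable.

## Known limitations

* The jitter SDs are plausible but not calibrated against any measured
  inter-subject variability; predictability curves are qualitatively
  shaped like real ones (rising from the unthresholded end, falling toward
  full consensus) but their absolute Dice values are design choices.
* The chance-null construction assumes the pool of (subject, region)
  labels is exchangeable within a hemisphere; regions of very different
  sizes make the null wide rather than invalid.
* Only triangulated single-component meshes, FreeSurfer ASCII
  label/surface files and OFF meshes are supported; binary surface
  formats and volume-to-surface projection are out of scope — labels are
  expected to arrive already on the common surface.
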