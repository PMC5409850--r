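Package: surfAtlas
Title: Probabilistic Surface Atlases and Cross-Validated Parcellation Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating probabilistic region-of-interest
    atlases on triangulated cortical surface meshes. Constructs per-vertex
    probabilistic maps and maximum probability maps from multi-subject surface
    labels, scores atlas predictability with leave-one-out cross-validated Dice
    coefficients across a threshold sweep, compares alignment conditions by
    paired sign-flip permutation testing, and quantifies correspondence between
    two parcellations against resampled chance levels with Bonferroni
    correction. Includes a deterministic synthetic-cohort generator (icosphere
    meshes, geodesic-cap ROIs with controllable inter-subject jitter) so the
    full pipeline is exercisable without imaging data, and readers/writers for
    FreeSurfer ASCII label and surface files and OFF meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
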