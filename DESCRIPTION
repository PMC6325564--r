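Package: wormswim
Title: Biomechanical Profiling of Swimming Nematodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the swimming gait of single C. elegans from bright-field
    movies or centerline time series. Extracts the body centerline frame by
    frame, builds curvature kymographs, and estimates beating frequency, wave
    speed, swimming speed, and head-normalized curvature profiles. Propulsive
    force and mechanical power are estimated with resistive force theory using
    slender-body drag coefficients. Includes a synthetic movie generator with
    full ground truth for validation, movie-level quality control, and
    group-comparison reporting (Kruskal-Wallis with Dunn post hoc tests,
    position-wise t tests with Holm-Sidak correction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    png,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
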