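Package: graphophon
Title: Grapho-Phonemic Systematicity: Glyph Shape Metrics, Stimulus Design,
    and Forced-Choice Survey Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying grapho-phonemic systematicity, the
    correlation between pairwise distances of letter shapes and pairwise
    distances of the sounds they encode. Provides shape-distance metrics on
    binarized glyph rasters (ink-pixel count, perimetric complexity,
    Hausdorff distance), phonological feature distances (Euclidean, cosine,
    Jaccard, feature edit), an accept-if-better stochastic search that
    assembles forced-choice stimulus materials maximizing systematicity
    under a target metric with cross-metric exclusivity validation, and
    analysis of forced-choice survey responses including a Monte Carlo
    permutation null for type-preference proportions. A synthetic-data
    module generates glyph libraries with plantable metric structure,
    binary phoneme feature spaces, and simulated multinomial participants,
    so the whole pipeline runs without external materials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
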