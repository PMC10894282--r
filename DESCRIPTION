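Package: semgrsa
Title: Consistency and Distinguishability Analysis of Multi-Channel Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to assess whether attempted hand movements produce
    consistent and distinguishable patterns of multi-channel surface
    electromyography (sEMG). Implements per-repetition root-mean-square
    (RMS) and mean-frequency (MNF) feature extraction with onset/recession
    trimming and per-channel normalization, within-movement consistency
    scoring via Kendall's coefficient of concordance, split-data
    representational dissimilarity matrices with an exemplar
    discriminability index (EDI) condition-label randomization test,
    across-limb consistency (exact Wilcoxon signed-rank) and RDM
    relatedness (Kendall tau-a label randomization) tests, and nonmetric
    multidimensional scaling under the squared-stress criterion. Includes
    a seeded synthetic two-limb sEMG session generator with controllable
    movement distinguishability, repetition consistency, and affected-limb
    degradation, emulating a mirrored bilateral recording protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
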