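Package: idiorsa
Title: Observer-Specific Representational Similarity Analysis of Perceived
    Visual Similarity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how multivoxel fMRI activity patterns track
    an observer's own fine-grained perceived similarity structure among
    object exemplars. Builds behaviour-based representational dissimilarity
    matrices (RDMs) from circular-arena arrangement tasks, stratifies pairs
    into low/medium/high perceived-similarity levels, computes region-of-
    interest brain RDMs (1 - Pearson r, percentile-converted), correlates
    brain and behaviour within and between observers, and quantifies
    observer specificity with an i-index tested against a subject-label
    randomization null. Includes leave-one-run-out linear decoding per
    similarity level, a compact hierarchical Gabor (HMAX-style) C2 feature
    model for model RDMs, a category-exemplar 1-back scoring module, and a
    synthetic-study generator (arrangements, trial sequences, behavioural
    logs, voxel patterns) with controllable shared and observer-specific
    structure so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse
Config/testthat/edition: 3
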