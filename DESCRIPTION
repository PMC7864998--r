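Package: trex
Title: Traceable Relevance Explainability for Multi-Grader Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc explainability for semantic segmentation models trained
    on ambiguous multi-grader ground truth. Quantifies agreement between
    graders and a model with pixel-wise Hamming distances (overall and per
    anatomical compartment), visualizes grading ensembles with metric
    multidimensional scaling and per-scan "neural recording" heatmaps, and
    tests inter-grader versus grader-model distances with unpaired
    Monte-Carlo permutation tests. Includes a synthetic multi-grader
    generator of layered retinal-OCT-like scenes with controllable grader
    bias and smooth boundary noise for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
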