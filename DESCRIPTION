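Package: chondrocolumn
Title: Quantification of Clonal Architecture and Cell Rearrangement in
    Growth-Plate Cartilage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how chondrocyte clones organize into
    proximodistally oriented columns in growth-plate cartilage. Implements
    cell and clone orientation statistics with threshold classification
    (minor-axis angle Phi, topmost-cell angle theta, polygon major-axis
    column orientation), sister-cell pivot kinematics (pivot angle omega
    trajectories, unwrapping, normalization and outcome classification),
    polyline-kymograph contact detection, junctional-intensity ratios and
    time courses, Pearson colocalization, and the supporting statistical
    battery (two-sample Watson's U2 permutation test, Wilcoxon rank-sum,
    Kolmogorov-Smirnov normality screen). A seeded synthetic-tissue
    generator produces cell tables, pivot tracks and rendered image frames
    with known ground truth, including presets for wild-type and
    planar-cell-polarity / N-cadherin perturbation phenotypes, so every
    estimator can be validated against the structure it assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
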