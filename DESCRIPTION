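Package: simmapr
Title: Similarity Maps for Molecular Fingerprints and Activity Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Visualizes the per-atom contributions to molecular
    fingerprint similarity and to the predicted activity probability of a
    classifier. For every atom of a test molecule, the fingerprint bits
    the atom participates in are removed and the similarity to a
    reference compound (or a model's probability of activity) is
    recomputed; the resulting difference is the atom's weight, and the
    normalized weights are rendered as a Gaussian contour overlay on the
    2D structure. Supports atom-pair and Morgan/ECFP-style circular
    fingerprints (bit and count vectors, element- or feature-based atom
    typing), Dice and Tanimoto similarity, and balanced random forest and
    Bernoulli naive Bayes activity models. Fingerprint hashing, molecule
    parsing and 2D layout are delegated to the RDKit toolkit through a
    bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    png,
    rpart,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with the RDKit toolkit on PATH
Config/testthat/edition: 3
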