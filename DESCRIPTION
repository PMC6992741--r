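Package: mirmeta
Title: Meta-Prediction of miRNA-Target Interactions from Heterogeneous
    Predictor Outputs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates the outputs of established miRNA-target prediction
    tools into a single support-vector-machine meta-classifier. Provides a
    fixed-order feature encoding for heterogeneous tool outputs (scores,
    p-values, binding positions, seed types, conservation flags, duplex
    energies), binding-energy-stratified training-set construction with
    permutation negatives and positive/negative ratio control, minimum
    redundancy-maximum relevance (MIQ) feature ranking with incremental
    feature selection, and a full confusion-matrix evaluation panel
    including the CHL index, the normalized harmonic mean of accuracy,
    normalized Matthews correlation and the F1 score. A synthetic-data
    generator emulates ground-truth interactions, two-component binding
    energy distributions, sequences and per-tool outputs with controllable
    operating characteristics so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
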