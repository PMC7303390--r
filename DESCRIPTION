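Package: connfp
Title: Connectome Fingerprinting and Brain-Behavior Predictive Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of functional and structural brain connectivity
    matrices (Pearson/Fisher-z functional connectivity; streamline-count,
    mean-length and quantitative-anisotropy structural connectivity),
    cross-session subject identification from connectome fingerprints with
    permutation-based significance, and connectome-based predictive
    modeling (CPM) of behavioral traits under leave-one-out
    cross-validation with Benjamini-Hochberg false discovery rate control.
    Includes a synthetic cohort generator with planted subject fingerprints
    and edge-behavior effects so that every stage of the pipeline can be
    validated against known ground truth without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
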