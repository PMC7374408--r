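Package: gaitbelief
Title: Dempster-Shafer Belief Classification of Gait Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective assessment of lower-limb gait function using
    principal component analysis of time-normalised gait waveforms and a
    Dempster-Shafer evidence-theory classifier (the Cardiff Classifier).
    Each retained principal-component score is mapped through a sigmoid
    transfer function to a body of evidence over osteoarthritic (OA) and
    non-pathological (NP) gait, and the evidence is combined by
    Dempster's rule into belief values B(OA), B(NP) and uncertainty U.
    Includes split-half feature ranking, leave-one-out cross-validation,
    projection of post-operative visits onto trained principal components,
    simplex (barycentric) visualisation of beliefs, pre/post change
    summaries with effect sizes, correlation of belief change against
    patient-reported outcome measures, and a synthetic cohort generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
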