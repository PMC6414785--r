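Package: mergenet
Title: Cross-Platform Transcriptome Integration and Co-Expression Network Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates probe-level expression matrices from different microarray
    platforms into one gene-level study (max-signal probe collapse, gene-universe
    intersection, optional renormalization, variance filtering), removes platform
    batch effects by parametric empirical-Bayes location/scale adjustment and audits
    the correction with principal variance component analysis, and compares weighted
    gene co-expression networks between conditions: soft-threshold selection,
    topological overlap, module detection with eigengene merging, intramodular
    connectivity and hub analysis, template matching against a regulator gene, and
    TSS-proximity peak enrichment of modules. Ships a two-platform synthetic-data
    generator with planted modules, hub, batch effects and peak enrichment so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    limma,
    ape,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
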