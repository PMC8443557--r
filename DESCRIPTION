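Package: synaptodev
Title: Developmental Synaptic Phenotype and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cortical synaptic development across
    early postnatal ages in exposure-model primates: detection of miniature
    excitatory and inhibitory synaptic currents from voltage-clamp traces
    with amplitude and area thresholds in baseline-noise units,
    excitation/inhibition ratios and long-term depression magnitude,
    intensity-based dendritic spine volumetry with optical-density
    calibration, call-repertoire Shannon entropy, per-age differential
    expression (Welch t-test with Benjamini-Hochberg adjustment),
    k-means clustering of log fold-change trajectories with AIC model
    selection, a phenotype-to-gene-cluster trajectory distance, and
    cross-species log fold-change concordance tests. Seeded synthetic-data
    generators provide planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
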