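Package: decaykit
Title: Spike-In Normalized mRNA Half-Life Estimation and CCR4-NOT Decay Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of mRNA turnover around the CCR4-NOT
    deadenylase complex. Estimates transcriptome-wide mRNA half-lives from
    actinomycin-D transcription shut-off RNA-seq time courses using ERCC
    spike-in normalization and per-gene log-linear first-order decay fits
    with reliability filtering; fits targeted qPCR/northern/western decay
    series; quantifies in vitro deadenylation rates from gel lane
    densitometry (marker calibration, most-abundant-tail extraction, linear
    rate estimation, fold inhibition); compares half-life tables between
    conditions with paired Wilcoxon signed-rank tests, half-life binning and
    gene-set subgroup analysis; and filters AP-MS interactome tables
    (presence filtering, bait-exclusive enrichment, SILAC one-sample t
    tests, gradient profile normalization). A synthetic-data module
    generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
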