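Package: rppaHet
Title: Intratumoral Heterogeneity and Sampling Bias Analysis for Reverse
    Phase Protein Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies intratumoral versus inter-patient heterogeneity of
    cell-signaling protein expression measured by reverse phase protein
    arrays (RPPA). Provides a synthetic-data generator with a hierarchical
    lognormal variance structure and an optional spot-level dilution-series
    layer, serial-dilution quantification with total-protein normalization,
    coefficient-of-variation heterogeneity statistics with Friedman and
    Mann-Whitney tests, Spearman-distance average-linkage clustering with
    co-clustering scores, and a tumor sampling-bias experiment that compares
    differential expression calls from per-tumor mean profiles against
    repeated randomly selected single samples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
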