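Package: gcnbench
Title: Benchmarking 16S rRNA Gene Copy Number Normalization Against Mock
    Communities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates whether dividing genus-level 16S rRNA amplicon counts
    by gene copy numbers (GCN) brings community profiles closer to known mock
    community compositions. Implements GCN correction with a configurable
    default copy number for genera without a database entry, residual
    sum-of-squares (RSS) comparison of observed and expected relative
    abundance profiles, Shannon diversity, genus richness and
    misidentification metrics, a Shannon-ratio exclusion rule for unreliable
    communities, cohort-level aggregation, a packaged reference benchmark of
    eleven mockrobiota communities, and a seeded multinomial mock-community
    simulator with copy-number bias, unidentified reads and spurious genera.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software, Normalization
RoxygenNote: 7.3.3
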