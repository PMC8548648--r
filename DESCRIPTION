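Package: mybkit
Title: Characterization of MYB Transcription-Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing plant MYB transcription-factor gene
    families from genome and transcriptome data: detection and classification
    of MYB DNA-binding-domain repeats (1R/R2R3/3R/4R), ProtParam-style protein
    descriptors, duplicate-pair discovery with tandem/segmental classification,
    Nei-Gojobori (NG86) Ka/Ks estimation with molecular-clock dating, QTL
    co-localization, collinearity (syntenic segment) chaining, microsatellite
    and cis-regulatory-element scanning of promoters, TMM normalization with
    negative-binomial differential expression, Pearson co-expression
    clustering, and qPCR 2^-ddCt quantification. Includes a synthetic-data
    generator that plants known repeats, duplications, rearrangements, SSRs
    and expression fold changes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    MASS,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
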