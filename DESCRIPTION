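Package: geoffset
Title: Landscape Genomics of Climate Maladaptation: Association Scans,
    RONA and Genomic Offsets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the climate-change vulnerability of
    structured plant populations from genotype and climate data. Implements
    genotype-environment association scanning (a deterministic latent-factor
    mixed-model scan with genomic-inflation calibration, and redundancy-
    analysis loading outliers), risk of non-adaptedness (RONA) from
    allele-frequency regressions, a gradient-forest-style turnover model
    with local, forward (dispersal-capped) and reverse genomic offsets,
    isolation-by-distance and isolation-by-environment Mantel machinery,
    Weir-Cockerham F_ST, nucleotide diversity, and derived-allele
    genetic-load proxies, together with a synthetic-landscape generator
    that produces VCF and TSV inputs with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    rpart,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
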