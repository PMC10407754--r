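Package: matequant
Title: Comparative Quantitative Proteomics of Mating-Transferred Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multiplexed isobaric-label (TMT)
    quantitative proteomics experiments that identify male ejaculate
    proteins transferred during mating by contrasting mated and virgin
    female reproductive tract samples across related species. Provides
    peptide-to-protein aggregation with unique-peptide filtering,
    trimmed-mean-of-M-values normalization, moderated two-group linear
    models with empirical Bayes variance shrinkage, orthogroup-keyed
    cross-species merging, ejaculate/female-reproductive-tract
    classification, cross-species divergence contrasts, k-means abundance
    clustering, gene-family resampling tests with hypergeometric
    references, evolutionary-rate (dN/dS) group comparisons, GO term
    enrichment, mRNA-protein correlation, and principal component
    analysis. A synthetic-data generator emulates the experimental design
    and provides planted ground truth for calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    withr
Config/testthat/edition: 3
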