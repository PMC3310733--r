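Package: mirsel
Title: Detecting Positive Selection on miRNA Target-Site Polymorphisms
Version: 0.1.0
Authors@R: person("mirsel", "developers", role = c("aut", "cre"),
    email = "mirsel@example.org")
Description: An end-to-end, simulation-backed pipeline for detecting
    positively selected microRNA regulatory interactions at single
    nucleotide polymorphisms. Provides allele-aware seed-site calling in
    15-nt polymorphic 3'UTR windows, Weir-Cockerham F_ST with bin-wise
    enrichment against a bootstrap null and a hypergeometric tail test,
    within-population sweep statistics (Fay-Wu's H, EHH, iHS, a composite
    likelihood ratio scan against a background site frequency spectrum),
    linkage-disequilibrium hitchhiking filters, and latitude-allele
    frequency cline testing, together with a ground-truth-annotated
    synthetic data generator (Balding-Nichols differentiation, LD,
    injected sweeps, planted seed sites and clines).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
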