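Package: besomatic
Title: Somatic Exomic Mutation Landscape Comparison for Barrett's Esophagus Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares somatic exomic mutation landscapes between exposure
    groups (NSAID users versus non-users) in Barrett's esophagus: trinucleotide
    mutation spectra on the 96 pyrimidine-referenced channels, de novo
    mutational-signature extraction by stability-selected non-negative matrix
    factorization and per-sample refitting against a reference signature set,
    variant-allele-frequency based clonality in diploid regions, pathway
    functional-mutation burden and a gene-count-normalized Shannon diversity
    index, and classification of somatic chromosome alterations from exome
    log-ratio/B-allele-frequency tracks into six classes. Includes a synthetic
    matched-cohort generator with known ground truth so every stage is testable
    without access to patient sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    fgsea,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
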