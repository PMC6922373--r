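Package: sangerscreen
Title: Indel Decomposition of Sanger Chromatograms and Clonality Triage
    for Gene-Edited Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies CRISPR/ZFN editing outcomes from bulk Sanger
    chromatograms by non-negative least-squares decomposition of the mixed
    trace onto indel-shifted wild-type components, yielding an indel-allele
    frequency spectrum with per-component significance and fit quality.
    Screens clone wells for clonality and genotype (retaining homozygous and
    compound-heterozygous knockouts, discarding wild-type-containing and
    non-clonal wells), aggregates and compares editing-modality indel
    footprints, and converts T7 endonuclease densitometry to indel
    fractions. Ships a synthetic chromatogram and amplicon-read generator
    plus a read-count oracle so every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    pracma,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
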