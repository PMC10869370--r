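Package: lohsig
Title: Tumor Loss-of-Heterozygosity Detection, Mutational Signature
    Refitting and Family Segregation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes tumors from paired germline/tumor variant calls:
    consensus somatic-variant filtering, loss-of-heterozygosity (LOH)
    detection from allele-fraction shifts at heterozygous germline sites with
    tumor-purity correction and region aggregation, SBS-96 and ID-83 mutation
    catalogue construction, simplex-constrained refitting of COSMIC-style
    reference signatures with a homologous recombination deficiency (HRD)
    classification rule, and pedigree carrier/segregation summaries including
    WHO-2019 serrated polyposis syndrome criteria. Ships a seeded synthetic
    data generator so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    quadprog,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
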