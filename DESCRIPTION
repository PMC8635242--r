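Package: salthap
Title: Haplotype Classification and Functional Marker Genotyping for the
    Soybean Salt-Tolerance Locus GmSALT3
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for classifying haplotypes of the soybean salt-tolerance
    gene GmSALT3 from variant matrices, for in-silico PCR and CAPS
    (cleaved amplified polymorphic sequence) marker genotyping, for
    summarising haplotype frequencies across eco-regions and breeding
    decades, for scoring genotype-phenotype concordance against chlorosis
    phenotypes, and for tracing alleles through cultivar pedigrees. Ships a
    deterministic synthetic-locus generator so the whole pipeline is testable
    without access to restricted resequencing panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
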