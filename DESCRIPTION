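Package: blocnet
Title: Allele Correlation Networks and Haplotype Bloc Discovery for
    Case-Control SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds allele-specific correlation networks from unphased
    diploid SNP genotypes using a four-valued allele co-occurrence
    coefficient, extracts multi-SNP haplotype blocs as connected
    components after truncating the network to a target mean node
    degree, screens blocs by carrier odds ratio through a
    Discovery/Validation/Replication cascade, and profiles bloc-carrier
    frequencies across populations with partial SNP overlap. Includes a
    planted-bloc genotype simulator so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
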