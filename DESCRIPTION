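Package: mhctyper
Title: Amplicon-Based MHC Genotyping and Population-Genetic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for diploid genotyping of highly
    polymorphic loci (such as MHC class II genes) from merged amplicon
    sequencing reads, together with the population-genetic analyses that
    typically follow. Includes ratio-threshold allele calling with PCR-chimera
    detection and pedigree validation, post-merge read filters, a
    minimum-allele-frequency filter, sequence diversity and neutrality
    statistics (Tajima's D, Fu and Li's D* and F*, Fu's Fs), exact
    Hardy-Weinberg and genotypic linkage-disequilibrium tests, Nei-Gojobori
    synonymous/nonsynonymous substitution analysis, and a synthetic-data
    generator that emulates amplicon read sets with realistic error structure
    (chimeras, allelic dropout, singleton noise, short reads) plus truth
    tables for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
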