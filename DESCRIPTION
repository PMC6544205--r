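Package: ukbkit
Title: Manage and Query UK Biobank Phenotype Filesets and Genetic Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Turns a UK-Biobank-style fileset (tab-delimited data table,
    categorical-coding script, and HTML data dictionary) into a single
    analysis-ready data frame with descriptive snake_case column names and
    coding labels applied. Provides demographic context summaries of a
    subset against a reference group, ICD-9/ICD-10 diagnosis queries
    (code meaning, keyword search, chapter lookup, prevalence, and
    frequency stratified by a reference variable), and genetic-metadata
    utilities: sample-QC column naming, KING kinship degree counts,
    phenotype-aware relatedness pruning to a maximal unrelated set, and
    readers/writers for PLINK and BGENIE phenotype, covariate and
    exclusion files. A bundled synthetic-fileset generator makes every
    component testable without access to real UK Biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
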