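Package: pofokit
Title: Parent-of-Origin Inference and Parent-of-Origin Effect Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the parent of origin (PofO) of haplotypes in cohorts
    without genotyped parents, by clustering distant relatives into surrogate
    parent groups, interchromosomal phasing from identity-by-descent (IBD)
    sharing, probabilistic maternal/paternal assignment from X-chromosome
    segment lengths and mitochondrial minor-variant sharing, and sex-specific
    crossover scoring in sibling pairs. Provides PofO-weighted dosage
    encodings and downstream parent-of-origin effect (POE) association scans
    (additive, paternal, maternal and differential), POE classification,
    multiple-testing thresholds and replication statistics. Includes a
    pedigree and cohort simulator with full ground truth so every inference
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
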