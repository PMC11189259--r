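Package: ykmer
Title: Assembly-Free Discovery of Y-Specific Repetitive CRISPR Target Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An assembly-free workflow for finding Y-chromosome-specific,
    highly repetitive CRISPR/Cas9 target sites from male and female
    whole-genome sequencing. Long reads are assigned to Y, autosomal or X
    bins by the Chromosome Quotient (the normalized female-to-male
    short-read coverage ratio); 25-mers from male short reads are profiled
    for sex specificity, filtered against off-targets in the autosomal and
    X bins, and reduced to SpCas9 guide candidates by PAM scanning.
    Includes an anchored-consensus designer for 44-bp FISH probes around a
    chosen target, scoring rules for hatching rate and progeny sex ratio,
    sperm sex-chromosome genotype summaries with exact rank-sum organ
    comparisons, and a synthetic genome and read simulator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
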