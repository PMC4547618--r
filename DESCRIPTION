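Package: ampliko
Title: Predict KEGG Ortholog Functional Profiles of Microbial Communities
    from 16S rRNA Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the relative KEGG Ortholog (KO) gene-content profile of a
    microbial community from a 16S rRNA amplicon profile labelled with marker
    reference sequences. OTU abundances are mapped to functionally annotated
    genomes through a precomputed sparse association matrix built by
    nearest-neighbour global-alignment identity at a minimum similarity
    threshold, corrected for per-genome 16S rRNA gene copy number, and combined
    linearly with per-genome relative KO profiles. Includes readers for QIIME
    classic OTU tables and SILVAngs-style assignment exports, a rank-correlation
    and exact sign-test evaluation protocol for paired amplicon/shotgun
    datasets, and a deterministic synthetic reference and community generator
    with known ground truth for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
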