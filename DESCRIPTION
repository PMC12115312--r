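Package: oryzakin
Title: Genus-Wide Analysis of Calcium-Dependent Protein Kinase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for genus-wide analysis of calcium-dependent
    protein kinase (CPK) gene families and their relatives (CRK, PEPRK, PPCK,
    CCaMK) across a set of related plant genomes. Detects protein kinase
    domains, EF-hand motifs and calcium-binding sites with a built-in
    PROSITE-style pattern engine; assigns family labels by seeded local
    alignment; clusters domain architectures into representative types and
    variants; classifies duplicate gene pairs into whole-genome, tandem,
    proximal, transposed and dispersed modes over gene orders with
    dynamic-programming collinear-block chaining; types the domain
    consequences of alternative splicing into a nine-category taxonomy; calls
    homoeolog expression bias in allotetraploids from FPKM matrices; and
    summarises tissue expression atlases. A seeded synthetic-data generator
    emulates the multi-genome study design with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    Biostrings,
    rtracklayer,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
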