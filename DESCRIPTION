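Package: rpksm
Title: Gene-Centric Functional Profiling of Stool Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-centric analysis of gut-microbiome shotgun metagenomes
    around metabolic-disease phenotypes. Builds reference-anchored
    metabolic gene families from annotated pangenome FASTA, quantifies
    family abundance in stool metagenomes with the RPKSM statistic
    (reads per kilobase per family size per million reads) from tabular
    protein-alignment files, post-processes taxonomic relative-abundance
    profiles, tests two-group differences with Mann-Whitney tests and
    Benjamini-Hochberg adjustment under cross-cohort consistency rules,
    and classifies gene prevalence (core / accessory / highly accessory)
    across genome and plasmid collections from profile-scan tables. A
    synthetic-data module generates every input format with known ground
    truth so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
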