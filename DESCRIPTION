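Package: bsascan
Title: Bulked-Segregant Association Scans for Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bulked-segregant analysis (BSA-seq) of pooled whole-genome
    sequencing from an F1 cross: quality filtering of multi-sample variant
    calls from allele depths, Euclidean-distance (ED) and delta-SNP-index
    association statistics, sliding-window genome scans with empirical
    thresholds (median + 3 SD, quantile, or null simulation), candidate
    region calling, mutant-versus-original genotype-pattern intersection,
    and coding-consequence analysis of candidate InDels. Includes a
    seeded simulator of pooled allele depths for a dominant-mutant F1
    cross (het x hom parents, phenotype-selected pools, Haldane linkage)
    that emits VCF, GFF3, FASTA and a ground-truth table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
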