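Package: pomesweep
Title: Selective-Sweep Scanning and Insertion-Allele Surveys for Pome Fruit Domestication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic toolkit for studying how bitterness was lost
    during apple and pear domestication. Computes windowed nucleotide diversity
    and the wild/cultivated theta-pi ratio from diploid VCF genotypes, calls
    top-quantile selective-sweep intervals and intersects them with gene
    annotations, characterises diagnostic insertion variants (length,
    target-site duplication, coding consequence) and genotypes accessions by
    in-silico PCR, tabulates per-taxon insertion-allele frequencies with
    Hudson, Weir-Cockerham and Nei Fst estimators, classifies candidate MYB
    proteins into R2R3 subgroups by neighbor-joining with bootstrap support,
    and tests genotype-phenotype association with one-way ANOVA and Fisher's
    LSD letter groupings. A seeded forward Wright-Fisher simulator generates
    complete synthetic study fixtures (reference FASTA, VCF, GFF3, panel and
    phenotype tables) with a domestication bottleneck and a positively
    selected insertion allele.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
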