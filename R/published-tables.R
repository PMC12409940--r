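#' Published insertion-genotype survey counts
#'
#' Per-taxon genotype-class counts from the published surveys of the
#' diagnostic insertion alleles: 459 *Malus* accessions genotyped at the
#' 411-bp coding-region insertion of the MYB tannin regulator, and 325
#' *Pyrus* accessions genotyped at the 57-bp promoter insertion of *MYBPA1*.
#' Columns: `group` (species), `pool` (wild/cultivated, or origin for pear),
#' `n_hom_no_ins`, `n_het`, `n_hom_ins`. Feed these into
#' [allele_frequency_table()] to reproduce the printed frequency columns
#' (e.g. 99.18% for *M. domestica*, 85.29% overall; 90.00% across *Pyrus*).
#'
#' @return A tibble of genotype-class counts.
#' @export
malus_mybtt_survey <- function() {
  read_survey_tsv("malus_mybtt_genotypes.tsv")
}

#' @rdname malus_mybtt_survey
#' @export
pyrus_mybpa1_survey <- function() {
  read_survey_tsv("pyrus_mybpa1_genotypes.tsv")
}

read_survey_tsv <- function(fname) {
  path <- system.file("extdata", fname, package = "pomesweep", mustWork = TRUE)
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE))
}
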