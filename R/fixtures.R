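#' Synthetic diagnostic-assay fixtures
#'
#' Constructs a fully synthetic primer pair plus the two allele templates of
#' a presence/absence indel assay: the no-insertion allele yields the short
#' product, the insertion-bearing allele the long one, and the two products
#' differ by exactly the insertion length. The insertion is planted with a
#' target-site duplication so [detect_insertion()] recovers it. Sequences are
#' generated deterministically from `seed`; these are synthetic stand-ins for
#' locus sequences that are not redistributed here, built to the published
#' amplicon geometry.
#'
#' `diagnostic_assay_fixture()` provides the two preset geometries used
#' throughout this package: `"apple"` (244-bp product without the insertion,
#' 655 bp with the 411-bp coding-region insertion) and `"pear"` (550 bp
#' without, 607 bp with the 57-bp promoter insertion).
#'
#' @param species `"apple"` or `"pear"`.
#' @param name Assay label.
#' @param insertion_length Insertion length, bp.
#' @param no_insertion_amplicon Product size on the insertion-free allele, bp.
#' @param inserted_seq Optional explicit inserted sequence (its tail is used
#'   as the TSD when it matches the planted site); generated when `NULL`.
#' @param location_class `"CDS"` or `"promoter"`.
#' @param tsd Target-site duplication to plant, or `NULL` for none.
#' @param primer_length Primer length, default 22.
#' @param flank Template flank outside the amplicon, default 30 bp.
#' @param seed Seed for the deterministic sequence draw.
#' @return A list of class `indel_fixture`: `assay` (an [indel_assay()]),
#'   `templates` (named character vector `no_insertion`, `insertion`),
#'   `insertion_point` (1-based, on the no-insertion template).
#' @export
diagnostic_assay_fixture <- function(species = c("apple", "pear")) {
  species <- match.arg(species)
  switch(species,
    apple = synthetic_indel_fixture(
      name = "MdMYBTT_411bp", insertion_length = 411L,
      no_insertion_amplicon = 244L, location_class = "CDS",
      tsd = "TTCCTAGT", seed = 101L
    ),
    pear = synthetic_indel_fixture(
      name = "MYBPA1_57bp", insertion_length = 57L,
      no_insertion_amplicon = 550L, location_class = "promoter",
      tsd = NULL, seed = 202L
    )
  )
}

#' @rdname diagnostic_assay_fixture
#' @export
synthetic_indel_fixture <- function(name, insertion_length,
                                    no_insertion_amplicon,
                                    inserted_seq = NULL,
                                    location_class = "CDS",
                                    tsd = "TTCCTAGT",
                                    primer_length = 22L, flank = 30L,
                                    seed = 101L) {
  stopifnot(no_insertion_amplicon > 2 * primer_length + 10)
  bases <- c("A", "C", "G", "T")
  tsd_len <- if (is.null(tsd)) 0L else nchar(tsd)

  build <- function(try_seed) {
    withr::with_seed(try_seed, {
      tmpl <- bases[sample.int(4, no_insertion_amplicon + 2 * flank,
                               replace = TRUE)]
      # insertion point: between the primer sites, clear of both
      ip <- flank + no_insertion_amplicon - primer_length - 5L
      if (tsd_len > 0) {
        tmpl[(ip - tsd_len + 1):ip] <- strsplit(tsd, "")[[1]]
      }
      ins <- inserted_seq
      if (is.null(ins)) {
        body <- bases[sample.int(4, insertion_length - tsd_len, replace = TRUE)]
        ins <- paste(c(body, if (tsd_len > 0) strsplit(tsd, "")[[1]]),
                     collapse = "")
      }
      no_ins <- paste(tmpl, collapse = "")
      with_ins <- paste0(substr(no_ins, 1, ip), ins,
                         substr(no_ins, ip + 1, nchar(no_ins)))
      fwd <- substr(no_ins, flank + 1L, flank + primer_length)
      rev_site <- substr(no_ins, flank + no_insertion_amplicon - primer_length + 1L,
                         flank + no_insertion_amplicon)
      rev <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rev_site)))
      list(no_ins = no_ins, with_ins = with_ins, fwd = fwd, rev = rev, ip = ip)
    })
  }

  assay_ok <- function(b, assay) {
    ok <- function(tmpl, expected) {
      tryCatch(insilico_pcr(tmpl, assay) == expected, error = function(e) FALSE)
    }
    ok(b$no_ins, assay$expected_amplicons[["no_insertion"]]) &&
      ok(b$with_ins, assay$expected_amplicons[["insertion"]])
  }

  for (try_seed in seed + 0:24) {
    b <- build(try_seed)
    assay <- indel_assay(name, b$fwd, b$rev, insertion_length, location_class,
                         no_insertion_amplicon)
    if (assay_ok(b, assay)) {
      return(structure(
        list(assay = assay,
             templates = c(no_insertion = b$no_ins, insertion = b$with_ins),
             insertion_point = b$ip),
        class = "indel_fixture"
      ))
    }
  }
  abort("could not construct a unique-primer fixture (unexpected)")
}

#' Synthetic MYB protein alignment for subgroup classification
#'
#' Simulates an aligned protein set with two reference subgroups (SG5 and
#' SG47, each descending from its own ancestor) plus query sequences derived
#' by point mutation from one subgroup's ancestor — the structure used to
#' exercise neighbor-joining subgroup assignment without redistributing any
#' real MYB sequences.
#'
#' @param n_refs_per_group Reference sequences per subgroup, default 3.
#' @param length Alignment length in residues, default 120.
#' @param group_divergence Fraction of positions separating the two subgroup
#'   ancestors, default 0.30.
#' @param within_divergence Per-sequence mutation fraction inside a subgroup,
#'   default 0.05.
#' @param seed RNG seed.
#' @return List: `alignment` (named character vector), `reference_labels`
#'   (named vector, ids -> subgroup), `truth` (tibble `query`, `subgroup`).
#' @export
simulate_myb_alignment <- function(n_refs_per_group = 3, length = 120,
                                   group_divergence = 0.30,
                                   within_divergence = 0.05, seed = 1) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(as.integer(seed), {
    mutate_at <- function(x, frac) {
      n <- max(1L, round(frac * length))
      pos <- sample.int(length, n)
      x[pos] <- vapply(x[pos], function(old) sample(setdiff(aa, old), 1), "")
      x
    }
    root <- aa[sample.int(20, length, replace = TRUE)]
    anc <- list(SG5 = mutate_at(root, group_divergence / 2),
                SG47 = mutate_at(root, group_divergence / 2))
    seqs <- list()
    labels <- character(0)
    for (grp in names(anc)) {
      for (i in seq_len(n_refs_per_group)) {
        id <- sprintf("%s_ref%d", grp, i)
        seqs[[id]] <- paste(mutate_at(anc[[grp]], within_divergence),
                            collapse = "")
        labels[id] <- grp
      }
    }
    truth <- tibble(query = c("query_A", "query_B"),
                    subgroup = c("SG5", "SG47"))
    seqs[["query_A"]] <- paste(mutate_at(anc$SG5, within_divergence), collapse = "")
    seqs[["query_B"]] <- paste(mutate_at(anc$SG47, within_divergence), collapse = "")
    list(alignment = unlist(seqs), reference_labels = labels, truth = truth)
  })
}
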