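#' Describe an insertion difference between two allele sequences
#'
#' Decomposes a pair of allele sequences that differ by one contiguous
#' insertion, returning the insertion point on the reference allele, the
#' inserted length, and the target-site duplication (TSD): the longest
#' `k <= tsd_max` such that the k bases ending at the insertion point equal
#' the k bases at the 3' end of the inserted block. A TSD is the footprint a
#' transposable element leaves at its integration site.
#'
#' The decomposition uses longest-common-prefix / longest-common-suffix; the
#' insertion is placed at the rightmost compatible point (after the last
#' common prefix base). Sequences differing by substitutions or by more than
#' one indel raise an unsupported-difference error.
#'
#' @param ref_allele_seq,ins_allele_seq DNA strings (character scalars);
#'   `ins_allele_seq` must be `ref_allele_seq` with one contiguous insertion.
#' @param tsd_max Maximum TSD length scanned, default 20.
#' @return A list of class `insertion_description`: `position` (1-based, the
#'   insertion falls after this reference base), `length`, `inserted_seq`,
#'   `tsd` (string or `NA`), `tsd_length`.
#' @export
detect_insertion <- function(ref_allele_seq, ins_allele_seq, tsd_max = 20) {
  r <- toupper(as.character(ref_allele_seq))
  s <- toupper(as.character(ins_allele_seq))
  Lr <- nchar(r); Li <- nchar(s)
  if (Li <= Lr) {
    abort("unsupported-difference: second sequence is not longer (no insertion)")
  }
  rv <- strsplit(r, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  d <- Li - Lr

  lcp <- 0L
  while (lcp < Lr && rv[lcp + 1L] == sv[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < Lr && rv[Lr - lcs] == sv[Li - lcs]) lcs <- lcs + 1L

  # a single contiguous insertion at point p requires Lr - lcs <= p <= lcp
  if (max(0L, Lr - lcs) > min(lcp, Lr)) {
    abort("unsupported-difference: sequences do not differ by a single contiguous insertion")
  }
  p <- min(lcp, Lr)
  inserted <- substr(s, p + 1L, p + d)

  tsd_len <- 0L
  kmax <- min(tsd_max, p, d)
  for (k in seq_len(kmax)) {
    if (substr(r, p - k + 1L, p) == substr(inserted, d - k + 1L, d)) tsd_len <- k
  }
  structure(
    list(
      position = p,
      length = d,
      inserted_seq = inserted,
      tsd = if (tsd_len > 0) substr(inserted, d - tsd_len + 1L, d) else NA_character_,
      tsd_length = tsd_len
    ),
    class = "insertion_description"
  )
}

#' Reconstruct the insertion-bearing allele from a description
#'
#' Round-trip companion of [detect_insertion()].
#'
#' @param ref_allele_seq Reference allele DNA string.
#' @param insertion An `insertion_description`.
#' @return The insertion-bearing allele sequence.
#' @export
apply_insertion <- function(ref_allele_seq, insertion) {
  r <- as.character(ref_allele_seq)
  paste0(substr(r, 1, insertion$position), insertion$inserted_seq,
         substr(r, insertion$position + 1, nchar(r)))
}

#' Classify the coding consequence of an insertion
#'
#' Promoter insertions are classified `regulatory`. For CDS insertions the
#' mutated CDS is translated: a length not divisible by 3 is a `frameshift`
#' (scanned for the first downstream stop); an in-frame insertion is
#' `premature_stop` if a stop codon appears before the original terminal
#' codon, else `in_frame_no_stop`. `truncated_protein_length` counts the
#' amino acids before the new stop.
#'
#' @param cds Coding sequence (DNA string, ATG..stop) of the unmutated allele.
#' @param insertion An `insertion_description` positioned on `cds`.
#' @param location_class `"CDS"` or `"promoter"`.
#' @return A list of class `insertion_effect`: `classification`,
#'   `truncated_protein_length` (aa or `NA`).
#' @export
classify_insertion_effect <- function(cds, insertion,
                                      location_class = c("CDS", "promoter")) {
  location_class <- match.arg(location_class)
  if (location_class == "promoter") {
    return(structure(list(classification = "regulatory",
                          truncated_protein_length = NA_integer_),
                     class = "insertion_effect"))
  }
  cds <- toupper(as.character(cds))
  if (insertion$position < 0 || insertion$position > nchar(cds)) {
    abort("coordinate error: insertion position outside the CDS")
  }
  mutated <- apply_insertion(cds, insertion)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(mutated), if.fuzzy.codon = "X", no.init.codon = TRUE
  )))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  frameshift <- insertion$length %% 3L != 0L
  orig_codons <- nchar(cds) %/% 3L  # includes the terminal stop codon
  if (frameshift) {
    classification <- "frameshift"
    trunc_len <- if (stop_at > 0) as.integer(stop_at - 1L) else NA_integer_
  } else if (stop_at > 0 && stop_at < orig_codons + insertion$length %/% 3L) {
    classification <- "premature_stop"
    trunc_len <- as.integer(stop_at - 1L)
  } else {
    classification <- "in_frame_no_stop"
    trunc_len <- NA_integer_
  }
  structure(list(classification = classification,
                 truncated_protein_length = trunc_len),
            class = "insertion_effect")
}

#' Define a diagnostic indel PCR assay
#'
#' Bundles a primer pair with the expected amplicon sizes for the
#' presence/absence genotyping of an insertion allele. The insertion-allele
#' amplicon must equal the no-insertion amplicon plus the insertion length.
#'
#' @param name Assay label.
#' @param forward_primer,reverse_primer Primer sequences, 5'->3'. The forward
#'   primer anneals to the plus strand; the reverse primer's reverse
#'   complement must match downstream.
#' @param insertion_length Insertion length in bp.
#' @param location_class `"CDS"` or `"promoter"`.
#' @param no_insertion_amplicon Expected product size on the
#'   insertion-free allele, bp.
#' @return A list of class `indel_assay`.
#' @export
indel_assay <- function(name, forward_primer, reverse_primer, insertion_length,
                        location_class, no_insertion_amplicon) {
  structure(
    list(
      name = name,
      forward_primer = toupper(forward_primer),
      reverse_primer = toupper(reverse_primer),
      insertion_length = as.integer(insertion_length),
      location_class = location_class,
      expected_amplicons = c(
        no_insertion = as.integer(no_insertion_amplicon),
        insertion = as.integer(no_insertion_amplicon + insertion_length)
      )
    ),
    class = "indel_assay"
  )
}

#' In-silico PCR amplicon size
#'
#' Predicts the product length of a primer pair on a template under an
#' exact-match, unique-hit policy: the forward primer must match the plus
#' strand exactly once, and the reverse complement of the reverse primer must
#' match exactly once downstream of the forward site. The amplicon length is
#' the distance from the start of the forward site to the end of the reverse
#' site, inclusive.
#'
#' @param template Template DNA string.
#' @param assay An [indel_assay()] (or pass primers directly).
#' @param forward,reverse Primer strings, used when `assay` is `NULL`.
#' @return Amplicon length in bp.
#' @export
insilico_pcr <- function(template, assay = NULL, forward = NULL, reverse = NULL) {
  if (!is.null(assay)) {
    forward <- assay$forward_primer
    reverse <- assay$reverse_primer
  }
  tmpl <- Biostrings::DNAString(toupper(as.character(template)))
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(toupper(forward)), tmpl)
  if (length(f_hits) == 0) abort("no-amplicon: forward primer does not match template")
  if (length(f_hits) > 1) abort("ambiguous-amplicon: forward primer matches template more than once")
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(reverse)))
  r_hits <- Biostrings::matchPattern(rc, tmpl)
  r_hits <- r_hits[BiocGenerics::start(r_hits) > BiocGenerics::end(f_hits)]
  if (length(r_hits) == 0) abort("no-amplicon: reverse primer does not match downstream of the forward site")
  if (length(r_hits) > 1) abort("ambiguous-amplicon: reverse primer matches more than once")
  as.integer(BiocGenerics::end(r_hits) - BiocGenerics::start(f_hits) + 1L)
}

#' Genotype a diploid sample from its two allele amplicons
#'
#' Runs [insilico_pcr()] on each allele template of a diploid sample and
#' derives the genotype class from amplicon-size evidence alone: two short
#' products are `hom_no_insertion`, two long are `hom_insertion`, one of each
#' is `heterozygous`; any amplification failure yields `failed`.
#'
#' @param allele_templates Character vector of length 2: the sample's two
#'   allele sequences spanning the assay region.
#' @param assay An [indel_assay()].
#' @return One of `"hom_no_insertion"`, `"heterozygous"`, `"hom_insertion"`,
#'   `"failed"`.
#' @export
genotype_by_amplicons <- function(allele_templates, assay) {
  stopifnot(length(allele_templates) == 2)
  sizes <- vapply(allele_templates, function(t) {
    tryCatch(insilico_pcr(t, assay), error = function(e) NA_integer_)
  }, integer(1))
  if (anyNA(sizes)) return("failed")
  cls <- vapply(sizes, function(s) {
    if (s == assay$expected_amplicons[["no_insertion"]]) "short"
    else if (s == assay$expected_amplicons[["insertion"]]) "long"
    else "other"
  }, "")
  if (any(cls == "other")) return("failed")
  n_long <- sum(cls == "long")
  c("hom_no_insertion", "heterozygous", "hom_insertion")[n_long + 1L]
}

#' Per-group insertion-allele frequency table
#'
#' Aggregates diploid genotype classes into the per-taxon and per-pool survey
#' table: counts of the three genotype classes and the insertion-allele
#' frequency `p_ins = (2 * n_hom_ins + n_het) / (2 * n)`. Accepts either a
#' per-sample call table (columns `sample_id`, `call`, plus grouping columns)
#' or a pre-summarised count table (columns `group`, `n_hom_no_ins`, `n_het`,
#' `n_hom_ins`). Failed calls are excluded from `n`; empty groups are omitted
#' with a warning. A `Total` row aggregates all groups. Percentages are
#' rounded half-up to 2 decimals, with the exact fraction retained in
#' `p_ins`.
#'
#' @param x Calls tibble or counts tibble (see Details above).
#' @param group Column (character name) defining groups when `x` is a call
#'   table, default `"taxon"`.
#' @param total Add a `Total` row, default `TRUE`.
#' @return Tibble `group`, `n`, `n_hom_no_ins`, `n_het`, `n_hom_ins`,
#'   `p_ins`, `p_ins_percent`.
#' @export
allele_frequency_table <- function(x, group = "taxon", total = TRUE) {
  if (all(c("n_hom_no_ins", "n_het", "n_hom_ins") %in% names(x))) {
    counts <- as_tibble(x)
    if (!"group" %in% names(counts)) counts$group <- counts[[group]]
  } else {
    stopifnot("call" %in% names(x), group %in% names(x))
    x <- x[x$call != "failed", , drop = FALSE]
    counts <- x |>
      dplyr::group_by(group = .data[[group]]) |>
      dplyr::summarise(
        n_hom_no_ins = sum(.data$call == "hom_no_insertion"),
        n_het = sum(.data$call == "heterozygous"),
        n_hom_ins = sum(.data$call == "hom_insertion"),
        .groups = "drop"
      )
  }
  counts$n <- counts$n_hom_no_ins + counts$n_het + counts$n_hom_ins
  drop <- counts$n == 0
  if (any(drop)) {
    warn(paste0("omitting empty group(s): ",
                paste(counts$group[drop], collapse = ", ")))
    counts <- counts[!drop, , drop = FALSE]
  }
  if (total && nrow(counts) > 1) {
    tot <- dplyr::summarise(
      counts, group = "Total",
      n_hom_no_ins = sum(.data$n_hom_no_ins), n_het = sum(.data$n_het),
      n_hom_ins = sum(.data$n_hom_ins), n = sum(.data$n)
    )
    counts <- dplyr::bind_rows(counts, tot)
  }
  counts$p_ins <- (2 * counts$n_hom_ins + counts$n_het) / (2 * counts$n)
  counts$p_ins_percent <- round_half_up(100 * counts$p_ins, 2)
  counts[, c("group", "n", "n_hom_no_ins", "n_het", "n_hom_ins",
             "p_ins", "p_ins_percent")]
}

# round half away from zero (printed-table convention); base round() is
# round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pairwise Fst between two groups at a biallelic locus
#'
#' Computes the fixation index between two allele-frequency records by one of
#' three labelled estimators: Hudson's two-population estimator (as
#' formulated from allele counts), Weir & Cockerham's theta for two demes
#' (using observed heterozygote counts), or Nei's Gst
#' `(Ht - Hs) / Ht` with unweighted subpopulation means. Negative estimates
#' are preserved in the raw output (clamp only for reporting). When both
#' groups are monomorphic for the same allele Fst is undefined and `NA` is
#' returned.
#'
#' @param rec_a,rec_b Single rows of an [allele_frequency_table()] (fields
#'   `n`, `n_hom_no_ins`, `n_het`, `n_hom_ins`, `p_ins`).
#' @param estimator `"hudson"`, `"weir_cockerham"` or `"nei_gst"`, or a
#'   vector of them.
#' @return Tibble `group_a`, `group_b`, `estimator`, `fst`.
#' @export
pairwise_fst <- function(rec_a, rec_b,
                         estimator = c("hudson", "weir_cockerham", "nei_gst")) {
  estimator <- match.arg(estimator, several.ok = TRUE)
  if (rec_a$n < 2 || rec_b$n < 2) abort("both groups must have n >= 2")
  p1 <- rec_a$p_ins; p2 <- rec_b$p_ins
  n1 <- 2 * rec_a$n; n2 <- 2 * rec_b$n   # allele counts
  monomorphic_same <- (p1 == p2) && (p1 == 0 || p1 == 1)

  one <- function(est) {
    if (monomorphic_same) return(NA_real_)
    switch(est,
      hudson = {
        num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
        den <- p1 * (1 - p2) + p2 * (1 - p1)
        num / den
      },
      weir_cockerham = wc_theta(rec_a, rec_b),
      nei_gst = {
        pbar <- (p1 + p2) / 2
        ht <- 2 * pbar * (1 - pbar)
        hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
        (ht - hs) / ht
      }
    )
  }
  tibble(
    group_a = rec_a[["group"]] %||% "a",
    group_b = rec_b[["group"]] %||% "b",
    estimator = estimator,
    fst = unname(vapply(estimator, one, numeric(1)))
  )
}

# Weir & Cockerham (1984) theta for r = 2 demes, using observed heterozygosity
# from the genotype-class counts.
wc_theta <- function(rec_a, rec_b) {
  r <- 2
  n_i <- c(rec_a$n, rec_b$n)                  # diploid sample sizes
  p_i <- c(rec_a$p_ins, rec_b$p_ins)
  h_i <- c(rec_a$n_het / rec_a$n, rec_b$n_het / rec_b$n)  # observed het
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}
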