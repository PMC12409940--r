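#' Diploid genotype matrix
#'
#' Container for diploid genotype calls at variant sites across samples, the
#' unit of data flowing from VCF ingestion into the diversity scan. Sites are
#' kept sorted by `(chrom, pos)`; allele codes are integers (0 = reference,
#' `1..k` = alternate alleles, `NA` = missing call). Coordinates are 1-based
#' inclusive throughout, as in VCF and GFF3.
#'
#' @param sites Tibble with columns `chrom` (character), `pos` (integer,
#'   1-based), `ref` (character), `alt` (list column of character vectors of
#'   alternate alleles).
#' @param allele1,allele2 Integer matrices, sites x samples, holding the two
#'   allele slots of each diploid call. `NA` in both slots marks a missing
#'   call.
#' @param sample_ids Character vector naming the matrix columns, in order.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'
#' @return An object of class `genotype_matrix`.
#' @seealso [read_vcf()], [apply_variant_filters()], [tidy.genotype_matrix()]
#' @export
genotype_matrix <- function(sites, allele1, allele2, sample_ids, chrom_lengths) {
  sites <- as_tibble(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.list(sites$alt),
    nrow(allele1) == nrow(sites),
    identical(dim(allele1), dim(allele2)),
    ncol(allele1) == length(sample_ids)
  )
  if (nrow(sites) > 0) {
    if (any(sites$pos < 1)) abort("site positions must be >= 1")
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    allele1 <- allele1[ord, , drop = FALSE]
    allele2 <- allele2[ord, , drop = FALSE]
    key <- paste(sites$chrom, sites$pos, sites$ref,
                 vapply(sites$alt, paste, "", collapse = ","))
    if (anyDuplicated(key)) abort("duplicate (chrom, pos, ref, alt) site records")
    n_allele <- lengths(sites$alt) + 1L
    mx <- pmax(
      suppressWarnings(apply(allele1, 1, max, na.rm = TRUE)),
      suppressWarnings(apply(allele2, 1, max, na.rm = TRUE))
    )
    mx[!is.finite(mx)] <- 0
    if (any(mx >= n_allele)) abort("allele index exceeds number of ALT alleles at a site")
  }
  colnames(allele1) <- colnames(allele2) <- sample_ids
  structure(
    list(
      sites = sites,
      allele1 = allele1,
      allele2 = allele2,
      sample_ids = sample_ids,
      chrom_lengths = chrom_lengths
    ),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d sites x %d samples on %d chromosome(s)\n",
    nrow(x$sites), length(x$sample_ids), length(x$chrom_lengths)
  ))
  n_miss <- sum(is.na(x$allele1))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", n_miss,
              100 * n_miss / max(1, length(x$allele1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), length(x$sample_ids))

#' Tidy a genotype matrix into long per-call records
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (site, sample): `chrom`, `pos`, `ref`,
#'   `sample_id`, `allele1`, `allele2`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  if (nrow(x$sites) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  sample_id = character(), allele1 = integer(), allele2 = integer()))
  }
  tibble(
    chrom = rep(x$sites$chrom, times = length(x$sample_ids)),
    pos = rep(x$sites$pos, times = length(x$sample_ids)),
    ref = rep(x$sites$ref, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = nrow(x$sites)),
    allele1 = as.integer(x$allele1),
    allele2 = as.integer(x$allele2)
  )
}

#' Subset a genotype matrix to a set of samples
#'
#' @param gm A [genotype_matrix()].
#' @param samples Character vector of sample ids to keep (order preserved).
#' @return A `genotype_matrix` restricted to `samples`.
#' @export
subset_samples <- function(gm, samples) {
  missing <- setdiff(samples, gm$sample_ids)
  if (length(missing) > 0) {
    abort(paste0("samples absent from genotype matrix: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(samples, gm$sample_ids)
  genotype_matrix(gm$sites, gm$allele1[, idx, drop = FALSE],
                  gm$allele2[, idx, drop = FALSE], samples, gm$chrom_lengths)
}

# per-site expected heterozygosity with sample-size correction:
# h = (n^2 - sum n_i^2) / (n (n - 1)) over non-missing called alleles.
# Returns 0 for sites with fewer than 2 called alleles (undefined -> no signal).
site_heterozygosity <- function(a1, a2) {
  n_sites <- nrow(a1)
  if (n_sites == 0) return(numeric(0))
  n <- rowSums(!is.na(a1)) + rowSums(!is.na(a2))
  max_code <- suppressWarnings(max(a1, a2, na.rm = TRUE))
  if (!is.finite(max_code)) max_code <- 0
  sumsq <- numeric(n_sites)
  for (v in 0:max_code) {
    cv <- rowSums(a1 == v, na.rm = TRUE) + rowSums(a2 == v, na.rm = TRUE)
    sumsq <- sumsq + cv^2
  }
  h <- ifelse(n >= 2, (n^2 - sumsq) / (n * (n - 1)), 0)
  h
}
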