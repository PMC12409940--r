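#' Read a VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (GT field required, other FORMAT fields ignored) into
#' a [genotype_matrix()]. Missing calls (`./.`) are preserved as `NA`;
#' multi-allelic sites are retained with integer allele codes. Sites are sorted
#' by `(chrom, pos)` on read. Chromosome lengths are taken from `##contig`
#' header lines when present, otherwise from the maximum observed position.
#'
#' @param path Path to a VCF file.
#' @param panel Optional population panel tibble (see [read_panel()]); every
#'   panel sample must be present in the VCF, otherwise a panel-mismatch error
#'   is raised.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 1) abort("VCF has no sample columns")
  sample_ids <- colnames(gt)[-1]
  n_sites <- nrow(fix)

  if (n_sites > 0) {
    fmt <- gt[, 1]
    gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                     function(f) match("GT", f), integer(1))
    if (anyNA(gt_idx)) {
      abort(sprintf("VCF record %d has no GT in FORMAT",
                    which(is.na(gt_idx))[1]))
    }
    calls <- gt[, -1, drop = FALSE]
    # strip any trailing FORMAT subfields, keep the GT token
    first_field <- function(x, k) {
      vapply(strsplit(x, ":", fixed = TRUE), function(p) p[k], "")
    }
    gt_str <- matrix("", n_sites, length(sample_ids))
    for (j in seq_along(sample_ids)) {
      gt_str[, j] <- first_field(calls[, j], 1L)  # GT is first per VCF spec
    }
    gt_str[is.na(gt_str)] <- "."  # vcfR converts missing fields to NA
    ok <- matrix(grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt_str),
                 n_sites)
    if (!all(ok)) {
      bad <- which(!ok, arr.ind = TRUE)[1, ]
      abort(sprintf("malformed genotype at VCF record %d, sample %s: '%s'",
                    bad[1], sample_ids[bad[2]], gt_str[bad[1], bad[2]]))
    }
    a_chr <- sub("^([^/|]+)([/|].*)?$", "\\1", gt_str)
    b_chr <- ifelse(grepl("[/|]", gt_str), sub("^[^/|]+[/|]", "", gt_str), a_chr)
    to_int <- function(m) {
      out <- suppressWarnings(matrix(as.integer(m), n_sites))
      out
    }
    a1 <- to_int(a_chr)
    a2 <- to_int(b_chr)
    # a half-missing diploid call is treated as missing
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    sites <- tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = strsplit(ifelse(is.na(fix$ALT) | fix$ALT == ".", "", fix$ALT), ",", fixed = TRUE)
    )
  } else {
    sites <- tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = list())
    a1 <- a2 <- matrix(NA_integer_, 0, length(sample_ids))
  }

  meta <- v@meta
  contig <- grep("^##contig=", meta, value = TRUE)
  if (length(contig) > 0) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", contig)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
    chrom_lengths <- setNames(lens, ids)
    chrom_lengths <- chrom_lengths[!is.na(chrom_lengths)]
  } else chrom_lengths <- numeric(0)
  for (ch in setdiff(unique(sites$chrom), names(chrom_lengths))) {
    chrom_lengths[ch] <- max(sites$pos[sites$chrom == ch])
  }

  if (!is.null(panel)) {
    absent <- setdiff(panel$sample_id, sample_ids)
    if (length(absent) > 0) {
      abort(paste0("panel-mismatch: samples in panel but not in VCF: ",
                   paste(absent, collapse = ", ")))
    }
  }
  genotype_matrix(sites, a1, a2, sample_ids, chrom_lengths)
}

#' Write a genotype matrix as a plain-text VCF v4.2 file
#'
#' Inverse of [read_vcf()] for the fields this package uses: CHROM, POS, REF,
#' ALT and per-sample GT. Round-trips genotype calls and positions exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in names(gm$chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(gm$chrom_lengths[[ch]])), con)
  }
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$sample_ids), collapse = "\t"), con)
  n <- nrow(gm$sites)
  if (n > 0) {
    fmt_gt <- matrix("./.", n, length(gm$sample_ids))
    called <- !is.na(gm$allele1)
    fmt_gt[called] <- paste0(gm$allele1[called], "/", gm$allele2[called])
    alt_str <- vapply(gm$sites$alt, function(a) {
      if (length(a) == 0) "." else paste(a, collapse = ",")
    }, "")
    lines <- paste(
      gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref, alt_str, ".", ".", ".",
      "GT", apply(fmt_gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Filter variant sites on missingness and minor allele frequency
#'
#' Applies the site-level quality filters used ahead of the diversity scan: a
#' site is removed iff its missing-call fraction exceeds `max_missing` or its
#' minor allele frequency, computed over non-missing alleles only, is strictly
#' below `min_maf`. Both comparisons are strict, so a site with MAF exactly
#' `min_maf` is retained. Sites where every call is missing are removed with
#' reason `"all_missing"` (MAF undefined). For multi-allelic sites MAF is the
#' combined frequency of all non-major alleles. Filtering removes whole sites
#' and never alters surviving genotype values; it is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param max_missing Maximum tolerated missing-call fraction, default 0.20.
#' @param min_maf Minimum minor allele frequency, default 0.05.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`, a tibble of removed sites with columns `chrom`, `pos`,
#'   `reason`, `missing_fraction`, `maf`.
#' @export
apply_variant_filters <- function(gm, max_missing = 0.20, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 0.5)
  if (length(gm$sample_ids) == 0) abort("genotype matrix has no samples")
  n_sites <- nrow(gm$sites)
  if (n_sites == 0) {
    return(list(genotypes = gm,
                report = tibble(chrom = character(), pos = integer(),
                                reason = character(),
                                missing_fraction = numeric(), maf = numeric())))
  }
  n_samples <- length(gm$sample_ids)
  n_missing <- rowSums(is.na(gm$allele1))
  miss_frac <- n_missing / n_samples

  n_called <- 2 * (n_samples - n_missing)
  max_code <- suppressWarnings(max(gm$allele1, gm$allele2, na.rm = TRUE))
  if (!is.finite(max_code)) max_code <- 0
  major <- numeric(n_sites)
  for (v in 0:max_code) {
    cv <- rowSums(gm$allele1 == v, na.rm = TRUE) +
      rowSums(gm$allele2 == v, na.rm = TRUE)
    major <- pmax(major, cv)
  }
  maf <- ifelse(n_called > 0, 1 - major / n_called, NA_real_)

  all_missing <- n_called == 0
  fail_miss <- miss_frac > max_missing
  fail_maf <- !all_missing & maf < min_maf
  drop <- all_missing | fail_miss | fail_maf
  reason <- dplyr::case_when(
    all_missing ~ "all_missing",
    fail_miss ~ "missingness",
    fail_maf ~ "low_maf",
    TRUE ~ NA_character_
  )
  report <- tibble(
    chrom = gm$sites$chrom[drop],
    pos = gm$sites$pos[drop],
    reason = reason[drop],
    missing_fraction = miss_frac[drop],
    maf = maf[drop]
  )
  keep <- !drop
  filtered <- genotype_matrix(
    gm$sites[keep, , drop = FALSE],
    gm$allele1[keep, , drop = FALSE],
    gm$allele2[keep, , drop = FALSE],
    gm$sample_ids, gm$chrom_lengths
  )
  list(genotypes = filtered, report = report)
}

#' Read gene models from a GFF3 file
#'
#' Returns only `gene`-type features, with 1-based inclusive coordinates
#' preserved. Attribute key/value pairs are kept as a single string; the
#' `ID` attribute becomes `gene_id`.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `attributes`.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  g <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) > 0 && any(g$end < g$start)) {
    abort("GFF3 format error: gene feature with end < start")
  }
  ids <- sub(".*?ID=([^;]+).*", "\\1", g$attributes)
  ids[!grepl("ID=", g$attributes)] <- NA_character_
  tibble(
    gene_id = ids,
    chrom = as.character(g$seqid),
    start = as.integer(g$start),
    end = as.integer(g$end),
    strand = as.character(g$strand),
    attributes = as.character(g$attributes)
  )
}

#' Write gene models as GFF3
#'
#' @param genes Tibble as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  attrs <- if ("attributes" %in% names(genes)) genes$attributes else
    paste0("ID=", genes$gene_id)
  writeLines(paste(genes$chrom, "pomesweep", "gene", genes$start, genes$end,
                   ".", genes$strand, ".", attrs, sep = "\t"), con)
  invisible(path)
}

#' Read or construct a population panel
#'
#' A panel assigns each sample to a pool (`wild` or `cultivated`) and an
#' optional taxon label. The file format is 2-column TSV `sample_id`,
#' `pool[:taxon]` (header optional, detected).
#'
#' @param path Path to a panel TSV.
#' @return Tibble with columns `sample_id`, `pool`, `taxon`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  raw <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(raw[1, 1]), "sample_id")) raw <- raw[-1, , drop = FALSE]
  pool_taxon <- strsplit(raw[, 2], ":", fixed = TRUE)
  tibble(
    sample_id = raw[, 1],
    pool = vapply(pool_taxon, `[`, "", 1),
    taxon = vapply(pool_taxon, function(x) if (length(x) > 1) x[2] else NA_character_, "")
  )
}

#' @rdname read_panel
#' @param panel Panel tibble to write.
#' @export
write_panel <- function(panel, path) {
  second <- ifelse(is.na(panel$taxon), panel$pool,
                   paste0(panel$pool, ":", panel$taxon))
  writeLines(c("sample_id\tpool", paste(panel$sample_id, second, sep = "\t")), path)
  invisible(path)
}

# samples belonging to a pool, validated against the genotype matrix
pool_samples <- function(panel, pool, gm = NULL) {
  s <- panel$sample_id[panel$pool == pool]
  if (length(s) == 0) abort(paste0("pool '", pool, "' is empty"))
  if (!is.null(gm)) {
    absent <- setdiff(s, gm$sample_ids)
    if (length(absent) > 0) {
      abort(paste0("panel-mismatch: samples not in genotype matrix: ",
                   paste(absent, collapse = ", ")))
    }
  }
  s
}
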