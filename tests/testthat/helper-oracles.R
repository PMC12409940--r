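# Independent oracles and fixture builders used across the suite.

# build a genotype_matrix from a character matrix of "a/b" calls
# (sites x samples), "./." for missing
build_gm <- function(calls, pos, chrom = "chr1", ref = NULL, alt = NULL,
                     chrom_lengths = NULL) {
  calls <- as.matrix(calls)
  n_sites <- nrow(calls)
  n_samp <- ncol(calls)
  split1 <- function(x, k) {
    v <- suppressWarnings(as.integer(vapply(strsplit(x, "/", fixed = TRUE),
                                            `[`, "", k)))
    v
  }
  a1 <- matrix(split1(calls, 1), n_sites)
  a2 <- matrix(split1(calls, 2), n_sites)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) {
    n_alt <- pmax(1, apply(cbind(a1, a2), 1, function(r) {
      m <- suppressWarnings(max(r, na.rm = TRUE))
      if (is.finite(m)) m else 1
    }))
    alt <- lapply(n_alt, function(k) c("T", "G", "C")[seq_len(k)])
  }
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(rep(max(pos) + 1000, length(unique(chrom))),
                                     unique(rep(chrom, length.out = n_sites)))
  }
  genotype_matrix(
    tibble::tibble(chrom = rep(chrom, length.out = n_sites),
                   pos = as.integer(pos), ref = ref, alt = alt),
    a1, a2, sprintf("s%02d", seq_len(n_samp)), chrom_lengths
  )
}

# brute-force windowed pi: mean pairwise mismatch indicator over all allele
# pairs at each site, summed and divided by window length
pi_bruteforce <- function(gm, samples, chrom, start, end) {
  idx <- match(samples, gm$sample_ids)
  in_win <- which(gm$sites$chrom == chrom & gm$sites$pos >= start &
                    gm$sites$pos <= end)
  total <- 0
  for (i in in_win) {
    alleles <- c(gm$allele1[i, idx], gm$allele2[i, idx])
    alleles <- alleles[!is.na(alleles)]
    n <- length(alleles)
    if (n < 2) next
    mm <- outer(alleles, alleles, "!=")
    total <- total + sum(mm[upper.tri(mm)]) / choose(n, 2)
  }
  total / (end - start + 1)
}

# random additive (tree-metric) distance matrix from a random unrooted tree
random_additive <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.1, 1))
    tr$tip.label <- sample(sprintf("t%02d", seq_len(n_taxa)))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# Fst oracles, coded separately from the package implementations
hudson_fst_oracle <- function(p1, n1_alleles, p2, n2_alleles) {
  hw <- p1 * (1 - p1) * n1_alleles / (n1_alleles - 1) +
    p2 * (1 - p2) * n2_alleles / (n2_alleles - 1)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  1 - hw / hb   # Hw here is already the two-pop mean x2 / 2 simplification
}

nei_gst_oracle <- function(p1, p2) {
  pbar <- mean(c(p1, p2))
  ht <- 2 * pbar * (1 - pbar)
  hs <- mean(c(2 * p1 * (1 - p1), 2 * p2 * (1 - p2)))
  (ht - hs) / ht
}

# Weir-Cockerham theta written directly from the published variance
# components for r demes (vector input)
wc_theta_oracle <- function(n_dip, p, het_obs) {
  r <- length(n_dip)
  nbar <- mean(n_dip)
  nc <- (r * nbar - sum(n_dip^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_dip * p) / (r * nbar)
  s2 <- sum(n_dip * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_dip * het_obs) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# allele-frequency record rows used by Fst tests
aft_record <- function(group, hom_ref, het, hom_ins) {
  allele_frequency_table(
    tibble::tibble(group = group, n_hom_no_ins = hom_ref, n_het = het,
                   n_hom_ins = hom_ins),
    total = FALSE
  )
}

# small, fast simulation configuration for structural tests
small_sim_config <- function(...) {
  simulation_config(chrom_length = 200000, generations = 60,
                    n_sample_wild = 12, n_sample_cult = 12, ...)
}
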