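#' Configuration for the domestication simulator
#'
#' Defines the study conditions the synthetic data emulate: a wild diploid
#' population evolving neutrally, and a cultivated lineage founded through a
#' domestication bottleneck that then experiences positive selection on a
#' diagnostic insertion allele inside a MYB-like gene. Defaults are chosen to
#' mirror the structure of a wild/cultivated pome-fruit panel: moderate wild
#' insertion-allele frequency, a strong bottleneck, and enough generations of
#' selection for the insertion to approach fixation in cultivars.
#'
#' The neutral background is organised in linkage blocks of
#' `block_size` bp. Each block carries one "anchor" variant on a young
#' haplotype bearing no other variation; a fraction `linked_fraction` of the
#' block's SNPs segregate only on the non-anchor background (complete
#' linkage), the remainder drift independently (recombined). The focal
#' block's anchor is the diagnostic insertion, so a sweep on it erases the
#' linked variation in cultivars — the hitchhiking signature the theta-pi
#' ratio scan detects. Every block has identical structure, which makes the
#' focal window statistically exchangeable with the rest of the genome when
#' selection is absent.
#'
#' @param chrom_length Chromosome length in bp, default 500000.
#' @param n_wild_founders Wild census size (diploids), default 200; also the
#'   cultivated census size after post-bottleneck recovery.
#' @param bottleneck_size Diploids founding the cultivated lineage, default 50.
#' @param generations Generations since domestication, default 200.
#' @param s Additive selection coefficient favouring the insertion allele in
#'   cultivars (genotype fitnesses 1, 1 + s/2, 1 + s), default 0.1.
#' @param snp_density Expected segregating SNPs per bp, default 1e-3
#'   (about 1 SNP/kb).
#' @param n_sample_wild,n_sample_cult Sampled diploids per pool, defaults 30.
#' @param block_size Linkage-block size in bp, default 50000.
#' @param linked_fraction Fraction of each block's SNPs in complete linkage
#'   with the block anchor, default 0.7.
#' @param founder_freq_range Range from which block-anchor founder
#'   frequencies are drawn, default `c(0.1, 0.4)`.
#' @param insertion_length Length of the focal insertion in bp, default 411.
#' @param tsd Target-site duplication sequence, default `"TTCCTAGT"`.
#' @param phenotype_means Named vector of mean PA content (mg/g) by genotype
#'   class, default `c(tt = 2, Tt = 9, TT = 10)` (tt = homozygous insertion).
#' @param phenotype_sd Phenotype noise SD, default 1.5.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(chrom_length = 500000,
                              n_wild_founders = 200,
                              bottleneck_size = 50,
                              generations = 200,
                              s = 0.1,
                              snp_density = 1e-3,
                              n_sample_wild = 30,
                              n_sample_cult = 30,
                              block_size = 50000,
                              linked_fraction = 0.7,
                              founder_freq_range = c(0.1, 0.4),
                              insertion_length = 411,
                              tsd = "TTCCTAGT",
                              phenotype_means = c(tt = 2, Tt = 9, TT = 10),
                              phenotype_sd = 1.5) {
  stopifnot(
    s >= 0, bottleneck_size <= n_wild_founders,
    linked_fraction >= 0, linked_fraction <= 1,
    chrom_length >= block_size,
    phenotype_means[["tt"]] <= phenotype_means[["Tt"]],
    phenotype_means[["Tt"]] <= phenotype_means[["TT"]]
  )
  structure(as.list(environment()), class = "simulation_config")
}

# one generation of Wright-Fisher drift for a vector of allele frequencies
wf_drift <- function(p, n_alleles) {
  rbinom(length(p), n_alleles, p) / n_alleles
}

# drift of conditional frequencies on the non-anchor background, whose
# effective size shrinks with anchor frequency p (floored at 2 alleles)
wf_drift_background <- function(q, p_block, block_of, n_alleles) {
  bg <- pmax(2, round(n_alleles * (1 - p_block[block_of])))
  rbinom(length(q), bg, q) / bg
}

#' Simulate a domestication study
#'
#' Forward Wright-Fisher simulation of the two-population design: the wild
#' population evolves neutrally at constant size; the cultivated lineage is
#' founded by a single bottleneck generation of `bottleneck_size` diploids
#' sampled from the wild founders, recovers to the wild census size, and then
#' evolves with additive selection `s` on the insertion allele. Both lineages
#' run `generations` generations from the shared founding state, after which
#' `n_sample_wild` + `n_sample_cult` diploids are sampled and written as a
#' genotype matrix (SNPs plus the focal indel with its full inserted
#' sequence). If the insertion allele is lost in the cultivated lineage
#' before sampling the run is retried (up to 100 times, with the retry count
#' recorded).
#'
#' Identical config + seed yields identical output (and byte-identical files
#' via [write_study()]).
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_study`: `genotypes` (a
#'   [genotype_matrix()]), `panel`, `genes`, `phenotypes`, `assay`
#'   (the diagnostic [indel_assay()] plus allele templates), `truth` (focal
#'   position, per-pool sampled insertion frequencies, per-window pi,
#'   retries), and the `config`.
#' @export
simulate_domestication <- function(cfg = simulation_config(), seed = 1) {
  withr::with_seed(as.integer(seed), simulate_domestication_impl(cfg))
}

simulate_domestication_impl <- function(cfg) {
  n_blocks <- floor(cfg$chrom_length / cfg$block_size)
  block_starts <- 1L + cfg$block_size * (seq_len(n_blocks) - 1L)
  focal_block <- ceiling(n_blocks / 2)

  # site layout: one anchor per block (focal anchor = the indel) + SNPs
  n_snps <- rpois(1, cfg$snp_density * cfg$chrom_length)
  snp_pos <- sort(sample.int(cfg$chrom_length, n_snps))
  anchor_pos <- as.integer(block_starts + floor(cfg$block_size / 2))
  # keep the TSD footprint upstream of the focal anchor free of SNPs
  tsd_footprint <- (anchor_pos[focal_block] - nchar(cfg$tsd)):anchor_pos[focal_block]
  snp_pos <- setdiff(snp_pos, c(anchor_pos, tsd_footprint))
  n_snps <- length(snp_pos)
  snp_block <- pmin(n_blocks, (snp_pos - 1L) %/% cfg$block_size + 1L)
  snp_linked <- runif(n_snps) < cfg$linked_fraction

  # founding state
  p0 <- runif(n_blocks, cfg$founder_freq_range[1], cfg$founder_freq_range[2])
  q0 <- runif(n_snps, 0.1, 0.9)

  n_wild_al <- 2 * cfg$n_wild_founders
  evolve <- function(p, q, n_alleles, gens, sel) {
    for (g in seq_len(gens)) {
      if (sel > 0) {
        pf <- p[focal_block]
        wbar <- pf^2 * (1 + sel) + 2 * pf * (1 - pf) * (1 + sel / 2) + (1 - pf)^2
        p_star <- (pf^2 * (1 + sel) + pf * (1 - pf) * (1 + sel / 2)) / wbar
        p[focal_block] <- p_star
      }
      p <- wf_drift(p, n_alleles)
      q[snp_linked] <- wf_drift_background(q[snp_linked], p,
                                           snp_block[snp_linked], n_alleles)
      q[!snp_linked] <- wf_drift(q[!snp_linked], n_alleles)
      if (sel > 0 && p[focal_block] == 0) return(NULL)  # insertion lost
    }
    list(p = p, q = q)
  }

  retries <- 0L
  repeat {
    # wild lineage: neutral drift from the founding state
    wild <- evolve(p0, q0, n_wild_al, cfg$generations, sel = 0)
    # cultivated lineage: bottleneck founding, recovery, then selection
    nb <- 2 * cfg$bottleneck_size
    pc <- rbinom(n_blocks, nb, p0) / nb
    qc <- q0
    qc[snp_linked] <- wf_drift_background(q0[snp_linked], pc,
                                          snp_block[snp_linked], nb)
    qc[!snp_linked] <- rbinom(sum(!snp_linked), nb, q0[!snp_linked]) / nb
    cult <- if (cfg$s > 0 && pc[focal_block] == 0) NULL else
      evolve(pc, qc, n_wild_al, cfg$generations, sel = cfg$s)
    if (!is.null(cult)) break
    retries <- retries + 1L
    if (retries > 100L) abort("insertion allele lost in cultivated lineage in 100 consecutive runs")
  }

  # sample diploid genotypes: per haplotype, anchor ~ Bern(p_b); linked SNPs
  # ride only the non-anchor background; unlinked SNPs are free
  sample_pool <- function(state, n_dip) {
    n_hap <- 2 * n_dip
    anchors <- matrix(
      rbinom(n_hap * n_blocks, 1, rep(state$p, each = n_hap)), n_hap)
    snps <- matrix(
      rbinom(n_hap * n_snps, 1, rep(state$q, each = n_hap)), n_hap)
    if (any(snp_linked)) {
      on_anchor <- anchors[, snp_block[snp_linked], drop = FALSE] == 1
      snps[, snp_linked][on_anchor] <- 0L
    }
    list(anchors = anchors, snps = snps)
  }
  hw <- sample_pool(wild, cfg$n_sample_wild)
  hc <- sample_pool(cult, cfg$n_sample_cult)

  # assemble the site table (reference bases assigned deterministically)
  bases <- c("A", "C", "G", "T")
  all_pos <- c(anchor_pos, snp_pos)
  is_anchor <- c(rep(TRUE, n_blocks), rep(FALSE, n_snps))
  ord <- order(all_pos)
  ref_b <- bases[sample.int(4, length(all_pos), replace = TRUE)]
  alt_b <- vapply(ref_b, function(r) sample(setdiff(bases, r), 1), "")

  ins_seq <- paste(c(bases[sample.int(4, cfg$insertion_length - nchar(cfg$tsd),
                                      replace = TRUE)],
                     strsplit(cfg$tsd, "")[[1]]), collapse = "")
  focal_pos <- anchor_pos[focal_block]
  focal_idx_unsorted <- focal_block  # anchors come first in all_pos
  # the focal REF base is the last TSD base so VCF and reference agree
  ref_b[focal_idx_unsorted] <- substr(cfg$tsd, nchar(cfg$tsd), nchar(cfg$tsd))
  ref_col <- ref_b
  alt_col <- as.list(unname(alt_b))
  alt_col[[focal_idx_unsorted]] <- paste0(ref_b[focal_idx_unsorted], ins_seq)

  sites <- tibble(chrom = "chr1", pos = all_pos, ref = ref_col, alt = alt_col)

  hap_to_calls <- function(h) {
    full <- cbind(h$anchors, h$snps)  # haplotypes x (anchors, snps)
    n_dip <- nrow(full) / 2
    a1 <- t(full[2 * seq_len(n_dip) - 1, , drop = FALSE])
    a2 <- t(full[2 * seq_len(n_dip), , drop = FALSE])
    list(a1 = a1, a2 = a2)
  }
  cw <- hap_to_calls(hw)
  cc <- hap_to_calls(hc)
  a1 <- cbind(cw$a1, cc$a1)
  a2 <- cbind(cw$a2, cc$a2)
  sample_ids <- c(sprintf("W%03d", seq_len(cfg$n_sample_wild)),
                  sprintf("C%03d", seq_len(cfg$n_sample_cult)))
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  gm <- genotype_matrix(sites[ord, ], a1[ord, , drop = FALSE],
                        a2[ord, , drop = FALSE], sample_ids,
                        c(chr1 = cfg$chrom_length))

  panel <- tibble(
    sample_id = sample_ids,
    pool = rep(c("wild", "cultivated"),
               c(cfg$n_sample_wild, cfg$n_sample_cult)),
    taxon = rep(c("synthetic_wild", "synthetic_cultivar"),
                c(cfg$n_sample_wild, cfg$n_sample_cult))
  )

  genes <- synthetic_genes(cfg, focal_pos)
  assay <- synthetic_study_assay(cfg, focal_pos, ins_seq)
  phenotypes <- simulate_phenotypes(
    focal_genotype_classes(gm, focal_pos),
    effects = cfg$phenotype_means, noise_sd = cfg$phenotype_sd
  )

  focal_site <- which(gm$sites$pos == focal_pos)
  freq_of <- function(samples) {
    idx <- match(samples, gm$sample_ids)
    mean(c(gm$allele1[focal_site, idx], gm$allele2[focal_site, idx]),
         na.rm = TRUE)
  }
  win <- make_windows(gm$chrom_lengths, cfg$block_size, cfg$block_size)
  truth_pi <- as_tibble(pi_ratio_scan(gm, panel, windows = win))[
    , c("chrom", "start", "end", "pi_wild", "pi_cult")]
  truth <- list(
    focal_chrom = "chr1", focal_pos = focal_pos,
    focal_block_start = block_starts[focal_block],
    focal_block_end = block_starts[focal_block] + cfg$block_size - 1L,
    insertion_length = cfg$insertion_length,
    p_ins_wild_sampled = freq_of(panel$sample_id[panel$pool == "wild"]),
    p_ins_cult_sampled = freq_of(panel$sample_id[panel$pool == "cultivated"]),
    window_pi = truth_pi,
    retries = retries
  )

  structure(
    list(genotypes = gm, panel = panel, genes = genes, phenotypes = phenotypes,
         assay = assay, truth = truth, config = cfg),
    class = "synthetic_study"
  )
}

#' @exportS3Method base::print
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d sites, %d wild + %d cultivated diploids; focal insertion at %s:%d\n",
    nrow(x$genotypes$sites), x$config$n_sample_wild, x$config$n_sample_cult,
    x$truth$focal_chrom, x$truth$focal_pos
  ))
  cat(sprintf("  sampled insertion frequency: wild %.3f, cultivated %.3f (retries %d)\n",
              x$truth$p_ins_wild_sampled, x$truth$p_ins_cult_sampled,
              x$truth$retries))
  invisible(x)
}

# gene annotation: the focal MYB-like gene straddles the insertion; decoys
# tile the rest of the chromosome
synthetic_genes <- function(cfg, focal_pos) {
  gene_len <- 3000L
  focal <- tibble(
    gene_id = "MYBTT_like", chrom = "chr1",
    start = as.integer(focal_pos - 1000L), end = as.integer(focal_pos - 1001L + gene_len),
    strand = "+", attributes = "ID=MYBTT_like;family=MYB;subgroup=SG5"
  )
  n_decoys <- 11L
  starts <- as.integer(round(seq(5000, cfg$chrom_length - gene_len - 5000,
                                 length.out = n_decoys)))
  decoys <- tibble(
    gene_id = sprintf("decoy_%02d", seq_len(n_decoys)), chrom = "chr1",
    start = starts, end = starts + gene_len - 1L, strand = "+",
    attributes = sprintf("ID=decoy_%02d;family=other", seq_len(n_decoys))
  )
  decoys <- decoys[!(decoys$start <= focal$end & decoys$end >= focal$start), ]
  out <- dplyr::bind_rows(focal, decoys)
  out[order(out$start), ]
}

# diagnostic assay over the focal insertion, with both allele templates
synthetic_study_assay <- function(cfg, focal_pos, ins_seq) {
  synthetic_indel_fixture(
    name = "focal_indel", insertion_length = cfg$insertion_length,
    no_insertion_amplicon = 244L, inserted_seq = ins_seq,
    location_class = "CDS", tsd = cfg$tsd
  )
}

#' Genotype classes at the focal indel of a simulated study
#'
#' @param gm The study's [genotype_matrix()].
#' @param focal_pos Focal indel position.
#' @return Tibble `sample_id`, `genotype_class` (`TT` = homozygous
#'   no-insertion, `Tt`, `tt` = homozygous insertion).
#' @export
focal_genotype_classes <- function(gm, focal_pos) {
  i <- which(gm$sites$pos == focal_pos)
  stopifnot(length(i) == 1)
  dose <- gm$allele1[i, ] + gm$allele2[i, ]
  tibble(
    sample_id = gm$sample_ids,
    genotype_class = c("TT", "Tt", "tt")[dose + 1L]
  )
}

#' Simulate genotype-dependent phenotypes
#'
#' Draws a trait value per sample as its genotype-class mean plus Gaussian
#' noise, emulating the observation that homozygous-insertion accessions have
#' markedly lower PA content than carriers of the functional allele.
#'
#' @param genotypes Tibble with columns `sample_id`, `genotype_class`
#'   (`TT`/`Tt`/`tt`).
#' @param effects Named vector of class means, default `c(tt = 2, Tt = 9,
#'   TT = 10)` mg/g.
#' @param noise_sd Gaussian noise SD, default 1.5; 0 gives exact class means.
#' @param seed Optional seed for a standalone reproducible draw.
#' @return Tibble `sample_id`, `genotype_class`, `trait_value`.
#' @export
simulate_phenotypes <- function(genotypes, effects = c(tt = 2, Tt = 9, TT = 10),
                                noise_sd = 1.5, seed = NULL) {
  draw <- function() {
    mu <- unname(effects[genotypes$genotype_class])
    tibble(
      sample_id = genotypes$sample_id,
      genotype_class = genotypes$genotype_class,
      trait_value = mu + rnorm(nrow(genotypes), 0, noise_sd)
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Write a synthetic study to disk
#'
#' Emits the full plain-text fixture bundle: reference FASTA, VCF v4.2, GFF3,
#' panel TSV, phenotype TSV, assay FASTA (both allele templates) and a truth
#' JSON. Deterministic: the same study object always produces byte-identical
#' files.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "reference.fa"),
    vcf = file.path(dir, "genotypes.vcf"),
    gff = file.path(dir, "genes.gff3"),
    panel = file.path(dir, "panel.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    assay = file.path(dir, "assay_alleles.fa"),
    truth = file.path(dir, "truth.json")
  )
  ref <- synthetic_reference(study)
  writeLines(c(">chr1", substring(ref, seq(1, nchar(ref), 70),
                                  pmin(nchar(ref), seq(70, nchar(ref) + 69, 70)))),
             paths[["fasta"]])
  write_vcf(study$genotypes, paths[["vcf"]])
  write_gff(study$genes, paths[["gff"]])
  write_panel(study$panel, paths[["panel"]])
  write.table(study$phenotypes, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(c(
    ">no_insertion_allele", study$assay$templates[["no_insertion"]],
    ">insertion_allele", study$assay$templates[["insertion"]]
  ), paths[["assay"]])
  truth <- study$truth
  truth$window_pi <- as.data.frame(truth$window_pi)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# deterministic reference sequence consistent with the emitted site table:
# REF bases are embedded at their positions, and the TSD is planted so it
# ends at the focal insertion point
synthetic_reference <- function(study) {
  cfg <- study$config
  bases <- c("A", "C", "G", "T")
  ref <- withr::with_seed(
    1L, bases[sample.int(4, cfg$chrom_length, replace = TRUE)])
  sites <- study$genotypes$sites
  ref[sites$pos] <- substr(sites$ref, 1, 1)
  tsd <- strsplit(cfg$tsd, "")[[1]]
  fp <- study$truth$focal_pos
  ref[(fp - length(tsd) + 1):fp] <- tsd
  paste(ref, collapse = "")
}
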