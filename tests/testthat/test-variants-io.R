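write_lines_vcf <- function(body_lines, samples = c("s1", "s2"), path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

test_that("read_vcf handles empty input and sorts unsorted sites", {
  gm <- read_vcf(write_lines_vcf(character(0)))
  expect_equal(nrow(gm$sites), 0)
  expect_equal(gm$sample_ids, c("s1", "s2"))

  path <- write_lines_vcf(c(
    "chr1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1\t1/1",
    "chr1\t50\t.\tG\tC\t.\t.\t.\tGT\t0/0\t./."
  ))
  gm <- read_vcf(path)
  expect_equal(gm$sites$pos, c(50L, 100L))
  expect_true(is.na(gm$allele1[1, 2]))          # missing call preserved
  expect_equal(unname(gm$allele2[2, 2]), 1L)
  expect_equal(unname(gm$chrom_lengths["chr1"]), 100000)
})

test_that("read_vcf keeps multi-allelic sites with integer allele codes", {
  path <- write_lines_vcf("chr1\t10\t.\tA\tT,G\t.\t.\t.\tGT\t1/2\t0/2")
  gm <- read_vcf(path)
  expect_equal(gm$sites$alt[[1]], c("T", "G"))
  expect_equal(gm$allele2[1, ], c(s1 = 2L, s2 = 2L))
})

test_that("read_vcf reports malformed genotypes and panel mismatches", {
  path <- write_lines_vcf("chr1\t10\t.\tA\tT\t.\t.\t.\tGT\t0/x\t0/0")
  expect_error(read_vcf(path), "malformed genotype.*record 1")

  ok <- write_lines_vcf("chr1\t10\t.\tA\tT\t.\t.\t.\tGT\t0/1\t0/0")
  panel <- tibble::tibble(sample_id = c("s1", "ghost"), pool = "wild",
                          taxon = NA_character_)
  expect_error(read_vcf(ok, panel), "panel-mismatch.*ghost")
})

test_that("simulated study VCF round-trips through write_vcf/read_vcf", {
  st <- simulate_domestication(small_sim_config(), seed = 11)
  path <- tempfile(fileext = ".vcf")
  write_vcf(st$genotypes, path)
  back <- read_vcf(path, st$panel)
  expect_identical(back$sites$pos, st$genotypes$sites$pos)
  expect_identical(back$sites$ref, st$genotypes$sites$ref)
  expect_identical(back$sites$alt, st$genotypes$sites$alt)
  expect_identical(unname(back$allele1), unname(st$genotypes$allele1))
  expect_identical(unname(back$allele2), unname(st$genotypes$allele2))
  expect_equal(back$chrom_lengths, st$genotypes$chrom_lengths)
})

test_that("site filters implement the strict missingness and MAF rules", {
  # 20 diploids: hand-constructed counts per site
  n <- 20
  mk_row <- function(g) paste0(g)
  ok_site <- rep("0/1", n)                       # MAF 0.5
  miss_site <- c(rep("./.", 5), rep("0/1", 15))  # 25% missing > 20%
  rare_site <- c("0/1", rep("0/0", 19))          # MAF 1/40 = 0.025 < 0.05
  edge_site <- c("0/1", "0/1", rep("0/0", 18))   # MAF 2/40 = 0.05, retained
  gone_site <- rep("./.", n)                     # all missing
  calls <- rbind(ok_site, miss_site, rare_site, edge_site, gone_site)
  gm <- build_gm(calls, pos = c(100, 200, 300, 400, 500))

  res <- apply_variant_filters(gm)
  expect_equal(nrow(res$genotypes$sites), 2)
  expect_setequal(res$genotypes$sites$pos, c(100, 400))
  expect_setequal(res$report$reason, c("missingness", "low_maf", "all_missing"))
  expect_equal(res$report$reason[res$report$pos == 500], "all_missing")

  # surviving genotype values are untouched
  expect_identical(res$genotypes$allele1[1, ], gm$allele1[1, ])

  # idempotent
  res2 <- apply_variant_filters(res$genotypes)
  expect_equal(nrow(res2$report), 0)
  expect_identical(res2$genotypes$sites, res$genotypes$sites)
})

test_that("a clean matrix passes the filters unchanged", {
  gm <- build_gm(rbind(rep("0/1", 8), rep("0/1", 8)), pos = c(10, 20))
  res <- apply_variant_filters(gm)
  expect_equal(nrow(res$report), 0)
  expect_identical(res$genotypes$sites, gm$sites)
})

test_that("read_gff returns only gene features with coordinates preserved", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t1099\t.\t+\t.\tID=g1;family=MYB",
    "chr1\tsrc\tmRNA\t100\t1099\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\texon\t100\t400\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\texon\t500\t1099\t.\t+\t.\tParent=g1.t1",
    "chr1\tsrc\tCDS\t100\t400\t.\t+\t0\tParent=g1.t1",
    "chr2\tsrc\tgene\t5000\t6000\t.\t-\t.\tID=g2",
    "chr2\tsrc\tmRNA\t5000\t6000\t.\t-\t.\tID=g2.t1;Parent=g2"
  ), path)
  genes <- read_gff(path)
  expect_equal(nrow(genes), 2)
  expect_equal(genes$gene_id, c("g1", "g2"))
  expect_equal(genes$end[1] - genes$start[1] + 1, 1000)
  expect_equal(genes$strand, c("+", "-"))
})

test_that("study GFF3 round-trips through write_gff/read_gff", {
  st <- simulate_domestication(small_sim_config(), seed = 3)
  path <- tempfile(fileext = ".gff3")
  write_gff(st$genes, path)
  back <- read_gff(path)
  expect_equal(back$gene_id, st$genes$gene_id)
  expect_equal(back$start, st$genes$start)
  expect_equal(back$end, st$genes$end)
})

test_that("panel files round-trip and pool lookup validates", {
  panel <- tibble::tibble(sample_id = c("a", "b", "c"),
                          pool = c("wild", "cultivated", "wild"),
                          taxon = c("sp1", NA, "sp2"))
  path <- tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(back$sample_id, panel$sample_id)
  expect_equal(back$pool, panel$pool)
  expect_equal(back$taxon, panel$taxon)
})
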