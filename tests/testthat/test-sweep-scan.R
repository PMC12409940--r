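test_that("window grid follows the anchored, no-partial-window convention", {
  w <- make_windows(c(chr1 = 100000), 50000, 5000)
  expect_equal(nrow(w), 11)
  expect_equal(c(w$start[1], w$end[1]), c(1, 50000))
  expect_equal(c(w$start[11], w$end[11]), c(50001, 100000))

  expect_equal(nrow(make_windows(c(chr1 = 50000), 50000, 5000)), 1)

  short <- make_windows(c(chr1 = 30000), 50000, 5000)
  expect_equal(nrow(short), 1)
  expect_equal(c(short$start, short$end), c(1, 30000))
})

test_that("window_pi matches the hand-derived multiplicity formula", {
  # 4 diploids, one site with 3 alt alleles among 8: h = 30/56
  gm1 <- build_gm(rbind(c("0/1", "0/1", "0/1", "0/0")), pos = 5000)
  p1 <- window_pi(gm1, gm1$sample_ids, "chr1", 1, 10000)
  expect_equal(p1, (30 / 56) / 10000, tolerance = 1e-12)
  expect_equal(p1, pi_bruteforce(gm1, gm1$sample_ids, "chr1", 1, 10000),
               tolerance = 1e-15)

  # second site with 4 alt alleles: h = 32/56
  gm2 <- build_gm(rbind(c("0/1", "0/1", "0/1", "0/0"),
                        c("0/1", "0/1", "1/1", "0/0")), pos = c(5000, 6000))
  p2 <- window_pi(gm2, gm2$sample_ids, "chr1", 1, 10000)
  expect_equal(p2, (30 / 56 + 32 / 56) / 10000, tolerance = 1e-12)

  # no variant sites in the window
  expect_equal(window_pi(gm2, gm2$sample_ids, "chr1", 20000, 30000), 0)
})

test_that("pi is invariant to sample order and ref/alt label swap", {
  calls <- rbind(c("0/1", "1/1", "0/0", "./.", "0/1"),
                 c("0/0", "0/1", "0/1", "1/1", "0/0"))
  gm <- build_gm(calls, pos = c(100, 900))
  base_pi <- window_pi(gm, gm$sample_ids, "chr1", 1, 1000)

  perm <- rev(gm$sample_ids)
  expect_equal(window_pi(gm, perm, "chr1", 1, 1000), base_pi)

  swap <- function(x) ifelse(x == "0/1", "1/0",
                        ifelse(x == "0/0", "1/1",
                          ifelse(x == "1/1", "0/0", x)))
  gm_sw <- build_gm(apply(calls, c(1, 2), swap), pos = c(100, 900))
  expect_equal(window_pi(gm_sw, gm_sw$sample_ids, "chr1", 1, 1000), base_pi)
})

test_that("window_pi equals the exhaustive pairwise oracle for small pools", {
  withr::with_seed(42, {
    for (rep in 1:10) {
      n_dip <- sample(2:6, 1)
      n_sites <- sample(1:6, 1)
      calls <- matrix(sample(c("0/0", "0/1", "1/1", "1/2", "./."),
                             n_dip * n_sites, replace = TRUE,
                             prob = c(0.3, 0.3, 0.2, 0.1, 0.1)),
                      n_sites, n_dip)
      gm <- build_gm(calls, pos = sort(sample.int(5000, n_sites)))
      expect_equal(window_pi(gm, gm$sample_ids, "chr1", 1, 5000),
                   pi_bruteforce(gm, gm$sample_ids, "chr1", 1, 5000),
                   tolerance = 1e-12)
    }
  })
})

test_that("ratio scan forms wild/cultivated ratios with undefined denominators flagged", {
  # wild polymorphic everywhere; cultivated monomorphic in the second window
  calls <- rbind(
    c("0/1", "0/1", "0/1", "0/1"),   # pos 1000   (both pools polymorphic)
    c("0/1", "0/1", "0/0", "0/0")    # pos 11000  (cultivated monomorphic)
  )
  gm <- build_gm(calls, pos = c(1000, 11000),
                 chrom_lengths = c(chr1 = 20000))
  panel <- tibble::tibble(sample_id = gm$sample_ids,
                          pool = c("wild", "wild", "cultivated", "cultivated"),
                          taxon = NA)
  scan <- pi_ratio_scan(gm, panel, window_size = 10000, step = 10000)
  expect_equal(scan$status, c("ok", "undefined_denominator"))
  h <- function(k) (16 - (k^2 + (4 - k)^2)) / (4 * 3)  # 4 alleles, k alt
  expect_equal(scan$ratio[1], h(2) / h(2))
  expect_true(is.na(scan$ratio[2]))

  # pure arithmetic contract
  fake <- tibble::tibble(chrom = "chr1", start = 1, end = 10,
                         pi_wild = 2e-4, pi_cult = 5e-5)
  expect_equal(fake$pi_wild / fake$pi_cult, 4)
})

test_that("sweep calling uses nearest-rank quantile with strict exceedance", {
  starts <- seq(1, by = 100000, length.out = 100)
  scan <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 49999,
                         ratio = as.numeric(1:100), status = "ok")
  calls <- call_sweeps(scan, top_fraction = 0.05)
  expect_equal(calls$threshold, 95)
  expect_equal(sum(calls$windows$called), 5)
  expect_equal(nrow(calls$intervals), 5)
  expect_setequal(calls$windows$ratio[calls$windows$called], 96:100)

  # all ratios equal: threshold equals the value, nothing exceeds strictly
  flat <- dplyr::mutate(scan, ratio = 2)
  flat_calls <- call_sweeps(flat)
  expect_equal(flat_calls$threshold, 2)
  expect_equal(sum(flat_calls$windows$called), 0)
})

test_that("overlapping and abutting called windows merge into maximal intervals", {
  scan <- tibble::tibble(
    chrom = "chr1",
    start = c(1, 5001, 200001, seq(400001, by = 50000, length.out = 37)),
    end = c(50000, 55000, 250000, seq(450000, by = 50000, length.out = 37)),
    ratio = c(100, 99, 98, 40 - seq_len(37)),
    status = "ok"
  )
  calls <- call_sweeps(scan, top_fraction = 0.075)  # top 3 of 40
  expect_equal(sum(calls$windows$called), 3)
  expect_equal(nrow(calls$intervals), 2)
  merged <- calls$intervals[calls$intervals$start == 1, ]
  expect_equal(c(merged$start, merged$end), c(1, 55000))
  expect_equal(merged$n_windows_merged, 2)
  expect_equal(merged$peak_ratio, 100)
})

test_that("for distinct ratios exactly floor(top_fraction * N) windows are called", {
  withr::with_seed(7, {
    for (N in c(20, 41, 100, 137)) {
      starts <- seq(1, by = 100000, length.out = N)
      scan <- tibble::tibble(chrom = "chr1", start = starts,
                             end = starts + 49999,
                             ratio = sample(seq(0.1, 50, length.out = N)),
                             status = "ok")
      calls <- call_sweeps(scan, top_fraction = 0.05)
      expect_equal(sum(calls$windows$called), floor(0.05 * N))
    }
  })
})

test_that("gene-overlap boundary is inclusive and uses the interval union", {
  one <- tibble::tibble(chrom = "chr1", start = 1000, end = 1099,
                        peak_ratio = 5)
  g <- tibble::tibble(gene_id = "g", chrom = "chr1", start = 1000, end = 1999,
                      strand = "+", attributes = "")
  expect_equal(genes_in_sweeps(one, g, 0.10)$overlap_fraction, 0.10)  # inclusive

  g99 <- dplyr::mutate(one, end = 1098)
  expect_equal(nrow(genes_in_sweeps(g99, g, 0.10)), 0)                # 99 bp

  # union across two merged intervals: 60 + 50 bp of a 1000-bp gene
  two <- tibble::tibble(chrom = "chr1", start = c(1000, 1500),
                        end = c(1059, 1549), peak_ratio = c(9, 7))
  hit <- genes_in_sweeps(two, g, 0.10)
  expect_equal(hit$overlap_bp, 110)
  expect_equal(hit$overlap_fraction, 0.11)
  expect_equal(hit$peak_ratio, 9)
})
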