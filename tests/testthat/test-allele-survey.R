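test_that("detect_insertion recovers position, length and target-site duplication", {
  tsd <- "TTCCTAGT"
  te <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 403,
                                         replace = TRUE), collapse = ""))
  ref <- paste0("AAA", tsd, "GGGACGTACGTAAC")
  ins_allele <- paste0("AAA", tsd, te, tsd, "GGGACGTACGTAAC")
  d <- detect_insertion(ref, ins_allele)
  expect_equal(d$length, 411)
  expect_equal(d$tsd, tsd)
  expect_equal(d$tsd_length, 8)
  expect_equal(d$position, 3 + nchar(tsd))
  expect_identical(apply_insertion(ref, d), ins_allele)  # round trip
})

test_that("detect_insertion handles 1-bp insertions and rejects non-insertions", {
  d <- detect_insertion("ACGT", "ACGGT")
  expect_equal(d$length, 1)
  expect_equal(d$tsd, "G")
  expect_equal(d$tsd_length, 1)

  expect_error(detect_insertion("ACGT", "ACGT"), "no insertion")
  expect_error(detect_insertion("ACGT", "AGGTT"), "unsupported-difference")
  expect_error(detect_insertion("ACGTACGT", "AXCGTACGTA"),
               "unsupported-difference")
})

test_that("insertion coding consequences are classified by translation", {
  cds <- "ATGAAACCCGGGTAA"  # M K P G *
  ins9 <- detect_insertion(cds, paste0(substr(cds, 1, 6), "AAATAAGGG",
                                       substr(cds, 7, nchar(cds))))
  eff <- classify_insertion_effect(cds, ins9, "CDS")
  expect_equal(eff$classification, "premature_stop")
  expect_equal(eff$truncated_protein_length, 3L)  # M K K before the new stop

  ins4 <- detect_insertion(cds, paste0(substr(cds, 1, 6), "ACCA",
                                       substr(cds, 7, nchar(cds))))
  expect_equal(classify_insertion_effect(cds, ins4, "CDS")$classification,
               "frameshift")

  in_frame <- detect_insertion(cds, paste0(substr(cds, 1, 6), "AAACCCGGG",
                                           substr(cds, 7, nchar(cds))))
  expect_equal(classify_insertion_effect(cds, in_frame, "CDS")$classification,
               "in_frame_no_stop")

  pear <- diagnostic_assay_fixture("pear")
  d57 <- detect_insertion(pear$templates[["no_insertion"]],
                          pear$templates[["insertion"]])
  expect_equal(d57$length, 57)
  expect_equal(classify_insertion_effect("ATGTAA", d57, "promoter")$classification,
               "regulatory")
})

test_that("in-silico PCR reproduces the diagnostic amplicon geometry", {
  apple <- diagnostic_assay_fixture("apple")
  expect_equal(insilico_pcr(apple$templates[["no_insertion"]], apple$assay), 244L)
  expect_equal(insilico_pcr(apple$templates[["insertion"]], apple$assay), 655L)

  pear <- diagnostic_assay_fixture("pear")
  expect_equal(insilico_pcr(pear$templates[["no_insertion"]], pear$assay), 550L)
  expect_equal(insilico_pcr(pear$templates[["insertion"]], pear$assay), 607L)

  # exact-match policy: one mismatched base kills the amplicon
  bad_fwd <- apple$assay$forward_primer
  substr(bad_fwd, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                                   substr(bad_fwd, 5, 5))[1]
  expect_error(
    insilico_pcr(apple$templates[["no_insertion"]], forward = bad_fwd,
                 reverse = apple$assay$reverse_primer),
    "no-amplicon"
  )
})

test_that("amplicon-size genotyping covers all diploid configurations", {
  fx <- diagnostic_assay_fixture("apple")
  short <- fx$templates[["no_insertion"]]
  long <- fx$templates[["insertion"]]
  expect_equal(genotype_by_amplicons(c(short, short), fx$assay), "hom_no_insertion")
  expect_equal(genotype_by_amplicons(c(long, long), fx$assay), "hom_insertion")
  expect_equal(genotype_by_amplicons(c(short, long), fx$assay), "heterozygous")
  expect_equal(genotype_by_amplicons(c(long, short), fx$assay), "heterozygous")

  dropout <- sub(fx$assay$forward_primer, "", short, fixed = TRUE)
  expect_equal(genotype_by_amplicons(c(short, dropout), fx$assay), "failed")
})

test_that("allele frequency table reproduces hand-counted fractions and totals", {
  rec <- aft_record("sp", 1, 4, 359)
  expect_equal(rec$p_ins, 722 / 728)
  expect_equal(rec$p_ins_percent, 99.18)

  zero <- aft_record("sp", 10, 0, 0)
  expect_equal(zero$p_ins_percent, 0)

  # per-sample call interface: failed calls drop out of n
  calls <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    taxon = c("a", "a", "a", "b", "b", "b"),
    call = c("hom_insertion", "heterozygous", "failed",
             "hom_no_insertion", "hom_no_insertion", "heterozygous")
  )
  tab <- allele_frequency_table(calls, group = "taxon")
  expect_equal(tab$n[tab$group == "a"], 2)
  expect_equal(tab$p_ins[tab$group == "a"], 3 / 4)
  expect_equal(tab$p_ins[tab$group == "b"], 1 / 6)

  # conservation: the Total row is the count-weighted aggregate
  tot <- tab[tab$group == "Total", ]
  expect_equal(tot$n, sum(tab$n[tab$group != "Total"]))
  expect_equal(
    tot$p_ins,
    sum(2 * tab$n_hom_ins[tab$group != "Total"] +
          tab$n_het[tab$group != "Total"]) / (2 * tot$n)
  )
})

test_that("the three Fst estimators behave at the degenerate corners", {
  # identical frequencies: Nei Gst is exactly 0, the corrected estimators
  # vanish up to their O(1/n) sampling terms
  a <- aft_record("a", 300, 400, 300)
  b <- aft_record("b", 300, 400, 300)
  fst <- pairwise_fst(a, b)
  expect_equal(fst$fst[fst$estimator == "nei_gst"], 0)
  expect_lt(abs(fst$fst[fst$estimator == "hudson"]), 3e-3)
  expect_lt(abs(fst$fst[fst$estimator == "weir_cockerham"]), 3e-3)

  # fixed difference
  fix <- pairwise_fst(aft_record("a", 0, 0, 50), aft_record("b", 50, 0, 0))
  expect_equal(fix$fst[fix$estimator == "hudson"], 1)
  expect_equal(fix$fst[fix$estimator == "nei_gst"], 1)

  # both monomorphic for the same allele: undefined
  mono <- pairwise_fst(aft_record("a", 50, 0, 0), aft_record("b", 20, 0, 0))
  expect_true(all(is.na(mono$fst)))
})

test_that("Fst estimators match independently coded formula oracles", {
  # the published-table genotype counts for cultivated vs wild apple
  a <- aft_record("domestica", 1, 4, 359)
  b <- aft_record("wild", 39, 51, 5)
  fst <- pairwise_fst(a, b)
  p1 <- 722 / 728; p2 <- 61 / 190
  expect_equal(fst$fst[fst$estimator == "hudson"],
               hudson_fst_oracle(p1, 728, p2, 190), tolerance = 1e-12)
  expect_equal(fst$fst[fst$estimator == "nei_gst"],
               nei_gst_oracle(p1, p2), tolerance = 1e-12)
  expect_equal(fst$fst[fst$estimator == "weir_cockerham"],
               wc_theta_oracle(c(364, 95), c(p1, p2), c(4 / 364, 51 / 95)),
               tolerance = 1e-12)
})

test_that("estimators agree on balanced large samples at equal true frequency", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      p <- runif(1, 0.2, 0.8)
      draw <- function(g) {
        n <- 800
        geno <- rbinom(n, 2, p)
        aft_record(g, sum(geno == 0), sum(geno == 1), sum(geno == 2))
      }
      fst <- pairwise_fst(draw("x"), draw("y"))
      expect_lt(max(fst$fst) - min(fst$fst), 0.02)
    }
  })
})

test_that("the two assay amplicons always differ by the insertion length", {
  for (sp in c("apple", "pear")) {
    fx <- diagnostic_assay_fixture(sp)
    expect_equal(
      insilico_pcr(fx$templates[["insertion"]], fx$assay) -
        insilico_pcr(fx$templates[["no_insertion"]], fx$assay),
      fx$assay$insertion_length
    )
  }
})
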