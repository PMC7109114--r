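test_that("interval deletion removes exactly the requested bases", {
  orf <- make_orf(240)
  expect_equal(nchar(orf), 720)
  del <- apply_interval_deletion(orf, 568, 581)
  expect_equal(nchar(del), 706)
  expect_equal(nchar(orf) - nchar(del), 14)

  expect_equal(apply_interval_deletion("ATGAAATTT", 4, 6), "ATGTTT")
  # single-base deletion
  s <- "ACGTACGT"
  expect_equal(nchar(apply_interval_deletion(s, 3, 3)), 7)
  # deletion then re-insertion restores the original
  cut <- substr(s, 3, 5)
  rest <- apply_interval_deletion(s, 3, 5)
  expect_identical(paste0(substr(rest, 1, 2), cut, substr(rest, 3, 5)), s)
  expect_error(apply_interval_deletion(s, 0, 2), "outside")
  expect_error(apply_interval_deletion(s, 5, 9), "outside")
})

test_that("ORF translation stops at the first stop codon", {
  expect_identical(translate_orf("ATGTAA")$protein, "M")
  tr <- translate_orf("ATGAAATAG")
  expect_identical(tr$protein, "MK")
  expect_true(tr$has_stop)
  # a 720-nt ORF whose only stop is the final codon encodes 239 aa
  orf <- make_orf(240)
  tr2 <- translate_orf(orf)
  expect_equal(tr2$n_aa, 239)
  expect_true(tr2$has_stop)
  # trailing partial codons are ignored; short input is flagged empty
  expect_identical(translate_orf("ATGAA")$protein, "M")
  expect_equal(translate_orf("AT")$n_aa, 0)
})

test_that("a 14-nt deletion causes frameshift, truncation and domain loss", {
  # pick a seed whose random ORF frameshifts to an early stop
  orf <- NULL
  for (s in 1:50) {
    cand <- make_orf(240, seed = s)
    eff <- effect_report_deletion(cand, 568, 581)
    if (eff$consequence == "frameshift+early stop") { orf <- cand; break }
  }
  expect_false(is.null(orf))
  domains <- tibble::tibble(
    name = c("Bbox1", "VP", "NLS"),
    start_aa = c(10, 200, 225), end_aa = c(50, 210, 235)
  )
  eff <- effect_report_deletion(orf, 568, 581, domains)
  expect_identical(eff$consequence, "frameshift+early stop")
  expect_equal(eff$wt_aa, 239)
  expect_lt(eff$mut_aa, eff$wt_aa)
  # frame breaks inside codon 190: 189 complete codons are shared
  expect_equal(eff$shared_prefix_aa, 189)
  # C-terminal domains beyond the shared prefix are reported lost
  expect_identical(eff$lost_domains, "VP,NLS")
})

test_that("shared prefix equals floor((del_start - 1) / 3) on random ORFs", {
  withr::local_seed(5)
  checked <- 0
  for (i in 1:60) {
    orf <- make_orf(sample(40:120, 1), seed = sample(1e6, 1))
    n <- nchar(orf)
    start <- sample(10:(n - 20), 1)
    len <- sample(c(1, 2, 4, 5, 7, 14), 1)
    eff <- effect_report_deletion(orf, start, start + len - 1)
    wt_p <- translate_orf(orf)$protein
    mut_p <- translate_orf(apply_interval_deletion(orf, start,
                                                   start + len - 1))$protein
    # oracle: direct character comparison of the two translations
    cmp <- 0
    while (cmp < min(nchar(wt_p), nchar(mut_p)) &&
           substr(wt_p, cmp + 1, cmp + 1) == substr(mut_p, cmp + 1, cmp + 1)) {
      cmp <- cmp + 1
    }
    expect_equal(eff$shared_prefix_aa, cmp)
    # the law holds whenever the first frameshifted codon changed
    if (cmp == (start - 1) %/% 3) checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("in-frame, missense and synonymous changes are distinguished", {
  orf <- "ATGAAACCCGGGTTTTAA"  # M K P G F *
  # 3-nt deletion on a codon boundary: in-frame, one aa shorter
  eff <- effect_report_deletion(orf, 4, 6)
  expect_identical(eff$consequence, "in-frame indel")
  expect_equal(eff$mut_aa, eff$wt_aa - 1)
  # AAA -> AAG keeps lysine
  expect_identical(effect_report(orf, 6, "A", "G")$consequence, "synonymous")
  # CCC -> CAC: proline to histidine
  expect_identical(effect_report(orf, 8, "C", "A")$consequence, "missense")
  # removing the stop codon in frame
  expect_identical(effect_report_deletion(orf, 16, 18)$consequence,
                   "stop lost")
  expect_error(effect_report(orf, 6, "G", "T"), "mismatch")
})

test_that("clone haplotypes split into full and del types with percentages", {
  withr::local_seed(9)
  wt <- make_orf(80)
  del_start <- 100; del_end <- 113
  del <- apply_interval_deletion(wt, del_start, del_end)
  reads <- c(rep(wt, 29), rep(del, 39))
  res <- classify_clone_haplotypes(reads, wt, del_start, del_end)
  expect_equal(res$n[res$type == "full"], 29)
  expect_equal(res$n[res$type == "del"], 39)
  expect_equal(res$pct[res$type == "full"], 42.65)
  expect_equal(res$pct[res$type == "del"], 57.35)

  res2 <- classify_clone_haplotypes(rep(wt, 5), wt, del_start, del_end)
  expect_equal(res2$pct[res2$type == "full"], 100)
  expect_equal(res2$n[res2$type == "del"], 0)

  res3 <- classify_clone_haplotypes(c(wt, del, del), wt, del_start, del_end)
  expect_equal(res3$pct[res3$type == "full"], 33.33)

  # a read not spanning the locus is unclassified and out of the denominator
  short <- substr(wt, 1, 50)
  res4 <- classify_clone_haplotypes(c(wt, del, short), wt, del_start, del_end)
  expect_equal(res4$n[res4$type == "unclassified"], 1)
  expect_equal(res4$pct[res4$type == "full"], 50)

  # amplicon length difference equals the deletion length
  expect_equal(nchar(wt) - nchar(del), del_end - del_start + 1)
})

test_that("FPKM is the printed ratio", {
  expect_equal(fpkm(10, 1, 1), 10)
  expect_equal(fpkm(0, 3, 2), 0)
  expect_equal(fpkm(100, 2, 0.5), 100)
  expect_warning(out <- fpkm(10, 0, 1), "Zero denominator")
  expect_true(is.na(out))
})
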