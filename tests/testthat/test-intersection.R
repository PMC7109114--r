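demo_regions <- function(chrom = "Chr4", lo = 8e6, hi = 20e6) {
  tibble::tibble(chrom = chrom, start = lo, end = hi,
                 span_start = lo, span_end = hi)
}

test_that("differential variants require differing callable genotypes", {
  v <- read_variants(extdata("candidate_table.vcf"), table_roles())
  v <- call_genotypes(v)
  reg <- demo_regions()

  d <- differential_variants(v, "red_parent", "original", reg)
  # het in the mutant (10,5) vs hom in the original (14,0) -> retained
  expect_true(18388296 %in% d$pos)
  # rows where the original has no read support are excluded, counted
  expect_gte(attr(d, "n_uncallable"), 4)

  # identical genotypes in both roles -> dropped
  both_hom <- make_variant(chrom = "Chr4", pos = 9e6, ads = list(
    red_parent = c(20, 0), original = c(15, 0), green_parent = c(12, 0),
    red_pool = c(10, 0), green_pool = c(11, 0)
  ))
  expect_equal(nrow(differential_variants(both_hom, "red_parent", "original",
                                          demo_regions())), 0)

  # outside all candidate regions -> dropped
  d2 <- differential_variants(v, "red_parent", "original",
                              demo_regions(lo = 1, hi = 2e6))
  expect_equal(nrow(d2), 0)
})

test_that("the mutual set is contained in each differential set", {
  v <- call_genotypes(read_variants(extdata("candidate_table.vcf"),
                                    table_roles()))
  reg <- demo_regions()
  key <- function(x) paste(x$chrom, x$pos)
  m <- mutual_differential_variants(v, regions = reg)
  d1 <- differential_variants(v, "red_parent", "original", reg)
  d2 <- differential_variants(v, "red_parent", "green_parent", reg)
  expect_true(all(key(m) %in% key(d1)))
  expect_true(all(key(m) %in% key(d2)))
})

test_that("the five-role pattern selects the het/het/hom/hom/hom signature", {
  v <- call_genotypes(read_variants(extdata("candidate_table.vcf"),
                                    table_roles()))
  hit <- select_by_pattern(v)
  # 10,5 / 14,0 / 20,0 / 39,0 / 24,9 matches the pattern
  expect_true(18388296 %in% hit$pos)
  counts <- attr(hit, "class_counts")
  expect_true(counts[["InDel"]] >= 1)

  # a heterozygous green pool breaks the pattern
  bad <- make_variant(chrom = "Chr4", pos = 9e6, ads = list(
    red_parent = c(10, 5), original = c(14, 0), green_parent = c(20, 0),
    red_pool = c(24, 9), green_pool = c(20, 10)
  ))
  expect_equal(nrow(select_by_pattern(bad)), 0)

  # hom means hom for the allele shared with the green parent:
  # an original hom for the *alternate* allele must not match
  bad2 <- make_variant(chrom = "Chr4", pos = 9.1e6, ads = list(
    red_parent = c(10, 5), original = c(0, 14), green_parent = c(20, 0),
    red_pool = c(24, 9), green_pool = c(39, 0)
  ))
  expect_equal(nrow(select_by_pattern(bad2)), 0)
})

test_that("the simulated causal locus matches the pattern in most replicates", {
  hits <- vapply(1:10, function(s) {
    sim <- small_sim(seed = s)
    causal_pos <- sim$truth$pos[sim$truth$causal]
    hit <- select_by_pattern(call_genotypes(sim$variants))
    causal_pos %in% hit$pos
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("coding consequences are classified and ranked", {
  gm <- tibble::tibble(
    gene_id = "g1", chrom = "Chr4", strand = "+",
    start = 10000L, end = 12000L,
    exons = list(tibble::tibble(start = c(10000L, 11000L),
                                end = c(10500L, 12000L))),
    cds = list(tibble::tibble(start = c(10000L, 11000L),
                              end = c(10500L, 12000L)))
  )
  mk <- function(pos, ref, alt) {
    make_variant(chrom = "Chr4", pos = pos, ref = ref, alt = alt,
                 ads = list(red_pool = c(10, 10), green_pool = c(10, 0)))
  }
  v <- dplyr::bind_rows(
    mk(10100L, "AGCAGCTGAAGTTCC", "A"),   # 14-nt deletion in CDS: frameshift
    mk(10200L, "ATTT", "A"),              # 3-nt deletion in CDS: in-frame
    mk(10700L, "A", "G"),                 # between exons: intron
    mk(9500L, "T", "C"),                  # 500 bp 5' of the gene: upstream
    mk(12400L, "G", "A"),                 # past the gene end: downstream
    mk(30000L, "C", "A")                  # far away: intergenic
  )
  ranked <- prioritize_cds(v, gm)
  expect_identical(
    ranked$effect_class[match(c(10100, 10200, 10700, 9500, 12400, 30000),
                              ranked$pos)],
    c("Frame shift", "In-frame indel", "Intron", "Upstream", "Downstream",
      "Intergenic")
  )
  expect_identical(ranked$pos[1], 10100L)
  expect_identical(ranked$effect_rank[match(10100, ranked$pos)], 1L)
  expect_identical(ranked$effect_rank[match(10200, ranked$pos)], 2L)
  expect_true(all(ranked$effect_rank[match(c(9500, 12400, 30000),
                                           ranked$pos)] == 3L))
  # classification honours the configurable distance
  far <- prioritize_cds(v, gm, updown_dist = 100)
  expect_identical(far$effect_class[match(9500, far$pos)], "Intergenic")
})

test_that("the planted frameshift outranks decoys in every clean replicate", {
  for (s in 1:5) {
    sim <- small_sim(seed = s)
    causal_pos <- sim$truth$pos[sim$truth$causal]
    hq <- filter_high_quality(sim$variants)
    expect_gte(nrow(hq), 50)
    ranked <- prioritize_cds(call_genotypes(hq), sim$gene_models)
    expect_identical(ranked$pos[1], causal_pos)
    expect_identical(ranked$effect_class[1], "Frame shift")
    expect_identical(ranked$effect_gene[1], "causal_gene")
  }
})
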