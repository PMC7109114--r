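brute_force_windows <- function(positions, values, chrom_length,
                                window, step, min_variants = 1) {
  offs <- seq(0, chrom_length - 1, by = step)
  offs <- offs[offs < chrom_length]
  vapply(offs, function(s) {
    inside <- positions > s & positions <= s + window
    if (sum(inside) < min_variants) NA_real_ else mean(values[inside])
  }, numeric(1))
}

test_that("window fitting is the within-window arithmetic mean", {
  # a single variant: every window covering it carries its value
  tr <- fit_windows(5e5, 0.7, chrom_length = 2e6,
                    window = 2e5, step = 5e4)
  covered <- tr$offset < 5e5 & tr$offset + 2e5 >= 5e5
  expect_true(all(tr$fitted[covered] == 0.7))
  expect_true(all(is.na(tr$fitted[!covered])))

  # two variants in one window: their mean
  tr2 <- fit_windows(c(100, 200), c(0.2, 0.4), chrom_length = 1000,
                     window = 1000, step = 500)
  expect_equal(tr2$fitted[1], 0.3)

  # constant values give a constant track wherever defined
  pos <- seq(1e4, 1e6, by = 1e4)
  tr3 <- fit_windows(pos, rep(0.5, length(pos)), chrom_length = 1e6,
                     window = 1e5, step = 1e4)
  expect_true(all(tr3$fitted[!is.na(tr3$fitted)] == 0.5))
})

test_that("window fitting matches a brute-force recomputation", {
  withr::local_seed(7)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    len <- sample(5e4:2e5, 1)
    pos <- sort(sample(seq_len(len), n))
    val <- runif(n)
    window <- sample(c(1e4, 2e4, 5e4), 1)
    step <- sample(c(2e3, 5e3, 1e4), 1)
    minv <- sample(1:3, 1)
    tr <- fit_windows(pos, val, len, window, step, minv)
    expect_equal(tr$fitted,
                 brute_force_windows(pos, val, len, window, step, minv),
                 tolerance = 1e-12)
  }
})

test_that("median+3SD and quantile thresholds match hand computation", {
  mk_track <- function(fitted) {
    structure(
      tibble::tibble(
        chrom = "c", offset = seq(0, by = 1e4, length.out = length(fitted)),
        win_start = 1, win_end = 1, midpoint = 1,
        n_variants = 1L, fitted = fitted
      ),
      class = c("bsa_track", "tbl_df", "tbl", "data.frame"),
      window = 2e6, step = 1e4, statistic = "ed5"
    )
  }
  # constant track: SD = 0 -> threshold = the constant
  expect_equal(threshold_median_3sd(mk_track(rep(0.4, 10)))$value, 0.4)
  # {0,0,0,1}: median 0, sample SD 0.5 -> 1.5
  expect_equal(threshold_median_3sd(mk_track(c(0, 0, 0, 1)))$value, 1.5)
  # symmetric delta track: median 0
  tr <- mk_track(c(-0.3, 0, 0.3))
  expect_equal(threshold_median_3sd(tr)$value, 0 + 3 * sd(c(-0.3, 0, 0.3)))
  expect_error(threshold_median_3sd(mk_track(c(0.1, NA, NA))), "2 defined")

  # quantile: type-7 linear interpolation; 1..100 at 0.99 -> 99.01
  expect_equal(threshold_quantile(mk_track(1:100), 0.99)$value, 99.01)
  expect_equal(threshold_quantile(mk_track(rep(0.2, 5)), 0.7)$value, 0.2)
  x <- c(0.1, 0.4, 0.15, 0.33, 0.8)
  expect_equal(threshold_quantile(mk_track(x), 0.5)$value, median(x))
  expect_error(threshold_quantile(mk_track(1:10), 1.2), "level")
})

test_that("null-simulation envelope shrinks with depth and is seed-stable", {
  thr <- threshold_null_simulation(depths = c(10, 40, 100, 1000),
                                   level = 0.90, n_sims = 1e4, seed = 1)
  env <- thr$params$envelope
  expect_true(all(diff(env$bound) < 0))
  expect_lt(env$bound[env$depth == 1000], 0.05)
  # Monte-Carlo self-consistency across seeds at depth 40
  b1 <- threshold_null_simulation(depths = 40, level = 0.90, n_sims = 1e5,
                                  seed = 1)$value
  b2 <- threshold_null_simulation(depths = 40, level = 0.90, n_sims = 1e5,
                                  seed = 99)$value
  expect_lt(abs(b1 - b2), 0.02)
  expect_warning(threshold_null_simulation(depths = 40, n_sims = 50), "noisy")
})

# synthetic track whose above-threshold windows span the anchor interval
# [start_offset, end_offset]; all other windows sit at the baseline
span_track <- function(start_offset, end_offset, chrom_length,
                       chrom = "Chr4", window = 2e6, step = 1e4,
                       high = 1, low = 0) {
  offs <- seq(0, by = step, length.out = ceiling(chrom_length / step))
  offs <- offs[offs < chrom_length]
  fitted <- ifelse(offs >= start_offset & offs <= end_offset, high, low)
  structure(
    tibble::tibble(
      chrom = chrom, offset = offs, win_start = offs + 1,
      win_end = pmin(offs + window, chrom_length),
      midpoint = offs + window / 2, n_variants = 1L, fitted = fitted
    ),
    class = c("bsa_track", "tbl_df", "tbl", "data.frame"),
    window = window, step = step, statistic = "ed5"
  )
}

test_that("region sizes reproduce published start/end arithmetic", {
  # 8,840,000-22,590,000 -> 13.75 Mb
  tr <- span_track(8840000, 22590000, 30e6)
  reg <- call_regions(tr, 0.5)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 8840000)
  expect_equal(reg$end, 22590000)
  expect_equal(reg$size_mb, 13.75)

  # 7,450,000-22,580,000 -> 15.13 Mb
  reg2 <- call_regions(span_track(7450000, 22580000, 30e6), 0.5)
  expect_equal(reg2$size_mb, 15.13)

  # 6,930,000-11,000,000 -> 4.07 Mb
  reg3 <- call_regions(span_track(6930000, 11000000, 30e6), 0.5)
  expect_equal(reg3$size_mb, 4.07)

  # single qualifying window: start = end, size 0
  reg4 <- call_regions(span_track(10470000, 10470000, 30e6), 0.5)
  expect_equal(reg4$start, reg4$end)
  expect_equal(reg4$size_mb, 0)

  # nothing above threshold: empty table
  expect_equal(nrow(call_regions(span_track(1e6, 2e6, 30e6, high = 0.1), 0.5)),
               0)
})

test_that("regions are exactly the above-threshold window runs", {
  withr::local_seed(11)
  offs <- seq(0, 99e4, by = 1e4)
  fitted <- runif(length(offs))
  fitted[sample(length(offs), 10)] <- NA
  tr <- structure(
    tibble::tibble(
      chrom = "c", offset = offs, win_start = offs + 1,
      win_end = offs + 2e6, midpoint = offs + 1e6,
      n_variants = 1L, fitted = fitted
    ),
    class = c("bsa_track", "tbl_df", "tbl", "data.frame"),
    window = 2e6, step = 1e4, statistic = "ed5"
  )
  thr <- 0.6
  reg <- call_regions(tr, thr)
  # every offset in a region is above threshold, and vice versa
  in_region <- rep(FALSE, length(offs))
  for (i in seq_len(nrow(reg))) {
    in_region <- in_region |
      (offs >= reg$start[i] & offs <= reg$end[i])
  }
  # offset 0 is reported as 1
  if (nrow(reg) && any(reg$start == 1)) {
    in_region <- in_region | offs == 0
  }
  above <- !is.na(fitted) & fitted >= thr
  expect_identical(in_region, above)
  # ties at the threshold count as above
  tr$fitted[3] <- thr
  reg_tie <- call_regions(tr, thr)
  expect_true(any(reg_tie$start <= offs[3] & reg_tie$end >= offs[3]))
  # runs broken by an undefined window are not merged
  expect_true(all(diff(sort(reg$start)) > 0))
})

test_that("region gene counts use the physical window span", {
  gm <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "Chr4",
    start = c(9e6, 12.3e6, 25e6), end = c(9.1e6, 12.4e6, 25.1e6)
  )
  tr <- span_track(8840000, 10000000, 30e6)
  reg <- call_regions(tr, 0.5, gene_models = gm)
  # span runs to the last window's end (10,000,000 + 2 Mb)
  expect_equal(reg$span_end, 12e6)
  expect_equal(reg$n_genes, 1L)
})
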