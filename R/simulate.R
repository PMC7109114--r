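#' Configuration for the F1 pooled-sequencing simulator
#'
#' Describes a cross of a heterozygous dominant (red) mutant parent by a
#' homozygous (green) parent, with 1:1 phenotype segregation in the F1 and
#' two phenotype-selected pools. Defaults emulate the study design the
#' package targets: one 30 Mb chromosome, markers every 10 kb, 50-plant
#' pools at ~50x mean depth, and a causal 14-nt frameshift deletion inside
#' a generated gene at 18,388,296 bp.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param marker_spacing Distance between simulated markers (bp).
#' @param causal_chrom,causal_pos Location of the causal locus.
#' @param map_rate Recombination map rate in cM/Mb (default 2.5).
#' @param pool_size Plants per pool (default 50; both pools equal).
#' @param mean_pool_depth Mean sequencing depth per pool (Poisson mean,
#'   default 50).
#' @param mean_parent_depth Mean depth of parent/original samples
#'   (default 30).
#' @param error_rate Per-read probability that a read reports the other
#'   allele of the biallelic site (default 0.005).
#' @param frac_noninformative Fraction of markers homozygous in both
#'   parents (decoys removed by the same-genotype filter; default 0.15).
#' @param frac_het_green Fraction of markers heterozygous in the green
#'   parent only (default 0.30). Their pool frequencies are independent of
#'   the causal locus, so the survivors among them form the unlinked
#'   background of the scan — the marker mix emulates a highly
#'   heterozygous outbred species, where both parents segregate variants
#'   genome-wide.
#' @param frac_het_both Fraction of markers heterozygous in both parents
#'   for the same alleles (default 0.10); these are not parent-informative
#'   for the SNP index and are counted as excluded.
#' @param frac_indel Fraction of markers emitted as 1-bp InDels rather
#'   than SNPs (default 0.17: detected SNPs outnumber InDels more than
#'   fivefold in this kind of resequencing data).
#' @param frac_original_diff Fraction of red-parent-heterozygous markers
#'   at which the original cultivar is homozygous reference, creating
#'   mutant-vs-original differential decoys (default 0.05).
#' @param n_multiallelic,n_lowdepth Counts of planted filter decoys:
#'   triallelic records and records with pool depth forced below 4.
#' @param decoy_gene_spacing Spacing of single-exon decoy genes along each
#'   chromosome (bp), so upstream/downstream/intergenic classes occur.
#' @param seed RNG seed used by [simulate_pools()]; `NULL` leaves the RNG
#'   state alone.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(chrom_lengths = c(Chr4 = 30e6),
                         marker_spacing = 1e4,
                         causal_chrom = "Chr4",
                         causal_pos = 18388296,
                         map_rate = 2.5,
                         pool_size = 50,
                         mean_pool_depth = 50,
                         mean_parent_depth = 30,
                         error_rate = 0.005,
                         frac_noninformative = 0.15,
                         frac_het_green = 0.30,
                         frac_het_both = 0.10,
                         frac_indel = 0.17,
                         frac_original_diff = 0.05,
                         n_multiallelic = 5,
                         n_lowdepth = 5,
                         decoy_gene_spacing = 5e5,
                         seed = NULL) {
  stopifnot(
    all(chrom_lengths >= 1), marker_spacing >= 1,
    causal_chrom %in% names(chrom_lengths),
    causal_pos >= 1, causal_pos <= chrom_lengths[[causal_chrom]],
    pool_size >= 1, mean_pool_depth > 0, mean_parent_depth > 0,
    error_rate >= 0, error_rate < 0.25,
    frac_noninformative >= 0, frac_het_green >= 0, frac_het_both >= 0,
    frac_noninformative + frac_het_green + frac_het_both < 0.95
  )
  structure(
    list(
      chrom_lengths = chrom_lengths, marker_spacing = marker_spacing,
      causal_chrom = causal_chrom, causal_pos = causal_pos,
      map_rate = map_rate, pool_size = pool_size,
      mean_pool_depth = mean_pool_depth,
      mean_parent_depth = mean_parent_depth,
      error_rate = error_rate,
      frac_noninformative = frac_noninformative,
      frac_het_green = frac_het_green,
      frac_het_both = frac_het_both,
      frac_indel = frac_indel,
      frac_original_diff = frac_original_diff,
      n_multiallelic = n_multiallelic, n_lowdepth = n_lowdepth,
      decoy_gene_spacing = decoy_gene_spacing,
      seed = seed
    ),
    class = "cross_config"
  )
}

#' Haldane recombination fraction
#'
#' `r = (1 - exp(-2d)) / 2` with `d` the map distance in Morgans derived
#' from physical distance and a constant map rate. No interference.
#'
#' @param distance_bp Physical distance in bp (vectorised, >= 0).
#' @param map_rate Map rate in cM/Mb.
#' @return Recombination fraction in \[0, 0.5).
#' @examples
#' recombination_fraction(10e6, 2.5)  # 0.19673
#' @export
recombination_fraction <- function(distance_bp, map_rate = 2.5) {
  stopifnot(all(distance_bp >= 0))
  d_morgan <- distance_bp / 1e6 * map_rate / 100
  (1 - exp(-2 * d_morgan)) / 2
}

# random CDS of n_codons coding codons (no internal stop) plus a final stop
random_orf <- function(n_codons) {
  codons <- apply(
    matrix(sample(c("A", "C", "G", "T"), 3 * (n_codons - 2), replace = TRUE),
           ncol = 3), 1, paste, collapse = ""
  )
  codons[codons %in% c("TAA", "TAG", "TGA")] <- "AAA"
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# causal gene: 3 exons, 720 bp CDS, deletion interval 568..581 of the CDS
# placed so the genomic deletion start anchors at config$causal_pos - 1.
build_causal_gene <- function(config) {
  cds_len <- 720L
  exon_cds <- list(c(1L, 240L), c(241L, 540L), c(541L, 720L))
  introns <- c(1200L, 968L)
  # genomic offset of CDS position 568 from gene start: 240+i1+300+i2+27
  off_568 <- 240L + introns[1] + 300L + introns[2] + 27L
  gene_start <- as.integer(config$causal_pos - off_568)
  ex_starts <- c(
    gene_start,
    gene_start + 240L + introns[1],
    gene_start + 240L + introns[1] + 300L + introns[2]
  )
  ex_ends <- ex_starts + c(240L, 300L, 180L) - 1L
  # CDS with a frameshift-visible deletion: resample until the 14-nt
  # deletion at 568..581 truncates the protein at an early stop
  for (i in 1:200) {
    cds <- random_orf(cds_len %/% 3L)
    eff <- effect_report_deletion(cds, 568L, 581L)
    if (eff$consequence == "frameshift+early stop" &&
        eff$mut_aa < eff$wt_aa) break
  }
  list(
    model = tibble(
      gene_id = "causal_gene", chrom = config$causal_chrom,
      strand = "+", start = gene_start, end = ex_ends[3],
      exons = list(tibble(start = ex_starts, end = ex_ends)),
      cds = list(tibble(start = ex_starts, end = ex_ends)),
      cds_len = cds_len, incomplete_orf = FALSE
    ),
    cds = cds,
    del_cds = c(568L, 581L),
    # genomic coordinates of the VCF record (anchor base before deletion)
    anchor_pos = as.integer(config$causal_pos - 1L)
  )
}

build_decoy_genes <- function(config) {
  out <- list()
  for (ch in names(config$chrom_lengths)) {
    starts <- seq(2.5e5, config$chrom_lengths[[ch]] - 2000,
                  by = config$decoy_gene_spacing)
    if (!length(starts)) next
    out[[ch]] <- tibble(
      gene_id = sprintf("%s_g%03d", ch, seq_along(starts)),
      chrom = ch, strand = "+",
      start = as.integer(starts), end = as.integer(starts + 1499),
      exons = map(starts, function(s) tibble(start = as.integer(s),
                                             end = as.integer(s + 1499))),
      cds = map(starts, function(s) tibble(start = as.integer(s),
                                           end = as.integer(s + 1499))),
      cds_len = 1500L, incomplete_orf = FALSE
    )
  }
  bind_rows(out)
}

#' Simulate pooled-sequencing variant calls for a dominant-mutant F1 cross
#'
#' For every marker a phase is drawn (the red parent's alternate allele in
#' coupling or repulsion with the causal mutation), each pool's allele
#' frequency is the mean over the `2 * pool_size` chromosomes of
#' phenotype-selected plants (Mendelian transmission with Haldane
#' recombination to the causal locus; pool membership by causal genotype,
#' perfect penetrance), read depths are Poisson and allele reads binomial
#' with a symmetric error rate. The causal variant itself is a 14-nt
#' deletion inside the CDS of a generated three-exon gene. Planted decoys
#' exercise each quality filter: triallelic records, low-depth records,
#' and markers homozygous in both parents.
#'
#' @param config A [cross_config()].
#' @return A list of class `bsa_simulation`:
#'   * `variants` — variant table in the [read_variants()] schema,
#'   * `truth` — per-marker tibble (`chrom`, `pos`, `r`, `phase`,
#'     `f_red_expected`, `f_green_expected`, `causal`, `marker_type`),
#'   * `gene_models` — causal + decoy gene models,
#'   * `cds` — named character vector of CDS sequences (the causal gene),
#'   * `config` — the configuration used.
#' Deterministic for a fixed `config$seed`.
#' @export
simulate_pools <- function(config = cross_config()) {
  stopifnot(inherits(config, "cross_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  e <- config$error_rate
  npl <- config$pool_size
  causal <- build_causal_gene(config)

  rows <- list()
  truths <- list()
  nt <- c("A", "C", "G", "T")

  for (ch in names(config$chrom_lengths)) {
    len <- config$chrom_lengths[[ch]]
    pos <- seq(config$marker_spacing, len, by = config$marker_spacing)
    # keep the causal record's surroundings clean
    pos <- pos[abs(pos - ifelse(ch == config$causal_chrom,
                                config$causal_pos, -1)) > 30]
    m <- length(pos)
    r <- if (ch == config$causal_chrom) {
      recombination_fraction(abs(pos - config$causal_pos), config$map_rate)
    } else {
      rep(0.5, m)
    }
    marker_type <- sample(
      c("hom_both", "het_green", "het_both", "het_red"), m, replace = TRUE,
      prob = c(config$frac_noninformative, config$frac_het_green,
               config$frac_het_both,
               1 - config$frac_noninformative - config$frac_het_green -
                 config$frac_het_both)
    )
    red_is_het <- marker_type %in% c("het_red", "het_both")
    green_is_het <- marker_type %in% c("het_green", "het_both")
    original_diff <- marker_type == "het_red" &
      runif(m) < config$frac_original_diff
    phase <- ifelse(runif(m) < 0.5, "coupling", "repulsion")
    phase[!red_is_het] <- NA

    # transmission probability of the alternate allele from the red parent;
    # the green parent transmits its alt (when het) independently of the
    # causal locus, so that half contributes Binom(npl, 1/2)
    p_alt_red_pool <- ifelse(red_is_het,
                             ifelse(phase == "coupling", 1 - r, r), 0)
    p_alt_green_pool <- ifelse(red_is_het,
                               ifelse(phase == "coupling", r, 1 - r), 0)

    # realised pool allele frequencies: alt copies among 2*npl chromosomes
    draw_f <- function(p_red_side) {
      (rbinom(m, npl, p_red_side) +
         ifelse(green_is_het, rbinom(m, npl, 0.5), 0L)) / (2 * npl)
    }
    f_red <- draw_f(p_alt_red_pool)
    f_green <- draw_f(p_alt_green_pool)

    # alleles
    is_indel <- runif(m) < config$frac_indel
    ref <- sample(nt, m, replace = TRUE)
    alt <- map_chr(ref, function(rf) sample(setdiff(nt, rf), 1))
    ins <- runif(m) < 0.5
    ref[is_indel & !ins] <- paste0(ref[is_indel & !ins], alt[is_indel & !ins])
    alt[is_indel & ins] <- paste0(ref[is_indel & ins], alt[is_indel & ins])

    read_ad <- function(f, depth_mean) {
      d <- rpois(m, depth_mean)
      a <- rbinom(m, d, f * (1 - e) + (1 - f) * e)
      cbind(d - a, a)
    }
    ad_red_pool <- read_ad(f_red, config$mean_pool_depth)
    ad_green_pool <- read_ad(f_green, config$mean_pool_depth)
    ad_red_parent <- read_ad(ifelse(red_is_het, 0.5, 0),
                             config$mean_parent_depth)
    # the original cultivar shares the red parent's genome apart from the
    # causal mutation and a small divergence fraction
    ad_original <- read_ad(ifelse(red_is_het & !original_diff, 0.5, 0),
                           config$mean_parent_depth)
    ad_green_parent <- read_ad(ifelse(green_is_het, 0.5, 0),
                               config$mean_parent_depth)

    marker_type[original_diff] <- "het_red_original_diff"

    rows[[ch]] <- tibble(
      chrom = ch, pos = as.integer(pos), ref = ref, alt = alt,
      alts = as.list(alt), n_alt = 1L,
      variant_class = classify_variant(ref, as.list(alt)),
      ad_red_parent = asplit_ad(ad_red_parent),
      ad_green_parent = asplit_ad(ad_green_parent),
      ad_original = asplit_ad(ad_original),
      ad_red_pool = asplit_ad(ad_red_pool),
      ad_green_pool = asplit_ad(ad_green_pool)
    )
    green_half <- ifelse(green_is_het, 0.25, 0)
    truths[[ch]] <- tibble(
      chrom = ch, pos = as.integer(pos), r = r, phase = phase,
      f_red_expected = p_alt_red_pool / 2 + green_half,
      f_green_expected = p_alt_green_pool / 2 + green_half,
      causal = FALSE, marker_type = marker_type
    )
  }

  variants <- bind_rows(rows)
  truth <- bind_rows(truths)

  # planted filter decoys: triallelic and low-depth records
  n_var <- nrow(variants)
  decoy_idx <- sample(which(truth$marker_type == "het_red"),
                      config$n_multiallelic + config$n_lowdepth)
  tri <- head(decoy_idx, config$n_multiallelic)
  for (i in tri) {
    rf <- substr(variants$ref[i], 1, 1)
    two <- sample(setdiff(nt, rf), 2)
    variants$ref[i] <- rf
    variants$alts[[i]] <- two
    variants$alt[i] <- paste(two, collapse = ",")
    variants$n_alt[i] <- 2L
    variants$variant_class[i] <- classify_variant(rf, list(two))
    d <- sum(variants$ad_red_pool[[i]])
    variants$ad_red_pool[[i]] <- c(d - 4L, 2L, 2L)
    variants$ad_green_pool[[i]] <- c(sum(variants$ad_green_pool[[i]]), 0L, 0L)
    for (role in c("red_parent", "green_parent", "original")) {
      variants[[ad_col(role)]][[i]] <-
        c(variants[[ad_col(role)]][[i]], 0L)
    }
    truth$marker_type[i] <- "decoy_multiallelic"
  }
  low <- tail(decoy_idx, config$n_lowdepth)
  for (i in low) {
    variants$ad_red_pool[[i]] <- c(2L, 1L)
    truth$marker_type[i] <- "decoy_lowdepth"
  }

  # causal variant: 14-nt deletion, red side het, green side hom full
  del <- causal$del_cds
  del_seq <- substr(causal$cds, del[1], del[2])
  anchor <- substr(causal$cds, del[1] - 1L, del[1] - 1L)
  causal_ref <- paste0(anchor, del_seq)
  f_red_c <- 0.5  # every red-pool plant is del/full
  pois1 <- function(mu) max(rpois(1, mu), 4L)
  mk_ad <- function(f, mu) {
    d <- pois1(mu)
    a <- rbinom(1, d, f * (1 - e) + (1 - f) * e)
    c(as.integer(d - a), as.integer(a))
  }
  causal_row <- tibble(
    chrom = config$causal_chrom, pos = causal$anchor_pos,
    ref = causal_ref, alt = anchor, alts = list(anchor), n_alt = 1L,
    variant_class = "InDel",
    ad_red_parent = list(mk_ad(0.5, config$mean_parent_depth)),
    ad_green_parent = list(mk_ad(0, config$mean_parent_depth)),
    ad_original = list(mk_ad(0, config$mean_parent_depth)),
    ad_red_pool = list(mk_ad(f_red_c, config$mean_pool_depth)),
    ad_green_pool = list(mk_ad(0, config$mean_pool_depth))
  )
  causal_truth <- tibble(
    chrom = config$causal_chrom, pos = causal$anchor_pos, r = 0,
    phase = "coupling", f_red_expected = 0.5, f_green_expected = 0,
    causal = TRUE, marker_type = "causal"
  )
  variants <- arrange(bind_rows(variants, causal_row),
                      .data$chrom, .data$pos)
  truth <- arrange(bind_rows(truth, causal_truth), .data$chrom, .data$pos)

  gene_models <- bind_rows(causal$model, build_decoy_genes(config))
  gene_models <- arrange(gene_models, .data$chrom, .data$start)

  structure(
    list(
      variants = variants, truth = truth, gene_models = gene_models,
      cds = c(causal_gene = causal$cds), config = config
    ),
    class = "bsa_simulation"
  )
}

asplit_ad <- function(mat) {
  lapply(seq_len(nrow(mat)), function(i) as.integer(mat[i, ]))
}

#' Write simulator ground truth as TSV
#'
#' @param truth The `truth` tibble of a [simulate_pools()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' Read simulator ground truth
#' @param path Path written by [write_truth()].
#' @return The truth tibble.
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    phase = readr::col_character(),
                    causal = readr::col_logical(),
                    marker_type = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Monte-Carlo mean ED of a marker at a given recombination fraction
#'
#' Simulates the per-variant ED statistic for a marker linked to the
#' causal locus at recombination fraction `r` in coupling phase. With
#' `pool_size = NULL` reads are drawn at the Mendelian-expected pool
#' frequencies `(1-r)/2` and `r/2`, so sequencing depth is the only noise
#' source and the mean converges to the closed form `(1-2r)/sqrt(2)` as
#' depth grows. Supplying a `pool_size` additionally resamples the finite
#' pool composition each replicate, which adds a folded-noise floor at
#' large `r`.
#'
#' @param r Recombination fraction in \[0, 0.5\].
#' @param depth Read depth per pool.
#' @param n_reps Number of replicate markers.
#' @param pool_size Plants per pool, or `NULL` for expected-frequency
#'   sampling.
#' @param error_rate Symmetric per-read error rate.
#' @return Numeric vector of `n_reps` ED values.
#' @export
simulate_marker_ed <- function(r, depth, n_reps, pool_size = NULL,
                               error_rate = 0) {
  stopifnot(r >= 0, r <= 0.5, depth > 0, n_reps >= 1)
  f_red <- rep((1 - r) / 2, n_reps)
  f_green <- rep(r / 2, n_reps)
  if (!is.null(pool_size)) {
    f_red <- rbinom(n_reps, pool_size, 1 - r) / (2 * pool_size)
    f_green <- rbinom(n_reps, pool_size, r) / (2 * pool_size)
  }
  e <- error_rate
  obs_red <- rbinom(n_reps, depth, f_red * (1 - e) + (1 - f_red) * e) / depth
  obs_green <- rbinom(n_reps, depth, f_green * (1 - e) + (1 - f_green) * e) /
    depth
  sqrt(2) * abs(obs_red - obs_green)
}
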