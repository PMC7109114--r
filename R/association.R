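#' Per-pool allele frequency vectors for one variant
#'
#' For SNPs the frequencies are laid out on the four nucleotide axes
#' (A, G, C, T; unused nucleotides 0); for InDels on \{ref, alt\} axes.
#' A pool with zero total depth yields `NULL` (the variant is excluded from
#' the scan with a reason, not an error).
#'
#' @param ref,alt Reference and (single) alternate allele.
#' @param ad_red,ad_green Integer depth vectors `c(ref, alt)` for the red
#'   and green pools (`NULL` = no read support).
#' @return A list with named numeric vectors `red` and `green` (each
#'   summing to 1), or `NULL` entries where the pool has no depth.
#' @examples
#' pool_frequencies("A", "T", ad_red = c(24, 9), ad_green = c(39, 0))
#' @export
pool_frequencies <- function(ref, alt, ad_red, ad_green) {
  one <- function(ad) {
    if (is.null(ad) || sum(ad) == 0) return(NULL)
    f <- ad[1:2] / sum(ad[1:2])
    if (nchar(ref) == 1L && nchar(alt) == 1L && ref != alt) {
      axes <- c(A = 0, G = 0, C = 0, T = 0)
      axes[ref] <- f[1]
      axes[alt] <- f[2]
      axes
    } else {
      c(ref = f[1], alt = f[2])
    }
  }
  list(red = one(ad_red), green = one(ad_green))
}

#' Euclidean distance between two pools' allele frequencies
#'
#' The per-variant ED statistic: the Euclidean norm of the difference
#' between the red and green pools' frequency vectors. For a biallelic site
#' this equals `sqrt(2) * |f_alt(red) - f_alt(green)|`, with maximum
#' `sqrt(2)` at complete separation.
#'
#' @param freq_red,freq_green Named frequency vectors on matching axes
#'   (see [pool_frequencies()]).
#' @return The ED value (>= 0).
#' @examples
#' ed_value(c(A = 0, T = 1), c(A = 1, T = 0))  # sqrt(2)
#' @export
ed_value <- function(freq_red, freq_green) {
  if (!identical(names(freq_red), names(freq_green))) {
    abort("Frequency vectors are on different axes.")
  }
  sqrt(sum((freq_red - freq_green)^2))
}

#' ED association value (fifth power)
#'
#' Raising ED to the fifth power suppresses background noise while keeping
#' the statistic strictly monotone in ED.
#'
#' @param ed ED value(s), >= 0.
#' @return `ed^5`.
#' @export
ed_association_value <- function(ed) {
  stopifnot(all(ed >= 0))
  ed^5
}

#' SNP index of one pool
#'
#' The fraction of reads carrying the female-parent-informative allele:
#' `M / (M + P)`, where `M` and `P` are the read depths of the female- and
#' male-parent alleles in that pool.
#'
#' @param m,p Non-negative depths of the female (`M`) and male (`P`)
#'   alleles (vectorised).
#' @return Index in \[0, 1\]; `NA` where `m + p == 0` (undefined for that
#'   variant).
#' @examples
#' snp_index(39, 0)  # 1
#' snp_index(24, 9)  # 0.7273
#' @export
snp_index <- function(m, p) {
  stopifnot(all(m >= 0), all(p >= 0))
  ifelse(m + p > 0, m / (m + p), NA_real_)
}

#' Delta SNP index
#'
#' `delta = index(aa) - index(ab)` where `aa` is the recessive (green) pool
#' and `ab` the dominant (red) pool. Values near 1 indicate strong
#' association with the dominant phenotype.
#'
#' @param index_aa,index_ab SNP indices of the green and red pools.
#' @return Delta in \[-1, 1\] (`NA` if either index is undefined).
#' @export
delta_snp_index <- function(index_aa, index_ab) {
  index_aa - index_ab
}

#' Which pool alleles are the female (M) and male (P) alleles
#'
#' The female allele is the allele carried homozygously (or uniquely) by
#' the female parent's called genotype; the male allele is the male
#' parent's other allele. Variants where the parents' genotypes do not
#' differ, or where the assignment is ambiguous (e.g. both parents
#' heterozygous for the same alleles), are not parent-informative.
#'
#' @param gt_female,gt_male Canonical genotype strings of the two parents
#'   (see [call_genotype()]).
#' @return Integer vector `c(female, male)` of 0-based allele indices, or
#'   `NULL` when the variant is not informative.
#' @keywords internal
parental_alleles <- function(gt_female, gt_male) {
  af <- gt_alleles(gt_female)
  am <- gt_alleles(gt_male)
  if (length(af) == 0 || length(am) == 0) return(NULL)
  if (identical(sort(af), sort(am))) return(NULL)  # same genotype (or same het)
  fem <- if (length(af) == 1) af else {
    u <- setdiff(af, am)
    if (length(u) == 1) u else return(NULL)
  }
  male <- if (length(am) == 1) {
    if (am == fem) return(NULL) else am
  } else {
    u <- setdiff(am, fem)
    if (length(u) == 1) u else return(NULL)
  }
  c(female = fem, male = male)
}

#' Add per-variant association statistics to a variant table
#'
#' Computes, per biallelic variant, the ED statistic and its fifth power
#' (`ed`, `ed5`) and/or the SNP-index family (`snp_index_aa` for the green
#' pool, `snp_index_ab` for the red pool, `delta_snp_index`). Variants that
#' cannot be scored (zero pool depth; non-informative parents for the SNP
#' index) get `NA` values and a reason in `stat_excluded`.
#'
#' @param variants A variant table; `gt_<role>` columns are added if absent
#'   (needed for the SNP index).
#' @param statistics Any of `"ED5"`, `"dSNPindex"`.
#' @param roles A [sample_roles()] map; only `female_role` is consulted, to
#'   orient the SNP index.
#' @return `variants` with statistic columns added.
#' @export
add_association_stats <- function(variants,
                                  statistics = c("ED5", "dSNPindex"),
                                  roles = default_roles()) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (!all(c(gt_col("red_parent")) %in% names(variants))) {
    variants <- call_genotypes(variants)
  }
  n <- nrow(variants)
  excl <- rep(NA_character_, n)
  ad_red <- variants$ad_red_pool
  ad_green <- variants$ad_green_pool
  dp <- function(ad) if (is.null(ad)) 0 else sum(ad)

  if ("ED5" %in% statistics) {
    ed <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (variants$n_alt[i] > 1L) { excl[i] <- "multiallelic"; next }
      if (dp(ad_red[[i]]) == 0 || dp(ad_green[[i]]) == 0) {
        excl[i] <- "zero_pool_depth"; next
      }
      fq <- pool_frequencies(variants$ref[i], variants$alts[[i]][1],
                             ad_red[[i]], ad_green[[i]])
      ed[i] <- ed_value(fq$red, fq$green)
    }
    variants$ed <- ed
    variants$ed5 <- ed_association_value(ifelse(is.na(ed), 0, ed))
    variants$ed5[is.na(ed)] <- NA_real_
  }

  if ("dSNPindex" %in% statistics) {
    female <- roles$female_role
    male <- roles$male_role
    idx_aa <- rep(NA_real_, n)
    idx_ab <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (variants$n_alt[i] > 1L) { excl[i] <- "multiallelic"; next }
      pa <- parental_alleles(variants[[gt_col(female)]][i],
                             variants[[gt_col(male)]][i])
      if (is.null(pa)) {
        if (is.na(excl[i])) excl[i] <- "not_parent_informative"
        next
      }
      depth_at <- function(ad, allele) {
        if (is.null(ad) || allele + 1L > length(ad)) 0 else ad[allele + 1L]
      }
      m_aa <- depth_at(ad_green[[i]], pa[["female"]])
      p_aa <- depth_at(ad_green[[i]], pa[["male"]])
      m_ab <- depth_at(ad_red[[i]], pa[["female"]])
      p_ab <- depth_at(ad_red[[i]], pa[["male"]])
      idx_aa[i] <- snp_index(m_aa, p_aa)
      idx_ab[i] <- snp_index(m_ab, p_ab)
      if ((is.na(idx_aa[i]) || is.na(idx_ab[i])) && is.na(excl[i])) {
        excl[i] <- "zero_informative_depth"
      }
    }
    variants$snp_index_aa <- idx_aa
    variants$snp_index_ab <- idx_ab
    variants$delta_snp_index <- delta_snp_index(idx_aa, idx_ab)
  }

  variants$stat_excluded <- excl
  variants
}
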