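#' Call a genotype from allele depths
#'
#' An allele is counted as *present* when its read count reaches
#' `min_allele_reads` and its within-sample frequency reaches
#' `min_allele_frac`. One present allele gives a homozygous call, two a
#' heterozygous call; more than two is `ambiguous`; none (or absent depths)
#' is `missing`. Depths of `NULL` — "no read support" — always give
#' `missing`: the absent state is distinct from observed zeros.
#'
#' @param ad Integer vector of allele depths (ref first), or `NULL` for no
#'   read support.
#' @param min_allele_reads Minimum reads for an allele to count as present
#'   (default 2).
#' @param min_allele_frac Minimum within-sample allele frequency (default
#'   0.10).
#' @return A list with `state` (one of `"hom_ref"`, `"hom_alt"`, `"het"`,
#'   `"ambiguous"`, `"missing"`), `alleles` (0-based indices of present
#'   alleles; 0 = ref), and `gt` (canonical string such as `"0"`, `"0/1"`,
#'   or `NA` for missing).
#' @examples
#' call_genotype(c(14, 0))$state  # hom_ref
#' call_genotype(c(10, 5))$state  # het
#' call_genotype(c(1, 0))$state   # missing (below min_allele_reads)
#' @export
call_genotype <- function(ad, min_allele_reads = 2, min_allele_frac = 0.10) {
  if (is.null(ad) || length(ad) == 0 || all(is.na(ad))) {
    return(list(state = "missing", alleles = integer(0), gt = NA_character_))
  }
  total <- sum(ad)
  present <- which(ad >= min_allele_reads &
                     (total > 0 & ad / total >= min_allele_frac)) - 1L
  state <- if (length(present) == 0) "missing"
  else if (length(present) == 1) {
    if (present == 0L) "hom_ref" else "hom_alt"
  } else if (length(present) == 2) "het" else "ambiguous"
  gt <- if (length(present) == 0) NA_character_
  else paste(present, collapse = "/")
  list(state = state, alleles = present, gt = gt)
}

#' Add per-role genotype calls to a variant table
#'
#' Applies [call_genotype()] to each role's allele-depth column and stores
#' the canonical genotype string in `gt_<role>` (`NA` = missing/uncallable).
#'
#' @param variants A variant table.
#' @inheritParams call_genotype
#' @return `variants` with five `gt_<role>` character columns added.
#' @export
call_genotypes <- function(variants, min_allele_reads = 2,
                           min_allele_frac = 0.10) {
  for (role in role_names()) {
    variants[[gt_col(role)]] <- map_chr(
      variants[[ad_col(role)]],
      function(ad) call_genotype(ad, min_allele_reads, min_allele_frac)$gt
    )
  }
  variants
}

gt_alleles <- function(gt) {
  if (is.na(gt)) return(integer(0))
  as.integer(strsplit(gt, "/", fixed = TRUE)[[1]])
}

gt_state <- function(gt) {
  n <- lengths(strsplit(gt, "/", fixed = TRUE))
  n[is.na(gt)] <- 0L
  out <- rep("ambiguous", length(gt))
  out[n == 0] <- "missing"
  hom <- n == 1
  out[hom & gt == "0"] <- "hom_ref"
  out[hom & gt != "0"] <- "hom_alt"
  out[n == 2] <- "het"
  out
}
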