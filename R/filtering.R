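#' High-quality variant filter for pooled association
#'
#' Applies, in order, the four filters that define the high-quality variant
#' set of a two-pool bulked-segregant design:
#'
#' 1. **multiple_genotypes** — more than two segregating alleles at the site
#'    (i.e. more than one alternate allele); both association statistics
#'    assume biallelic sites.
#' 2. **low_depth** — total read depth below `min_depth` in either pool
#'    (`depth_scope = "pool"`, default) or in any of the five samples
#'    (`depth_scope = "sample"`). Absent depths count as zero here.
#' 3. **same_genotype** — called genotypes identical in the two pools, or
#'    either pool uncallable; such sites carry no contrast.
#' 4. **not_from_recessive_parent** — the recessive (green) pool carries an
#'    allele not present in the recessive parent's called genotype; under
#'    clean segregation every green-pool allele must come from the green
#'    parent, so these are artefact-prone sites.
#'
#' @param variants A variant table (see [read_variants()]).
#' @param min_depth Minimum pool (or sample) total depth (default 4, i.e.
#'   drop sites supported by fewer than four reads).
#' @param depth_scope `"pool"` or `"sample"`; see above.
#' @param recessive_pool,recessive_parent Role names of the recessive pool
#'   and the recessive parent (defaults `green_pool` / `green_parent`).
#' @param min_allele_reads,min_allele_frac Genotype-calling thresholds, see
#'   [call_genotype()].
#' @return The surviving variants (with `gt_<role>` columns added), with a
#'   telescoping stage report attached as attribute `"filter_report"`
#'   (retrieve with [filter_report()]) and per-variant fail reasons as
#'   attribute `"filter_reasons"`.
#' @examples
#' \dontrun{
#' hq <- filter_high_quality(variants)
#' filter_report(hq)
#' }
#' @export
filter_high_quality <- function(variants,
                                min_depth = 4,
                                depth_scope = c("pool", "sample"),
                                recessive_pool = "green_pool",
                                recessive_parent = "green_parent",
                                min_allele_reads = 2,
                                min_allele_frac = 0.10) {
  depth_scope <- match.arg(depth_scope)
  if (!recessive_pool %in% role_names() ||
      !recessive_parent %in% role_names()) {
    abort("Unknown recessive role.")
  }
  variants <- arrange(variants, .data$chrom, .data$pos)
  variants <- call_genotypes(variants, min_allele_reads, min_allele_frac)
  n0 <- nrow(variants)
  reasons <- rep(NA_character_, n0)
  alive <- rep(TRUE, n0)
  report <- tibble(
    stage = character(), n_in = integer(), n_removed = integer(),
    n_out = integer()
  )
  drop_stage <- function(stage, fail) {
    fail <- alive & fail
    report <<- bind_rows(report, tibble(
      stage = stage, n_in = sum(alive), n_removed = sum(fail),
      n_out = sum(alive) - sum(fail)
    ))
    reasons[fail] <<- stage
    alive[fail] <<- FALSE
  }

  # 1. multiple genotypes (>2 alleles)
  drop_stage("multiple_genotypes", variants$n_alt > 1L)

  # 2. depth below min_depth
  depth_of <- function(role) {
    map_int(variants[[ad_col(role)]], function(ad) {
      if (is.null(ad)) 0L else as.integer(sum(ad))
    })
  }
  scope_roles <- if (depth_scope == "pool") {
    c("red_pool", "green_pool")
  } else {
    role_names()
  }
  low <- Reduce(`|`, lapply(scope_roles, function(r) depth_of(r) < min_depth))
  drop_stage("low_depth", low)

  # 3. identical (or uncallable) pool genotypes
  gt_r <- variants$gt_red_pool
  gt_g <- variants$gt_green_pool
  same <- is.na(gt_r) | is.na(gt_g) | (gt_r == gt_g)
  drop_stage("same_genotype", same)

  # 4. recessive pool carries an allele absent from the recessive parent
  gt_rpool <- variants[[gt_col(recessive_pool)]]
  gt_rpar <- variants[[gt_col(recessive_parent)]]
  foreign <- map_lgl(seq_len(n0), function(i) {
    a_pool <- gt_alleles(gt_rpool[i])
    a_par <- gt_alleles(gt_rpar[i])
    length(a_par) == 0 || !all(a_pool %in% a_par)
  })
  drop_stage("not_from_recessive_parent", foreign)

  out <- variants[alive, , drop = FALSE]
  attr(out, "filter_report") <- report
  attr(out, "filter_reasons") <- tibble(
    chrom = variants$chrom, pos = variants$pos, reason = reasons
  )
  out
}

#' Retrieve the stage report of a filtered variant table
#'
#' @param x The result of [filter_high_quality()].
#' @return A tibble with columns `stage`, `n_in`, `n_removed`, `n_out`;
#'   counts telescope (each stage's `n_out` is the next stage's `n_in`).
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report")
  if (is.null(rep)) abort("No filter report attached; run filter_high_quality().")
  rep
}

#' Write a filter stage report as TSV
#' @param x The result of [filter_high_quality()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(x, path) {
  readr::write_tsv(filter_report(x), path)
  invisible(path)
}
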