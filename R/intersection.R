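#' Variants whose genotypes differ between two samples
#'
#' Restricts a variant table to the supplied candidate regions and keeps
#' the variants whose called genotypes differ between `role_a` and
#' `role_b`. Variants with an uncallable genotype in either role are
#' excluded and counted (attribute `"n_uncallable"`); variants outside all
#' regions are dropped first.
#'
#' @param variants A variant table (genotypes are called if absent).
#' @param role_a,role_b Role names to compare (e.g. the mutant parent vs
#'   the original cultivar it arose from).
#' @param regions A region tibble from [call_regions()], or `NULL` to use
#'   all variants.
#' @return The differential subset, with attribute `"n_uncallable"`.
#' @export
differential_variants <- function(variants, role_a = "red_parent",
                                  role_b = "original", regions = NULL) {
  if (!all(c(role_a, role_b) %in% role_names())) abort("Unknown role.")
  if (!gt_col(role_a) %in% names(variants)) {
    variants <- call_genotypes(variants)
  }
  if (!is.null(regions) && nrow(regions) > 0) {
    # membership is judged on the physical window span when present,
    # falling back to the printed anchor bounds
    r_start <- if ("span_start" %in% names(regions)) regions$span_start else regions$start
    r_end <- if ("span_end" %in% names(regions)) regions$span_end else regions$end
    inside <- map_lgl(seq_len(nrow(variants)), function(i) {
      any(regions$chrom == variants$chrom[i] &
            r_start <= variants$pos[i] &
            r_end >= variants$pos[i])
    })
    variants <- variants[inside, ]
  } else if (!is.null(regions)) {
    variants <- variants[0, ]
  }
  ga <- variants[[gt_col(role_a)]]
  gb <- variants[[gt_col(role_b)]]
  uncallable <- is.na(ga) | is.na(gb)
  out <- variants[!uncallable & ga != gb, ]
  attr(out, "n_uncallable") <- sum(uncallable)
  out
}

#' Mutually different variants (mutant vs original AND mutant vs parent)
#'
#' The intersection of the differential sets of the mutant against the
#' original cultivar and against the other (non-mutant) parent, inside the
#' candidate regions: the mutation of interest must distinguish the mutant
#' from both.
#'
#' @inheritParams differential_variants
#' @param mutant_role,original_role,other_parent_role Roles of the mutant
#'   parent, its original cultivar, and the other parent of the cross.
#' @return The mutual differential subset.
#' @export
mutual_differential_variants <- function(variants,
                                         mutant_role = "red_parent",
                                         original_role = "original",
                                         other_parent_role = "green_parent",
                                         regions = NULL) {
  a <- differential_variants(variants, mutant_role, original_role, regions)
  b <- differential_variants(variants, mutant_role, other_parent_role, regions)
  key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt)
  a[key(a) %in% key(b), ]
}

#' The five-role genotype pattern of a dominant de novo mutation
#'
#' @param red_parent,red_pool,green_parent,original,green_pool Required
#'   call per role: the mutant parent and the dominant pool heterozygous,
#'   the green parent, the original cultivar and the green pool homozygous
#'   for the shared (recessive) allele.
#' @return A named character vector of class `bsa_pattern`.
#' @export
genotype_pattern <- function(red_parent = "het", red_pool = "het",
                             green_parent = "hom", original = "hom",
                             green_pool = "hom") {
  states <- c(red_parent = red_parent, red_pool = red_pool,
              green_parent = green_parent, original = original,
              green_pool = green_pool)
  ok <- states %in% c("het", "hom")
  if (!all(ok)) abort("Pattern states must be 'het' or 'hom'.")
  structure(states, class = "bsa_pattern")
}

#' Select variants matching a genotype pattern
#'
#' Keeps variants whose five called genotypes match the pattern exactly.
#' "hom" means homozygous for the allele shared with the green parent (the
#' recessive allele), not merely any homozygote, and every "het" genotype
#' must carry that shared allele plus one other — the configuration of a
#' heterozygous dominant de novo mutation segregating 1:1.
#'
#' @param variants A variant table (genotypes are called if absent).
#' @param pattern A [genotype_pattern()].
#' @return The matching subset; the count by `variant_class` is attached as
#'   attribute `"class_counts"`.
#' @export
select_by_pattern <- function(variants, pattern = genotype_pattern()) {
  if (!gt_col("red_parent") %in% names(variants)) {
    variants <- call_genotypes(variants)
  }
  hom_roles <- names(pattern)[pattern == "hom"]
  het_roles <- names(pattern)[pattern == "het"]
  match_one <- function(i) {
    gp <- gt_alleles(variants$gt_green_parent[i])
    if (length(gp) != 1) return(FALSE)   # anchor: green parent must be hom
    shared <- gp
    for (r in hom_roles) {
      a <- gt_alleles(variants[[gt_col(r)]][i])
      if (length(a) != 1 || a != shared) return(FALSE)
    }
    for (r in het_roles) {
      a <- gt_alleles(variants[[gt_col(r)]][i])
      if (length(a) != 2 || !(shared %in% a)) return(FALSE)
    }
    TRUE
  }
  out <- variants[map_lgl(seq_len(nrow(variants)), match_one), ]
  attr(out, "class_counts") <- table(out$variant_class)
  out
}

#' Classify and rank variants by coding consequence
#'
#' Locates each variant relative to the gene models (`CDS`, `Intron`,
#' `Upstream`, `Downstream`, `Intergenic`; up/downstream within
#' `updown_dist` of the gene, strand-aware) and, within CDS, separates
#' frameshift InDels (length change not divisible by 3) from in-frame
#' changes. Ranking: CDS frameshift (1) > other CDS (2) > everything
#' else (3).
#'
#' @param variants A variant table.
#' @param gene_models A gene-model tibble (see [read_gene_models()]).
#' @param updown_dist Up/downstream classification distance in bp
#'   (default 5000).
#' @return `variants` with `effect_class`, `effect_gene`, `effect_rank`
#'   columns, sorted by rank (then position).
#' @export
prioritize_cds <- function(variants, gene_models, updown_dist = 5000) {
  n <- nrow(variants)
  eff <- character(n)
  gene <- rep(NA_character_, n)
  rank <- integer(n)
  for (i in seq_len(n)) {
    v_start <- variants$pos[i]
    v_end <- v_start + nchar(variants$ref[i]) - 1L
    gm <- gene_models[gene_models$chrom == variants$chrom[i], ]
    len_change <- abs(nchar(variants$ref[i]) -
                        max(nchar(variants$alts[[i]])))
    hit <- NULL
    class <- "Intergenic"
    # inside a gene?
    inside <- which(gm$start <= v_end & gm$end >= v_start)
    if (length(inside)) {
      g <- gm[inside[1], ]
      hit <- g$gene_id
      cd <- g$cds[[1]]
      in_cds <- any(cd$start <= v_end & cd$end >= v_start)
      if (in_cds) {
        class <- if (variants$variant_class[i] == "InDel" &&
                     len_change %% 3L != 0L) "Frame shift"
        else if (variants$variant_class[i] == "InDel") "In-frame indel"
        else "CDS"
      } else {
        class <- "Intron"
      }
    } else if (nrow(gm)) {
      # nearest gene within updown_dist, oriented by its strand
      d_up <- ifelse(gm$strand == "-", v_start - gm$end, gm$start - v_end)
      d_dn <- ifelse(gm$strand == "-", gm$start - v_end, v_start - gm$end)
      near_up <- which(d_up > 0 & d_up <= updown_dist)
      near_dn <- which(d_dn > 0 & d_dn <= updown_dist)
      if (length(near_up)) {
        j <- near_up[which.min(d_up[near_up])]
        class <- "Upstream"; hit <- gm$gene_id[j]
      } else if (length(near_dn)) {
        j <- near_dn[which.min(d_dn[near_dn])]
        class <- "Downstream"; hit <- gm$gene_id[j]
      }
    }
    eff[i] <- class
    gene[i] <- hit %||% NA_character_
    rank[i] <- if (class == "Frame shift") 1L
    else if (class %in% c("In-frame indel", "CDS")) 2L else 3L
  }
  variants$effect_class <- eff
  variants$effect_gene <- gene
  variants$effect_rank <- rank
  arrange(variants, .data$effect_rank, .data$chrom, .data$pos)
}

#' Write a candidate-variant table as TSV
#'
#' Mirrors the layout of a candidate-variant summary: position, alleles,
#' per-role depths (comma-joined, `N` for no read support), effect and
#' gene.
#'
#' @param variants A variant table, typically after [prioritize_cds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(variants, path) {
  fmt <- function(col) map_chr(variants[[col]], function(v) {
    if (is.null(v)) "N" else paste(v, collapse = ",")
  })
  out <- tibble(
    variant_type = variants$variant_class,
    chrom = variants$chrom,
    position = variants$pos,
    reference = variants$ref,
    alternate = variants$alt,
    red_parent = fmt("ad_red_parent"),
    original = fmt("ad_original"),
    green_parent = fmt("ad_green_parent"),
    green_pool = fmt("ad_green_pool"),
    red_pool = fmt("ad_red_pool"),
    effect = variants$effect_class %||% NA_character_,
    gene_id = variants$effect_gene %||% NA_character_
  )
  readr::write_tsv(out, path)
  invisible(path)
}
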