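#' Classify a variant as SNP or InDel
#'
#' A site is a SNP only when the reference allele and every alternate allele
#' are single bases; any length difference (including mixed multiallelic
#' records) makes it an InDel.
#'
#' @param ref Reference allele string (vectorised).
#' @param alts Alternate alleles: a character vector for one variant, or a
#'   list of character vectors parallel to `ref`.
#' @return `"SNP"` or `"InDel"`, vectorised over variants.
#' @examples
#' classify_variant("C", "T")                    # "SNP"
#' classify_variant("AGCAGCTGAAGTTCC", "A")      # "InDel"
#' classify_variant("G", c("T", "GA"))           # "InDel"
#' @export
classify_variant <- function(ref, alts) {
  if (!is.list(alts)) alts <- list(alts)
  if (length(ref) != length(alts)) {
    if (length(ref) == 1L) ref <- rep(ref, length(alts))
    else abort("`ref` and `alts` lengths differ.")
  }
  ok <- nzchar(ref) & map_lgl(alts, function(a) length(a) > 0 && all(nzchar(a)))
  if (!all(ok)) abort("Empty allele string.")
  ifelse(
    nchar(ref) == 1L & map_lgl(alts, function(a) all(nchar(a) == 1L)),
    "SNP", "InDel"
  )
}

#' Read multi-sample variant calls into a variant table
#'
#' Parses a VCF with per-sample allele depths (`AD`) and normalises it into
#' the package's tabular data model, with the five samples of a
#' bulked-segregant design addressed by role. "No read support" (`AD` of
#' `.`/missing for a sample) is kept as an explicit absent state (`NULL`
#' list-column entry), never coerced to zero.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param roles A [sample_roles()] map; every role's sample must be present
#'   in the VCF header.
#' @param ad_policy What to do with records whose FORMAT lacks `AD`
#'   entirely: `"skip"` (drop, with a message) or `"fail"`.
#' @return A tibble with one row per record, sorted by (chromosome,
#'   position): columns `chrom`, `pos`, `ref`, `alt` (comma-separated
#'   alternate alleles), `alts` (list of character vectors), `n_alt`,
#'   `variant_class`, and one `ad_<role>` list-column of integer depth
#'   vectors (ref count first) per role.
#' @export
read_variants <- function(path, roles, ad_policy = c("skip", "fail")) {
  ad_policy <- match.arg(ad_policy)
  stopifnot(inherits(roles, "bsa_roles"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(vcf@gt)[-1]
  absent <- roles$samples[!(roles$samples %in% have)]
  if (length(absent)) {
    abort(paste0(
      "Sample(s) not in VCF header: ",
      paste(sprintf("%s (role %s)", absent, names(absent)), collapse = ", ")
    ))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  no_ad <- !grepl("(^|:)AD(:|$)", vcf@gt[, "FORMAT"])
  if (any(no_ad)) {
    if (ad_policy == "fail") {
      abort(sprintf("%d record(s) have no AD field in FORMAT.", sum(no_ad)))
    }
    message(sprintf("Skipping %d record(s) without an AD field.", sum(no_ad)))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, dimnames = list(NULL, names(ad)))

  keep <- !no_ad
  alts <- strsplit(fix[keep, "ALT"], ",", fixed = TRUE)
  out <- tibble(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"],
    alt = fix[keep, "ALT"],
    alts = alts,
    n_alt = lengths(alts)
  )
  out$variant_class <- classify_variant(out$ref, out$alts)
  for (role in role_names()) {
    out[[ad_col(role)]] <- parse_ad(ad[keep, roles$samples[[role]]])
  }
  validate_variants(out)
  arrange(out, .data$chrom, .data$pos)
}

parse_ad <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "." || !nzchar(s)) return(NULL)
    v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
    if (anyNA(v)) NULL else v
  })
}

validate_variants <- function(x) {
  if (any(x$pos < 1L)) abort("Variant positions must be >= 1.")
  bad <- map2(x$ref, x$alts, function(r, a) any(a == r))
  if (any(unlist(bad))) abort("Reference allele equals an alternate allele.")
  invisible(x)
}

#' Write a variant table as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with a single `AD` FORMAT field, the
#' inverse of [read_variants()]: positions, alleles and allele depths
#' round-trip exactly. Missing depths are written as `.`.
#'
#' @param variants A variant table as returned by [read_variants()] or
#'   [simulate_pools()].
#' @param path Output path.
#' @param roles A [sample_roles()] map giving the sample column names.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, roles = default_roles()) {
  variants <- arrange(variants, .data$chrom, .data$pos)
  fmt_ad <- function(col) {
    map_chr(variants[[col]], function(v) {
      if (is.null(v)) "." else paste(v, collapse = ",")
    })
  }
  body <- cbind(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt,
    ".", "PASS", ".", "AD"
  )
  for (role in role_names()) body <- cbind(body, fmt_ad(ad_col(role)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(roles$samples[role_names()])), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read gene models from GFF3 or a simple interval table
#'
#' GFF3 input is parsed with rtracklayer; `gene` features define genes and
#' `exon`/`CDS` features are attached by following `Parent` links (through
#' mRNA features where present). A tab-separated interval table with columns
#' `gene_id`, `chrom`, `start`, `end` and optionally `strand` defines
#' single-exon genes whose CDS equals the interval.
#'
#' @param path Path to a `.gff3`/`.gff` file or a TSV interval table.
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, list-columns `exons` and `cds` (tibbles of
#'   `start`/`end`, sorted), `cds_len`, and `incomplete_orf` (`TRUE` when
#'   the total CDS length is not divisible by 3).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    df <- as_tibble(as.data.frame(gr))
    df$Parent <- map_chr(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    })
    genes <- filter(df, .data$type == "gene")
    if (nrow(genes) == 0) abort("No gene features in GFF3.")
    # resolve each feature's gene by walking Parent links (<= 3 hops)
    id2parent <- setNames(df$Parent, df$ID)
    to_gene <- function(id) {
      for (i in 1:3) {
        if (is.na(id)) return(NA_character_)
        if (id %in% genes$ID) return(id)
        id <- unname(id2parent[id])
      }
      NA_character_
    }
    feats <- filter(df, .data$type %in% c("exon", "CDS"))
    feats$gene_id <- map_chr(feats$Parent, to_gene)
    build <- function(g) {
      fx <- filter(feats, .data$gene_id == g)
      ex <- arrange(filter(fx, .data$type == "exon"), .data$start)
      cd <- arrange(filter(fx, .data$type == "CDS"), .data$start)
      if (nrow(ex) == 0) ex <- cd  # CDS-only annotations
      list(
        exons = tibble(start = ex$start, end = ex$end),
        cds = tibble(start = cd$start, end = cd$end)
      )
    }
    parts <- map(genes$ID, build)
    out <- tibble(
      gene_id = genes$ID,
      chrom = as.character(genes$seqnames),
      strand = as.character(genes$strand),
      start = genes$start,
      end = genes$end,
      exons = map(parts, "exons"),
      cds = map(parts, "cds")
    )
  } else {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    if (!all(need %in% names(df))) {
      abort("Interval table needs columns gene_id, chrom, start, end.")
    }
    if (!"strand" %in% names(df)) df$strand <- "+"
    out <- tibble(
      gene_id = as.character(df$gene_id),
      chrom = as.character(df$chrom),
      strand = df$strand,
      start = as.integer(df$start),
      end = as.integer(df$end),
      exons = map2(df$start, df$end, function(s, e) tibble(start = s, end = e)),
      cds = map2(df$start, df$end, function(s, e) tibble(start = s, end = e))
    )
  }
  validate_gene_models(out)
}

validate_gene_models <- function(x) {
  check_gene <- function(gene_id, exons, cds) {
    if (nrow(exons) > 1) {
      if (any(exons$start[-1] <= exons$end[-nrow(exons)])) {
        abort(sprintf("Gene %s: exons overlap or are unsorted.", gene_id))
      }
    }
    in_exon <- map_lgl(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    })
    if (!all(in_exon)) {
      abort(sprintf("Gene %s: CDS interval outside exons.", gene_id))
    }
    sum(cds$end - cds$start + 1)
  }
  x$cds_len <- as.integer(pmap(
    list(x$gene_id, x$exons, x$cds), check_gene
  ))
  x$incomplete_orf <- x$cds_len %% 3L != 0L
  if (any(x$incomplete_orf)) {
    warn(sprintf("%d gene(s) have CDS length not divisible by 3.",
                 sum(x$incomplete_orf)))
  }
  x
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()] for models built in-package (e.g. by the
#' simulator): emits gene / mRNA / exon / CDS features with `ID`/`Parent`
#' attributes.
#'
#' @param gene_models Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  row9 <- function(chrom, type, start, end, strand, attr) {
    paste(chrom, "bsascan", type, start, end, ".", strand, ".", attr,
          sep = "\t")
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(gene_models))) {
    g <- gene_models[i, ]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(
      lines,
      row9(g$chrom, "gene", g$start, g$end, g$strand,
           paste0("ID=", g$gene_id)),
      row9(g$chrom, "mRNA", g$start, g$end, g$strand,
           paste0("ID=", tid, ";Parent=", g$gene_id))
    )
    ex <- g$exons[[1]]
    cd <- g$cds[[1]]
    lines <- c(
      lines,
      row9(g$chrom, "exon", ex$start, ex$end, g$strand,
           paste0("Parent=", tid)),
      row9(g$chrom, "CDS", cd$start, cd$end, g$strand,
           paste0("Parent=", tid))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract a gene's spliced CDS sequence
#'
#' Concatenates the CDS intervals along the chromosome and reverse
#' complements for minus-strand genes, so the result starts at the ATG.
#'
#' @param gene One row of a gene-model tibble.
#' @param chrom_seq Chromosome sequence as a single string or
#'   [Biostrings::DNAString].
#' @return The CDS sequence as a character string.
#' @export
extract_cds_sequence <- function(gene, chrom_seq) {
  s <- as.character(chrom_seq)
  cd <- gene$cds[[1]]
  pieces <- substring(s, cd$start, cd$end)
  seq <- paste(pieces, collapse = "")
  if (gene$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq
}
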