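#' Delete an interval from a coding sequence
#'
#' Removes positions `start..end` (1-based, inclusive) from a sequence.
#'
#' @param cds Sequence as a single string.
#' @param start,end 1-based inclusive bounds, `1 <= start <= end <=
#'   nchar(cds)`.
#' @return The sequence with `end - start + 1` bases removed.
#' @examples
#' apply_interval_deletion("ATGAAATTT", 4, 6)  # "ATGTTT"
#' @export
apply_interval_deletion <- function(cds, start, end) {
  n <- nchar(cds)
  if (start < 1 || end < start || end > n) {
    abort(sprintf("Deletion %d..%d outside sequence of length %d.",
                  start, end, n))
  }
  paste0(substr(cds, 1, start - 1), substr(cds, end + 1, n))
}

#' Translate an open reading frame
#'
#' Translates from position 1 with the standard genetic code, stopping at
#' (and excluding) the first stop codon; trailing bases short of a codon
#' are ignored. Sequences shorter than one codon give an empty protein.
#'
#' @param cds Nucleotide sequence as a single string.
#' @return A list: `protein` (amino-acid string), `n_aa`, and `has_stop`
#'   (whether a stop codon was reached).
#' @examples
#' translate_orf("ATGAAATAG")$protein  # "MK"
#' @export
translate_orf <- function(cds) {
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) {
    return(list(protein = "", n_aa = 0L, has_stop = FALSE))
  }
  trimmed <- substr(cds, 1, n_codon * 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(trimmed),
    genetic.code = Biostrings::GENETIC_CODE,
    if.fuzzy.codon = "X"
  ))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    protein <- substr(aa, 1, stop_at - 1)
    list(protein = protein, n_aa = nchar(protein), has_stop = TRUE)
  } else {
    list(protein = aa, n_aa = nchar(aa), has_stop = FALSE)
  }
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  diff <- which(av != bv)
  if (length(diff) == 0) n else diff[1] - 1L
}

#' Coding consequence of a variant applied to a CDS
#'
#' Applies a replacement (`ref` -> `alt` at `pos`, VCF-style; covers SNPs,
#' insertions and deletions) to the wild-type CDS, translates both, and
#' reports the consequence class, protein lengths, the shared N-terminal
#' prefix, and which wild-type protein domains extend beyond that prefix
#' (reported as lost/disrupted).
#'
#' @param wt_cds Wild-type CDS (in frame from position 1).
#' @param pos 1-based position of `ref` within the CDS.
#' @param ref,alt Replaced and replacement sequence at `pos`.
#' @param domains Optional tibble/data.frame of wild-type protein domains
#'   with columns `name`, `start_aa`, `end_aa`.
#' @return A one-row tibble: `consequence` (one of `"synonymous"`,
#'   `"missense"`, `"in-frame indel"`, `"frameshift+early stop"`,
#'   `"stop lost"`, `"non-coding"`), `wt_aa`, `mut_aa`,
#'   `shared_prefix_aa`, `lost_domains` (comma-joined, `""` if none).
#' @export
effect_report <- function(wt_cds, pos, ref, alt, domains = NULL) {
  n <- nchar(wt_cds)
  if (pos < 1 || pos > n) {
    wt <- translate_orf(wt_cds)
    return(tibble(
      consequence = "non-coding", wt_aa = wt$n_aa, mut_aa = wt$n_aa,
      shared_prefix_aa = wt$n_aa, lost_domains = ""
    ))
  }
  observed <- substr(wt_cds, pos, pos + nchar(ref) - 1L)
  if (observed != ref) {
    abort(sprintf("Reference allele mismatch at CDS position %d: expected '%s', found '%s'.",
                  pos, ref, observed))
  }
  mut_cds <- paste0(substr(wt_cds, 1, pos - 1L), alt,
                    substr(wt_cds, pos + nchar(ref), n))
  wt <- translate_orf(wt_cds)
  mut <- translate_orf(mut_cds)
  prefix <- longest_common_prefix(wt$protein, mut$protein)
  len_change <- nchar(alt) - nchar(ref)
  consequence <- if (len_change == 0L) {
    if (identical(wt$protein, mut$protein)) "synonymous" else "missense"
  } else if (len_change %% 3L == 0L) {
    if (!mut$has_stop && wt$has_stop) "stop lost" else "in-frame indel"
  } else {
    if (mut$has_stop) "frameshift+early stop" else "stop lost"
  }
  lost <- ""
  if (!is.null(domains) && nrow(domains) > 0) {
    gone <- domains$end_aa > prefix
    lost <- paste(domains$name[gone], collapse = ",")
  }
  tibble(
    consequence = consequence, wt_aa = wt$n_aa, mut_aa = mut$n_aa,
    shared_prefix_aa = prefix, lost_domains = lost
  )
}

#' Coding consequence of an interval deletion
#'
#' Convenience wrapper around [effect_report()] for a deletion given as a
#' CDS interval.
#'
#' @inheritParams effect_report
#' @param start,end 1-based inclusive CDS interval to delete.
#' @return See [effect_report()].
#' @export
effect_report_deletion <- function(wt_cds, start, end, domains = NULL) {
  if (start > 1) {
    effect_report(wt_cds, start - 1L,
                  substr(wt_cds, start - 1L, end),
                  substr(wt_cds, start - 1L, start - 1L),
                  domains)
  } else {
    effect_report(wt_cds, 1L, substr(wt_cds, 1L, end + 1L),
                  substr(wt_cds, end + 1L, end + 1L), domains)
  }
}

#' Classify cloned amplicon sequences as full or deletion type
#'
#' Classifies each sequenced clone by presence of the deleted segment in
#' its local context: a clone is *full* when it contains the wild-type
#' junction (flank + deleted segment + flank) and *del* when it contains
#' the deletion junction (the two flanks juxtaposed). Clones matching
#' neither (e.g. not spanning the locus) are counted `unclassified` and
#' excluded from the percentage denominator.
#'
#' @param reads Character vector of clone sequences.
#' @param wt_seq Wild-type sequence containing the deletion locus.
#' @param del_start,del_end 1-based inclusive bounds of the deleted segment
#'   within `wt_seq`.
#' @param flank Flank length used to anchor the junction (default 10 bp,
#'   truncated at sequence ends).
#' @return A tibble with rows `full`, `del`, `unclassified`: columns
#'   `type`, `n`, `pct` (percent of classified clones, rounded to 2
#'   decimals; `NA` for unclassified).
#' @examples
#' wt <- "AAAACCCCGGGGTTTT"
#' del <- paste0(substr(wt, 1, 6), substr(wt, 11, 16))
#' classify_clone_haplotypes(c(wt, del, del), wt, 7, 10, flank = 4)
#' @export
classify_clone_haplotypes <- function(reads, wt_seq, del_start, del_end,
                                      flank = 10) {
  n <- nchar(wt_seq)
  if (del_start < 1 || del_end < del_start || del_end > n) {
    abort("Deletion interval outside the wild-type sequence.")
  }
  left <- substr(wt_seq, max(1, del_start - flank), del_start - 1)
  seg <- substr(wt_seq, del_start, del_end)
  right <- substr(wt_seq, del_end + 1, min(n, del_end + flank))
  full_sig <- paste0(left, seg, right)
  del_sig <- paste0(left, right)
  is_full <- grepl(full_sig, reads, fixed = TRUE)
  is_del <- !is_full & grepl(del_sig, reads, fixed = TRUE)
  n_full <- sum(is_full)
  n_del <- sum(is_del)
  n_un <- length(reads) - n_full - n_del
  tot <- n_full + n_del
  pct <- function(k) if (tot > 0) round(100 * k / tot, 2) else NA_real_
  tibble(
    type = c("full", "del", "unclassified"),
    n = c(n_full, n_del, n_un),
    pct = c(pct(n_full), pct(n_del), NA_real_)
  )
}

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = cDNA fragments / (mapped fragments (millions) x transcript
#' length (kb))`.
#'
#' @param cdna_fragments Fragment count assigned to the transcript.
#' @param mapped_fragments_millions Total mapped fragments, in millions.
#' @param transcript_length_kb Transcript length in kilobases.
#' @return The FPKM value (vectorised); `NA` with a warning when a
#'   denominator is zero.
#' @examples
#' fpkm(100, 2, 0.5)  # 100
#' @export
fpkm <- function(cdna_fragments, mapped_fragments_millions,
                 transcript_length_kb) {
  denom <- mapped_fragments_millions * transcript_length_kb
  if (any(denom <= 0)) {
    warn("Zero denominator in FPKM; returning NA.")
  }
  ifelse(denom > 0, cdna_fragments / denom, NA_real_)
}
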