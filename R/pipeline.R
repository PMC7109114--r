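#' Write a simulated dataset to disk
#'
#' Runs [simulate_pools()] and writes the four artefacts a real run would
#' consume: `variants.vcf`, `genes.gff3`, `cds.fasta` (the causal gene's
#' coding sequence), `truth.tsv`, plus `config.yaml` recording the
#' configuration.
#'
#' @param config A [cross_config()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty existing directory (default `FALSE`;
#'   refusing is an error).
#' @return The simulation object, invisibly, with attribute `"dir"`.
#' @export
run_simulate <- function(config = cross_config(), dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) > 0 && !force) {
    abort(sprintf("Output directory '%s' is not empty; use force = TRUE.", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_pools(config)
  write_variants(sim$variants, file.path(dir, "variants.vcf"))
  write_gene_models(sim$gene_models, file.path(dir, "genes.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$cds),
    file.path(dir, "cds.fasta")
  )
  write_truth(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  attr(sim, "dir") <- dir
  invisible(sim)
}

#' Run the full bulked-segregant association scan
#'
#' Orchestrates the pipeline: quality filtering, per-statistic and
#' per-variant-class (SNP / InDel) sliding-window scans with their
#' empirical thresholds, candidate-region calling, mutant-vs-original
#' genotype intersection with pattern selection, and coding-consequence
#' prioritisation when gene models are supplied.
#'
#' @param variants A variant table ([read_variants()] or
#'   [simulate_pools()]`$variants`).
#' @param roles A [sample_roles()] map (orients the SNP index).
#' @param gene_models Optional gene-model tibble.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @param statistics Statistics to scan: `"ED5"`, `"dSNPindex"`, or both.
#' @param window,step,min_variants Sliding-window parameters (defaults
#'   2 Mb / 10 kb / 1).
#' @param ed_threshold,delta_threshold Threshold methods per statistic:
#'   `"median_3sd"` or `"quantile"` (the scan's empirical choices).
#' @param quantile_level Level for quantile thresholds (default 0.99).
#' @param delta_mode `"signed"` or `"absolute"` region calling for the
#'   delta SNP index.
#' @param updown_dist Up/downstream classification distance (bp).
#' @param out_dir Optional directory; when given, writes `regions.tsv`,
#'   `track_<statistic>_<class>.tsv`, `candidates.tsv`,
#'   `filter_report.tsv` and `manifest.yaml`.
#' @param seed Optional seed recorded in the manifest and set before any
#'   stochastic stage.
#' @return An object of class `bsa_scan`: list with `variants` (filtered),
#'   `filter_report`, `tracks` (one `bsa_track` per statistic x class),
#'   `thresholds`, `regions` (with `method` and `variant_type` columns),
#'   `candidates` (pattern-matched, prioritised when models given), and
#'   `manifest`.
#' @export
run_scan <- function(variants,
                     roles = default_roles(),
                     gene_models = NULL,
                     chrom_lengths = NULL,
                     statistics = c("ED5", "dSNPindex"),
                     window = 2e6, step = 1e4, min_variants = 1,
                     ed_threshold = "median_3sd",
                     delta_threshold = "quantile",
                     quantile_level = 0.99,
                     delta_mode = c("signed", "absolute"),
                     updown_dist = 5000,
                     out_dir = NULL,
                     seed = NULL) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  delta_mode <- match.arg(delta_mode)
  if (!is.null(seed)) set.seed(seed)

  n_input <- nrow(variants)
  hq <- filter_high_quality(variants)
  report <- filter_report(hq)
  hq <- add_association_stats(hq, statistics = statistics, roles = roles)

  stat_cols <- c(ED5 = "ed5", dSNPindex = "delta_snp_index")[statistics]
  thr_methods <- c(ED5 = ed_threshold, dSNPindex = delta_threshold)[statistics]
  tracks <- list()
  thresholds <- list()
  regions <- list()
  for (s in statistics) {
    for (cls in c("SNP", "InDel")) {
      sub <- hq[hq$variant_class == cls & !is.na(hq[[stat_cols[[s]]]]), ]
      key <- paste(s, cls, sep = "_")
      if (nrow(sub) == 0) next
      tr <- scan_track(sub, stat_cols[[s]], chrom_lengths,
                       window, step, min_variants)
      if (sum(!is.na(tr$fitted)) < 2) next
      thr <- if (thr_methods[[s]] == "median_3sd") threshold_median_3sd(tr)
      else threshold_quantile(tr, quantile_level)
      mode <- if (s == "dSNPindex") delta_mode else "signed"
      reg <- call_regions(tr, thr, gene_models, mode = mode)
      if (nrow(reg)) {
        reg$method <- if (s == "ED5") "ED" else "SNP index"
        reg$variant_type <- cls
      }
      tracks[[key]] <- tr
      thresholds[[key]] <- thr
      regions[[key]] <- reg
    }
  }
  region_tbl <- bind_rows(regions)
  if (nrow(region_tbl)) {
    region_tbl <- select(region_tbl, "method", "variant_type", "chrom",
                         "start", "end", "size_mb", dplyr::everything())
  }

  # intersection: mutant vs original and vs other parent, inside regions,
  # then the five-role pattern, then coding prioritisation
  candidates <- hq[0, ]
  if (nrow(region_tbl)) {
    mut <- mutual_differential_variants(hq, regions = region_tbl)
    candidates <- select_by_pattern(mut)
    if (!is.null(gene_models) && nrow(candidates)) {
      candidates <- prioritize_cds(candidates, gene_models, updown_dist)
    }
  }

  manifest <- list(
    package = as.character(utils::packageVersion("bsascan")),
    seed = seed,
    config_hash = rlang::hash(list(statistics, window, step, min_variants,
                                   ed_threshold, delta_threshold,
                                   quantile_level, delta_mode, updown_dist)),
    n_input = n_input,
    filter_stages = setNames(as.list(report$n_removed), report$stage),
    n_high_quality = report$n_out[nrow(report)],
    n_regions = nrow(region_tbl),
    n_candidates = nrow(candidates)
  )

  out <- structure(
    list(
      variants = hq, filter_report = report, tracks = tracks,
      thresholds = thresholds, regions = region_tbl,
      candidates = candidates, manifest = manifest
    ),
    class = "bsa_scan"
  )
  if (!is.null(out_dir)) write_scan_outputs(out, out_dir)
  out
}

write_scan_outputs <- function(scan, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(scan$filter_report, file.path(out_dir, "filter_report.tsv"))
  readr::write_tsv(scan$regions, file.path(out_dir, "regions.tsv"))
  for (key in names(scan$tracks)) {
    readr::write_tsv(as_tibble(scan$tracks[[key]]),
                     file.path(out_dir, sprintf("track_%s.tsv", key)))
  }
  if (nrow(scan$candidates)) {
    write_candidate_table(scan$candidates, file.path(out_dir, "candidates.tsv"))
  }
  yaml::write_yaml(scan$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @method print bsa_scan
#' @export
print.bsa_scan <- function(x, ...) {
  cat("<bsa_scan>\n")
  cat(sprintf("  %d high-quality variants (of %d input)\n",
              x$manifest$n_high_quality, x$manifest$n_input))
  for (key in names(x$thresholds)) {
    cat(sprintf("  %s threshold (%s): %.4g\n", key,
                x$thresholds[[key]]$method, x$thresholds[[key]]$value))
  }
  cat(sprintf("  %d candidate region(s), %d pattern-matched candidate(s)\n",
              nrow(x$regions), nrow(x$candidates)))
  if (nrow(x$candidates) && "effect_class" %in% names(x$candidates)) {
    top <- x$candidates[1, ]
    cat(sprintf("  top candidate: %s:%d %s (%s)\n", top$chrom, top$pos,
                top$effect_class, top$effect_gene %||% "-"))
  }
  invisible(x)
}

#' @describeIn run_scan `tidy()` returns the candidate-region table.
#' @param x A `bsa_scan` object.
#' @param ... Unused.
#' @export
tidy.bsa_scan <- function(x, ...) {
  as_tibble(x$regions)
}

#' @describeIn run_scan `glance()` returns a one-row scan summary.
#' @export
glance.bsa_scan <- function(x, ...) {
  peak <- if (nrow(x$regions)) max(x$regions$peak_value) else NA_real_
  tibble(
    n_input = x$manifest$n_input,
    n_high_quality = x$manifest$n_high_quality,
    n_regions = nrow(x$regions),
    n_candidates = nrow(x$candidates),
    peak_value = peak
  )
}
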