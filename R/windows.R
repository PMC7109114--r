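#' Fit per-variant association values in sliding windows
#'
#' Windows of width `window` advance by `step` along one chromosome,
#' anchored at position 0: internally window *k* is the half-open interval
#' `[k*step, k*step + window)` in 0-based coordinates, i.e. genomic
#' positions `k*step + 1 .. k*step + window`. The fitted value of a window
#' is the arithmetic mean of the raw values of the variants inside it;
#' windows holding fewer than `min_variants` variants are undefined (`NA`
#' fitted value) and take no part in threshold computation.
#'
#' @param positions Sorted 1-based variant positions on one chromosome.
#' @param values Per-variant raw statistic, parallel to `positions`
#'   (`NA`s are dropped together with their positions).
#' @param chrom_length Chromosome length in bp; windows start while
#'   `k*step < chrom_length`.
#' @param window,step Window width and step in bp (defaults 2 Mb / 10 kb).
#' @param min_variants Minimum variants for a window to be defined
#'   (default 1).
#' @return A `bsa_track` tibble with columns `offset` (0-based window
#'   start), `win_start`/`win_end` (1-based inclusive, end capped at
#'   `chrom_length`), `midpoint`, `n_variants`, `fitted`.
#' @export
fit_windows <- function(positions, values, chrom_length,
                        window = 2e6, step = 1e4, min_variants = 1) {
  stopifnot(window >= step, chrom_length >= 1)
  keep <- !is.na(values)
  positions <- positions[keep]
  values <- values[keep]
  if (is.unsorted(positions)) {
    o <- order(positions)
    positions <- positions[o]
    values <- values[o]
  }
  offs <- seq(0, by = step, length.out = ceiling(chrom_length / step))
  offs <- offs[offs < chrom_length]
  lo <- findInterval(offs, positions)
  hi <- findInterval(offs + window, positions)
  cnt <- hi - lo
  cs <- c(0, cumsum(values))
  fitted <- (cs[hi + 1] - cs[lo + 1]) / cnt
  fitted[cnt < min_variants] <- NA_real_
  structure(
    tibble(
      offset = offs,
      win_start = offs + 1,
      win_end = pmin(offs + window, chrom_length),
      midpoint = offs + window / 2,
      n_variants = cnt,
      fitted = fitted
    ),
    class = c("bsa_track", "tbl_df", "tbl", "data.frame"),
    window = window, step = step
  )
}

#' Genome-wide sliding-window track for one statistic
#'
#' Groups a scored variant table by chromosome and applies [fit_windows()]
#' to the chosen statistic column.
#'
#' @param variants A variant table scored by [add_association_stats()].
#' @param stat_col Column holding the raw per-variant statistic
#'   (`"ed5"` or `"delta_snp_index"`).
#' @param chrom_lengths Named vector of chromosome lengths; chromosomes
#'   absent from it use the maximum variant position.
#' @inheritParams fit_windows
#' @return A `bsa_track` tibble with a leading `chrom` column.
#' @export
scan_track <- function(variants, stat_col,
                       chrom_lengths = NULL,
                       window = 2e6, step = 1e4, min_variants = 1) {
  if (!stat_col %in% names(variants)) {
    abort(sprintf("Column `%s` not found; run add_association_stats().", stat_col))
  }
  chroms <- sort(unique(variants$chrom))
  tracks <- map(chroms, function(ch) {
    v <- variants[variants$chrom == ch, ]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(v$pos)
    }
    tr <- fit_windows(v$pos, v[[stat_col]], len, window, step, min_variants)
    tr$chrom <- ch
    tr
  })
  out <- bind_rows(tracks)
  out <- out[, c("chrom", setdiff(names(out), "chrom"))]
  structure(out,
            class = c("bsa_track", "tbl_df", "tbl", "data.frame"),
            window = window, step = step, statistic = stat_col)
}

new_threshold <- function(statistic, method, value, params = list()) {
  structure(
    list(statistic = statistic, method = method, value = value,
         params = params),
    class = "bsa_threshold"
  )
}

#' @method print bsa_threshold
#' @export
print.bsa_threshold <- function(x, ...) {
  cat(sprintf("<bsa_threshold> %s by %s: %.6g\n",
              x$statistic %||% "?", x$method, x$value))
  invisible(x)
}

#' Median + 3 SD threshold
#'
#' The empirical threshold used for ED scans: the median of the defined
#' fitted window values plus three sample standard deviations, computed
#' genome-wide over the supplied track.
#'
#' @param track A `bsa_track` (possibly multi-chromosome).
#' @return A `bsa_threshold` object.
#' @export
threshold_median_3sd <- function(track) {
  f <- track$fitted[!is.na(track$fitted)]
  if (length(f) < 2) abort("Need at least 2 defined windows.")
  new_threshold(attr(track, "statistic"), "median_plus_3sd",
                median(f) + 3 * sd(f))
}

#' Quantile threshold
#'
#' The empirical threshold used for delta-SNP-index scans: the `level`
#' quantile of the defined fitted window values, with linear interpolation
#' between order statistics (R's default type-7 quantile).
#'
#' @param track A `bsa_track`.
#' @param level Quantile level in (0, 1); default 0.99.
#' @return A `bsa_threshold` object.
#' @export
threshold_quantile <- function(track, level = 0.99) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  f <- track$fitted[!is.na(track$fitted)]
  if (length(f) < 1) abort("Need at least 1 defined window.")
  new_threshold(attr(track, "statistic"), "quantile",
                unname(quantile(f, level, type = 7)),
                params = list(level = level))
}

#' Null-simulation threshold for the delta SNP index
#'
#' Simulates the delta SNP index under the no-association null of an F1 of
#' heterozygous x homozygous parents: in each pool, reads are drawn
#' binomially at the Mendelian expectation of the female-allele fraction
#' (3/4), so only sequencing-depth noise enters; the bound at a depth is
#' the `level` quantile of |delta|. The bound shrinks to 0 as depth grows.
#'
#' @param depths Integer vector of pool depths at which to tabulate the
#'   envelope.
#' @param level Confidence level (default 0.90); the bound is the `level`
#'   quantile of |delta| under the null.
#' @param n_sims Simulations per depth (default 10000; values below 100
#'   warn).
#' @param seed Optional RNG seed for reproducibility.
#' @param reference_depth Depth at which the scalar `value` of the returned
#'   threshold is evaluated (nearest tabulated depth; default the median
#'   of `depths`).
#' @return A `bsa_threshold` whose `params$envelope` is a tibble
#'   `(depth, bound)`.
#' @export
threshold_null_simulation <- function(depths = c(10, 20, 40, 80),
                                      level = 0.90, n_sims = 1e4,
                                      seed = NULL,
                                      reference_depth = NULL) {
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  if (n_sims < 100) warn("n_sims < 100: envelope will be noisy.")
  if (!is.null(seed)) set.seed(seed)
  f_null <- 0.75  # female-allele fraction in both pools for het x hom F1
  env <- tibble(
    depth = as.integer(depths),
    bound = map_dbl(depths, function(d) {
      aa <- rbinom(n_sims, d, f_null) / d
      ab <- rbinom(n_sims, d, f_null) / d
      unname(quantile(abs(aa - ab), level, type = 7))
    })
  )
  reference_depth <- reference_depth %||% median(depths)
  i <- which.min(abs(env$depth - reference_depth))
  new_threshold("delta_snp_index", "null_simulation", env$bound[i],
                params = list(level = level, n_sims = n_sims,
                              envelope = env,
                              reference_depth = env$depth[i]))
}

#' Call candidate regions from a fitted track
#'
#' A candidate region is a maximal run of consecutive defined windows whose
#' fitted value reaches the threshold (ties count as above). Runs separated
#' by even one below-threshold or undefined window are kept separate.
#' Regions are reported by window anchor coordinates — `start` is the first
#' qualifying window's start offset (floored at 1) and `end` the last
#' qualifying window's start offset — so a single-window region has size
#' 0 Mb.
#'
#' @param track A `bsa_track` with a `chrom` column (from [scan_track()]).
#' @param threshold A `bsa_threshold` or a plain number.
#' @param gene_models Optional gene-model tibble; when given, each region
#'   gains the count of genes overlapping `[start, end]`.
#' @param mode `"signed"` (default) compares fitted values as-is;
#'   `"absolute"` compares `|fitted|` (for delta-SNP-index tracks where
#'   phase orientation is unknown).
#' @return A tibble of regions: `chrom`, `start`, `end` (window anchor
#'   coordinates), `size_mb`, `span_start`/`span_end` (the full genomic
#'   extent covered by the qualifying windows, used for gene counting and
#'   variant membership), `peak_pos` (midpoint of the best window),
#'   `peak_value`, `n_windows`, and `n_genes` when models are supplied.
#'   Empty when nothing exceeds the threshold.
#' @export
call_regions <- function(track, threshold, gene_models = NULL,
                         mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  thr <- if (inherits(threshold, "bsa_threshold")) threshold$value
  else as.numeric(threshold)
  if (!"chrom" %in% names(track)) track$chrom <- "chr"
  step <- attr(track, "step") %||% 1e4
  fit <- if (mode == "absolute") abs(track$fitted) else track$fitted
  above <- !is.na(fit) & fit >= thr
  if (!any(above)) {
    return(tibble(
      chrom = character(), start = double(), end = double(),
      size_mb = double(), span_start = double(), span_end = double(),
      peak_pos = double(), peak_value = double(), n_windows = integer()
    ))
  }
  sub <- track[above, ]
  sub$fit_cmp <- fit[above]
  sub <- arrange(sub, .data$chrom, .data$offset)
  new_run <- c(TRUE, sub$chrom[-1] != sub$chrom[-nrow(sub)] |
                 diff(sub$offset) != step)
  sub$run <- cumsum(new_run)
  regions <- sub |>
    group_by(.data$run) |>
    summarise(
      chrom = .data$chrom[1],
      start = max(min(.data$offset), 1),
      end = max(.data$offset),
      span_start = min(.data$win_start),
      span_end = max(.data$win_end),
      peak_pos = .data$midpoint[which.max(.data$fit_cmp)],
      peak_value = .data$fitted[which.max(.data$fit_cmp)],
      n_windows = n(),
      .groups = "drop"
    ) |>
    mutate(size_mb = (.data$end - .data$start) / 1e6) |>
    select("chrom", "start", "end", "size_mb", "span_start", "span_end",
           "peak_pos", "peak_value", "n_windows") |>
    arrange(.data$chrom, .data$start)
  if (!is.null(gene_models)) {
    regions$n_genes <- map_int(seq_len(nrow(regions)), function(i) {
      sum(gene_models$chrom == regions$chrom[i] &
            gene_models$start <= regions$span_end[i] &
            gene_models$end >= regions$span_start[i])
    })
  }
  regions
}
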