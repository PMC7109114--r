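#' Plot a fitted association track
#'
#' Scan-style figure: fitted window values as a line along each
#' chromosome, optionally the raw per-variant statistic as points and the
#' association threshold as a dashed line.
#'
#' @param track A `bsa_track` from [scan_track()].
#' @param threshold Optional `bsa_threshold` or number.
#' @param variants Optional scored variant table; when given, the raw
#'   statistic (the track's `statistic` attribute) is drawn as points.
#' @return A ggplot object.
#' @export
plot_track <- function(track, threshold = NULL, variants = NULL) {
  stat_col <- attr(track, "statistic") %||% "statistic"
  p <- ggplot2::ggplot()
  if (!is.null(variants) && stat_col %in% names(variants)) {
    p <- p + ggplot2::geom_point(
      data = variants,
      ggplot2::aes(x = .data$pos / 1e6, y = .data[[stat_col]]),
      colour = "grey70", size = 0.4, alpha = 0.6, na.rm = TRUE
    )
  }
  df <- as_tibble(track)
  if (!"chrom" %in% names(df)) df$chrom <- "chr"
  p <- p + ggplot2::geom_line(
    data = df,
    ggplot2::aes(x = .data$midpoint / 1e6, y = .data$fitted),
    linewidth = 0.5, na.rm = TRUE
  )
  if (!is.null(threshold)) {
    thr <- if (inherits(threshold, "bsa_threshold")) threshold$value
    else as.numeric(threshold)
    p <- p + ggplot2::geom_hline(yintercept = thr, colour = "red",
                                 linetype = "dashed")
  }
  p +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = stat_col) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bsa_track <- function(object, threshold = NULL, ...) {
  plot_track(object, threshold = threshold)
}

#' @export
autoplot.bsa_scan <- function(object, which = NULL, ...) {
  keys <- names(object$tracks)
  if (length(keys) == 0) abort("Scan holds no tracks.")
  key <- which %||% keys[1]
  plot_track(object$tracks[[key]], object$thresholds[[key]],
             variants = object$variants)
}
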