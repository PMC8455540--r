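TALLY_NAMES <- c("pass", "too_short", "too_many_n", "low_mean_quality",
                 "trimmed", "orphans_dropped")

# Bundle of everything one sample produced: output paths, raw/clean QC
# accumulators, verdict tallies and base accounting.
new_qc_result <- function(sample, files, encoding, config,
                          stats_raw, stats_clean, tallies, bases,
                          paired = FALSE, keep_orphans = FALSE) {
  stopifnot(all(TALLY_NAMES %in% names(tallies)))
  structure(
    list(
      sample = sample,
      files = files,
      encoding = encoding,
      config = config,
      stats_raw = stats_raw,
      stats_clean = stats_clean,
      tallies = tallies[TALLY_NAMES],
      bases = bases,
      paired = paired,
      keep_orphans = keep_orphans
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  t <- x$tallies
  cat(sprintf("<qc_result> sample '%s' (%s)\n", x$sample,
              if (x$paired) "paired-end" else "single-end"))
  cat(sprintf("  quality format:    %s\n", x$encoding$name))
  cat(sprintf("  reads in:          %d\n", x$stats_raw$n_reads))
  cat(sprintf("  reads retained:    %d\n", x$stats_clean$n_reads))
  cat(sprintf("  failed: %d too short, %d too many N, %d low mean quality\n",
              t[["too_short"]], t[["too_many_n"]], t[["low_mean_quality"]]))
  cat(sprintf("  trimmed (retained): %d\n", t[["trimmed"]]))
  if (t[["orphans_dropped"]] > 0) {
    cat(sprintf("  passing orphans dropped with failed mates: %d\n",
                t[["orphans_dropped"]]))
  }
  invisible(x)
}

#' Tidy the per-read verdict tallies of a sample
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return A tibble with one row per outcome (`pass`, the three fail
#'   reasons, `trimmed`, `orphans_dropped`) and its read count.
#' @export
tidy.qc_result <- function(x, ...) {
  tibble(outcome = names(x$tallies), n_reads = as.integer(x$tallies))
}

#' One-row summary of a sample's QC run
#'
#' The same fields written to the summary TSV by [render_summary()]:
#' detected quality format, raw/clean read and base counts, length
#' extremes and means, average per-read mean Phred, per-reason fail
#' counts, trimmed-read count and bases removed by each trimmer.
#'
#' @param x A `qc_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.qc_result <- function(x, ...) {
  raw <- glance(x$stats_raw)
  cln <- glance(x$stats_clean)
  t <- x$tallies
  tibble(
    sample = x$sample,
    quality_format = x$encoding$name,
    raw_reads = raw$n_reads,
    clean_reads = cln$n_reads,
    raw_bases = raw$n_bases,
    clean_bases = cln$n_bases,
    raw_min_length = raw$min_length,
    raw_max_length = raw$max_length,
    raw_mean_length = raw$mean_length,
    clean_min_length = cln$min_length,
    clean_max_length = cln$max_length,
    clean_mean_length = cln$mean_length,
    raw_mean_quality = raw$mean_quality,
    clean_mean_quality = cln$mean_quality,
    fail_too_short = t[["too_short"]],
    fail_too_many_n = t[["too_many_n"]],
    fail_low_mean_quality = t[["low_mean_quality"]],
    orphans_dropped = t[["orphans_dropped"]],
    reads_trimmed = t[["trimmed"]],
    adapter_bases_removed = x$bases[["adapter_removed"]],
    quality_bases_removed = x$bases[["quality_removed"]]
  )
}

#' Write the per-sample summary table
#'
#' A two-column (field, value) tab-separated file named
#' `<sample>_summary.tsv`. Counts are plain integers; undefined length and
#' quality fields of an empty sample are written as `NA`.
#'
#' @param result A `qc_result`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the path written.
#' @export
render_summary <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  g <- glance(result)
  long <- tibble(
    field = names(g),
    value = vapply(g, function(v) {
      if (is.na(v)) "NA"
      else if (is.numeric(v) && v == round(v)) format(v, scientific = FALSE)
      else if (is.numeric(v)) sprintf("%.4f", v)
      else as.character(v)
    }, character(1))
  )
  path <- file.path(outdir, paste0(result$sample, "_summary.tsv"))
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

# raw-vs-clean overlay tables behind the four report plots
overlay_table <- function(result, type) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(result$stats_raw, type = type), series = "raw",
                  .before = 1),
    dplyr::mutate(tidy(result$stats_clean, type = type), series = "clean",
                  .before = 1)
  )
}

#' Per-panel QC plots for a sample
#'
#' Four raw-vs-clean overlays: mean Phred per read position (line), percent
#' of reads per mean-quality bin (bar), percent of reads per GC bin (line),
#' and per-position base composition (line, faceted by series).
#'
#' @param result A `qc_result`.
#' @return A ggplot object.
#' @name qc_plots
NULL

#' @rdname qc_plots
#' @export
plot_position_quality <- function(result) {
  d <- dplyr::filter(overlay_table(result, "position_quality"),
                     !is.na(.data$mean_quality))
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$mean_quality,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste0(result$sample, ": mean quality by position"),
                  x = "position in read (bp)", y = "mean Phred score",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_read_quality_hist <- function(result) {
  d <- overlay_table(result, "read_quality")
  ggplot2::ggplot(d, ggplot2::aes(.data$quality_bin, .data$percent,
                                  fill = .data$series)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(title = paste0(result$sample, ": read mean-quality distribution"),
                  x = "mean Phred score of read", y = "% of reads",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_gc_content <- function(result) {
  d <- overlay_table(result, "gc")
  ggplot2::ggplot(d, ggplot2::aes(.data$gc_bin, .data$percent,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste0(result$sample, ": GC content distribution"),
                  x = "GC content (%)", y = "% of reads", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname qc_plots
#' @export
plot_base_composition <- function(result) {
  d <- overlay_table(result, "base_composition")
  ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$percent,
                                  colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1) +
    ggplot2::labs(title = paste0(result$sample, ": base composition by position"),
                  x = "position in read (bp)", y = "% of bases",
                  colour = "base") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for QC results
#'
#' @param object A `qc_result`.
#' @param type One of `"position_quality"`, `"read_quality"`, `"gc"`,
#'   `"base_composition"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qc_result <- function(object, type = c("position_quality",
                                                "read_quality", "gc",
                                                "base_composition"), ...) {
  type <- match.arg(type)
  switch(type,
    position_quality = plot_position_quality(object),
    read_quality = plot_read_quality_hist(object),
    gc = plot_gc_content(object),
    base_composition = plot_base_composition(object)
  )
}

#' Write the four QC plots and their backing tables
#'
#' Every plot's exact numeric content is written as a tab-separated table
#' next to the PNG, so downstream checks can assert numbers rather than
#' pixels: `<sample>_per_position_quality.tsv`,
#' `<sample>_read_quality_hist.tsv`, `<sample>_gc_hist.tsv`,
#' `<sample>_base_composition.tsv` and the matching `.png` files.
#'
#' @param result A `qc_result`.
#' @param outdir Output directory (created if missing).
#' @param png Also render the PNG images (the tables are always written)?
#' @return Invisibly, a named character vector of the paths written.
#' @export
render_plots <- function(result, outdir, png = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(outdir, result$sample)
  tables <- list(
    per_position_quality = overlay_table(result, "position_quality"),
    read_quality_hist = overlay_table(result, "read_quality"),
    gc_hist = overlay_table(result, "gc"),
    base_composition = overlay_table(result, "base_composition")
  )
  paths <- character()
  for (nm in names(tables)) {
    p <- paste0(stem, "_", nm, ".tsv")
    readr::write_tsv(tables[[nm]], p, progress = FALSE)
    paths[paste0(nm, "_tsv")] <- p
  }
  if (png) {
    plots <- list(
      per_position_quality = plot_position_quality(result),
      read_quality_hist = plot_read_quality_hist(result),
      gc_hist = plot_gc_content(result),
      base_composition = plot_base_composition(result)
    )
    for (nm in names(plots)) {
      p <- paste0(stem, "_", nm, ".png")
      suppressMessages(ggplot2::ggsave(p, plots[[nm]], width = 7,
                                       height = 4.5, dpi = 100))
      paths[paste0(nm, "_png")] <- p
    }
  }
  invisible(paths)
}
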