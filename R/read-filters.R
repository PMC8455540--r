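#' Configure trimming and filtering
#'
#' Bundles every per-read threshold in one object. By default only the
#' mean-quality filter is active, at Phred 20 (about 99% base-call
#' accuracy); all trimming and the N/length filters are off until set.
#' `max_n` and `max_n_fraction` are mutually exclusive ways to bound
#' uncalled-base content.
#'
#' @param min_mean_quality Reads whose mean Phred is strictly below this
#'   fail; a read exactly at the threshold passes. Default 20.
#' @param max_n Maximum allowed count of `N` bases, or `NULL` (off).
#' @param max_n_fraction Maximum allowed fraction of `N` bases in `[0, 1]`,
#'   or `NULL` (off).
#' @param min_length Minimum post-trim length. Zero-length reads always fail
#'   regardless (empty sequences are invalid FASTQ output). Default 0.
#' @param trim_quality_threshold Per-base Phred threshold for 3' quality
#'   trimming, or `NULL` (off).
#' @param adapters An [adapter_set()] (or adapters coercible to one), or
#'   `NULL` (off).
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_mean_quality = 20,
                          max_n = NULL,
                          max_n_fraction = NULL,
                          min_length = 0L,
                          trim_quality_threshold = NULL,
                          adapters = NULL) {
  if (!is.null(max_n) && !is.null(max_n_fraction)) {
    abort("`max_n` and `max_n_fraction` are mutually exclusive")
  }
  if (!is.null(max_n) && (max_n < 0 || is.na(max_n))) {
    abort("`max_n` must be a non-negative integer")
  }
  if (!is.null(max_n_fraction) &&
      (is.na(max_n_fraction) || max_n_fraction < 0 || max_n_fraction > 1)) {
    abort("`max_n_fraction` must be in [0, 1]")
  }
  if (min_length < 0) abort("`min_length` must be non-negative")
  if (!is.null(adapters)) adapters <- as_adapter_set(adapters)
  structure(
    list(
      min_mean_quality = min_mean_quality,
      max_n = if (is.null(max_n)) NULL else as.integer(max_n),
      max_n_fraction = max_n_fraction,
      min_length = as.integer(min_length),
      trim_quality_threshold = trim_quality_threshold,
      adapters = adapters
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  onoff <- function(v) if (is.null(v)) "off" else format(v)
  cat("<filter_config>\n")
  cat("  min mean quality:  ", format(x$min_mean_quality), "\n")
  cat("  max N count:       ", onoff(x$max_n), "\n")
  cat("  max N fraction:    ", onoff(x$max_n_fraction), "\n")
  cat("  min length:        ", format(x$min_length), "\n")
  cat("  3' quality trim:   ", onoff(x$trim_quality_threshold), "\n")
  cat("  adapters:          ",
      if (is.null(x$adapters)) "off"
      else paste(x$adapters$adapters, collapse = ","), "\n")
  invisible(x)
}

#' Count uncalled bases in each sequence
#'
#' @param sequence Character vector of normalized (uppercase) sequences.
#' @return Integer vector of `N` counts.
#' @export
count_uncalled <- function(sequence) {
  as.integer(stringr::str_count(sequence, stringr::fixed("N")))
}

FAIL_REASONS <- c("too_short", "too_many_n", "low_mean_quality")

#' Trim and filter reads, producing one verdict per read
#'
#' Applies the fixed pipeline order: adapter trimming, then 3' quality
#' trimming, then the filters on the post-trim read -- length, uncalled
#' bases, mean quality. The first failing check sets the single
#' `fail_reason` and later checks are skipped, so the per-reason tallies
#' partition the input exactly.
#'
#' @param reads A reads tibble.
#' @param config A [filter_config()].
#' @param encoding A [quality_encoding()] (detected or forced).
#' @return The reads tibble (sequence/quality post-trim) with columns
#'   `adapter_bases_removed`, `quality_bases_removed`, `was_trimmed`,
#'   `length`, `n_count`, `mean_quality`, `fail_reason`
#'   (`"none"`/`"too_short"`/`"too_many_n"`/`"low_mean_quality"`) and
#'   `status` (`"pass"`/`"fail"`).
#' @export
evaluate_reads <- function(reads, config = filter_config(), encoding) {
  assert_reads(reads)
  encoding <- as_quality_encoding(encoding)
  out <- reads
  if (!is.null(config$adapters)) {
    out <- trim_adapter(out, config$adapters)
  } else {
    out$adapter_bases_removed <- integer(nrow(out))
  }
  if (!is.null(config$trim_quality_threshold)) {
    out <- trim_quality_3prime(out, config$trim_quality_threshold, encoding)
  } else {
    out$quality_bases_removed <- integer(nrow(out))
  }
  out$was_trimmed <- (out$adapter_bases_removed + out$quality_bases_removed) > 0L
  out$length <- nchar(out$sequence)
  out$n_count <- count_uncalled(out$sequence)
  out$mean_quality <- mean_qualities(out$quality, encoding, out$read_id)

  too_short <- out$length < max(config$min_length, 1L)
  too_n <- rep(FALSE, nrow(out))
  if (!is.null(config$max_n)) {
    too_n <- out$n_count > config$max_n
  } else if (!is.null(config$max_n_fraction)) {
    too_n <- !too_short & (out$n_count / out$length > config$max_n_fraction)
  }
  low_q <- !is.na(out$mean_quality) & out$mean_quality < config$min_mean_quality

  out$fail_reason <- dplyr::case_when(
    too_short ~ "too_short",
    too_n ~ "too_many_n",
    low_q ~ "low_mean_quality",
    .default = "none"
  )
  out$status <- ifelse(out$fail_reason == "none", "pass", "fail")
  out
}
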