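#' GC content of each sequence, in percent
#'
#' `100 * (G + C) / (A + C + G + T)`. Uncalled bases are excluded from both
#' numerator and denominator; a read with no called base has undefined GC and
#' returns `NA` (such reads are tallied separately in the stats object, not
#' binned).
#'
#' @param sequence Character vector of normalized sequences.
#' @return Numeric vector of GC percentages (`NA` where undefined).
#' @export
gc_percent <- function(sequence) {
  gc <- stringr::str_count(sequence, "[GC]")
  called <- stringr::str_count(sequence, "[ACGT]")
  ifelse(called > 0L, 100 * gc / called, NA_real_)
}

empty_qc_stats <- function() {
  structure(
    list(
      n_reads = 0L, n_bases = 0, n_no_called = 0L,
      min_len = NA_integer_, max_len = NA_integer_, sum_len = 0,
      sum_mean_quality = 0,
      pos_qual_sum = numeric(), pos_count = integer(),
      base_counts = matrix(0L, nrow = 5L, ncol = 0L,
                           dimnames = list(names(BASE_CODES), NULL)),
      gc_hist = integer(101L),        # bins 0..100, round-half-up
      read_q_hist = integer(61L)      # bins 0..60, floor of mean Phred
    ),
    class = "qc_stats"
  )
}

#' Streaming QC statistics for a set of reads
#'
#' A mergeable accumulator of every number behind the QC report: read/base
#' counts, length extremes, per-position quality sums and base composition,
#' a 1-point-wide GC histogram (round-half-up of per-read GC percent) and a
#' 1-point-wide read-quality histogram (floor of per-read mean Phred,
#' clamped to 0--60). Build one per chunk and combine with [merge_stats()];
#' the merged result is identical to accumulating the concatenated stream.
#'
#' @param reads A reads tibble, or `NULL` for an empty accumulator.
#' @param encoding A [quality_encoding()]; required when `reads` is nonempty.
#' @return A `qc_stats` object.
#' @export
qc_stats <- function(reads = NULL, encoding = NULL) {
  s <- empty_qc_stats()
  if (is.null(reads) || nrow(reads) == 0L) return(s)
  update_stats(s, reads, encoding)
}

#' Fold a batch of reads into a QC accumulator
#'
#' @param stats A `qc_stats` object.
#' @param reads A reads tibble.
#' @param encoding A [quality_encoding()].
#' @return The updated `qc_stats`.
#' @export
update_stats <- function(stats, reads, encoding) {
  assert_reads(reads)
  if (nrow(reads) == 0L) return(stats)
  encoding <- as_quality_encoding(encoding)
  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  maxlen <- max(lens)

  sbytes <- lapply(reads$sequence, charToRaw)
  sb <- as.integer(unlist(sbytes, use.names = FALSE))
  scores <- unlist(phred_list(reads$quality, encoding, reads$read_id),
                   use.names = FALSE)
  posv <- sequence(lens)
  grp <- rep.int(seq_len(n), lens)

  s <- empty_qc_stats()
  s$n_reads <- n
  s$n_bases <- sum(lens)
  s$min_len <- min(lens)
  s$max_len <- maxlen
  s$sum_len <- sum(lens)

  if (maxlen > 0L) {
    s$pos_count <- tabulate(posv, maxlen)
    s$pos_qual_sum <- as.numeric(
      rowsum(scores, posv, reorder = TRUE)[, 1]
    )
    bi <- match(sb, BASE_CODES)
    s$base_counts <- matrix(
      tabulate((posv - 1L) * 5L + bi, 5L * maxlen),
      nrow = 5L, dimnames = list(names(BASE_CODES), NULL)
    )
  }

  # per-read aggregates
  mq <- rep(NA_real_, n)
  if (any(lens > 0L)) {
    qsums <- rowsum(scores, grp, reorder = TRUE)[, 1]
    nz <- sort(unique(grp))
    mq[nz] <- qsums / lens[nz]
  }
  s$sum_mean_quality <- sum(mq, na.rm = TRUE)
  # zero-length reads carry no quality signal; they land in bin 0
  qbin <- ifelse(is.na(mq), 0L, pmin(pmax(floor(mq), 0), 60))
  s$read_q_hist <- tabulate(qbin + 1L, 61L)

  gc <- gc_percent(reads$sequence)
  s$n_no_called <- sum(is.na(gc))
  if (any(!is.na(gc))) {
    gcbin <- floor(gc[!is.na(gc)] + 0.5)  # round half up
    s$gc_hist <- tabulate(gcbin + 1L, 101L)
  }
  merge_stats(stats, s)
}

pad_to <- function(x, len, fill = 0) {
  if (length(x) >= len) return(x)
  c(x, rep(fill, len - length(x)))
}

#' Merge two QC accumulators
#'
#' Elementwise sums (position arrays padded to the longer length), min/max
#' combined by min/max. Merging is associative and commutative with the
#' empty accumulator as identity, so chunk results can be combined in any
#' order.
#'
#' @param a,b `qc_stats` objects.
#' @return The combined `qc_stats`.
#' @export
merge_stats <- function(a, b) {
  if (!inherits(a, "qc_stats") || !inherits(b, "qc_stats")) {
    abort("merge_stats() expects two qc_stats objects")
  }
  if (a$n_reads == 0L) return(b)
  if (b$n_reads == 0L) return(a)
  maxlen <- max(length(a$pos_count), length(b$pos_count))
  bc_a <- cbind(a$base_counts,
                matrix(0L, 5L, maxlen - ncol(a$base_counts)))
  bc_b <- cbind(b$base_counts,
                matrix(0L, 5L, maxlen - ncol(b$base_counts)))
  structure(
    list(
      n_reads = a$n_reads + b$n_reads,
      n_bases = a$n_bases + b$n_bases,
      n_no_called = a$n_no_called + b$n_no_called,
      min_len = min(a$min_len, b$min_len),
      max_len = max(a$max_len, b$max_len),
      sum_len = a$sum_len + b$sum_len,
      sum_mean_quality = a$sum_mean_quality + b$sum_mean_quality,
      pos_qual_sum = pad_to(a$pos_qual_sum, maxlen) +
        pad_to(b$pos_qual_sum, maxlen),
      pos_count = pad_to(a$pos_count, maxlen) + pad_to(b$pos_count, maxlen),
      base_counts = `dimnames<-`(bc_a + bc_b,
                                 list(names(BASE_CODES), NULL)),
      gc_hist = a$gc_hist + b$gc_hist,
      read_q_hist = a$read_q_hist + b$read_q_hist
    ),
    class = "qc_stats"
  )
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf(
    "<qc_stats> %d reads, %s bases%s\n", x$n_reads,
    format(x$n_bases, big.mark = ","),
    if (x$n_reads > 0)
      sprintf(", length %d-%d, mean quality %.2f",
              x$min_len, x$max_len, x$sum_mean_quality / x$n_reads)
    else ""
  ))
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a QC accumulator
#'
#' @param x A `qc_stats` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_reads`, `n_bases`, `min_length`,
#'   `max_length`, `mean_length`, `mean_quality` (mean over reads of the
#'   per-read mean Phred).
#' @export
glance.qc_stats <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    n_bases = x$n_bases,
    min_length = x$min_len,
    max_length = x$max_len,
    mean_length = if (x$n_reads > 0) x$sum_len / x$n_reads else NA_real_,
    mean_quality = if (x$n_reads > 0) x$sum_mean_quality / x$n_reads
                   else NA_real_
  )
}

#' Tidy a QC accumulator into report tables
#'
#' @param x A `qc_stats` object.
#' @param type Which table: `"position_quality"` (mean Phred per 1-based
#'   position), `"read_quality"` (read counts and percentages per
#'   mean-quality bin), `"gc"` (read counts and percentages per GC bin) or
#'   `"base_composition"` (percent A/C/G/T/N per position).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.qc_stats <- function(x, type = c("position_quality", "read_quality",
                                      "gc", "base_composition"), ...) {
  type <- match.arg(type)
  switch(
    type,
    position_quality = tibble(
      position = seq_along(x$pos_count),
      n_reads = x$pos_count,
      mean_quality = ifelse(x$pos_count > 0,
                            x$pos_qual_sum / x$pos_count, NA_real_)
    ),
    read_quality = tibble(
      quality_bin = 0:60,
      n_reads = x$read_q_hist,
      percent = if (x$n_reads > 0) 100 * x$read_q_hist / x$n_reads
                else rep(NA_real_, 61L)
    ),
    gc = {
      binned <- x$n_reads - x$n_no_called
      tibble(
        gc_bin = 0:100,
        n_reads = x$gc_hist,
        percent = if (binned > 0) 100 * x$gc_hist / binned
                  else rep(NA_real_, 101L)
      )
    },
    base_composition = {
      npos <- ncol(x$base_counts)
      cnt <- as.vector(x$base_counts)  # column-major: 5 bases per position
      tot <- rep(x$pos_count, each = 5L)
      tibble(
        position = rep(seq_len(npos), each = 5L),
        base = rep(names(BASE_CODES), times = npos),
        n_bases = cnt,
        percent = ifelse(tot > 0, 100 * cnt / tot, NA_real_)
      )
    }
  )
}
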