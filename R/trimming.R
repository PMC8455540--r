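#' Define the adapter set used for 3' adapter trimming
#'
#' Adapters may be given as a character vector, a single comma-separated
#' string, or the path to a FASTA file (headers ignored). List order is
#' preserved and used to break ties when two adapters match at the same
#' position.
#'
#' @param adapters Adapter sequences over A/C/G/T, each at least 5 bases.
#' @param max_mismatch_fraction Allowed Hamming mismatches as a fraction of
#'   the aligned length, in `[0, 1)`. Default 0 (exact matching).
#' @return An `adapter_set` object.
#' @export
adapter_set <- function(adapters, max_mismatch_fraction = 0) {
  if (is.character(adapters) && length(adapters) == 1L && file.exists(adapters)) {
    adapters <- read_adapter_fasta(adapters)
  } else if (is.character(adapters) && length(adapters) == 1L &&
             grepl(",", adapters, fixed = TRUE)) {
    adapters <- strsplit(adapters, ",", fixed = TRUE)[[1]]
  }
  adapters <- toupper(trimws(adapters))
  adapters <- adapters[nzchar(adapters)]
  if (length(adapters) == 0L) abort("no adapter sequences supplied")
  if (any(grepl("[^ACGT]", adapters))) {
    abort("adapter sequences may only contain A, C, G, T")
  }
  if (any(nchar(adapters) < 5L)) {
    abort("adapter sequences must be at least 5 bases long")
  }
  if (!is.numeric(max_mismatch_fraction) || length(max_mismatch_fraction) != 1L ||
      is.na(max_mismatch_fraction) ||
      max_mismatch_fraction < 0 || max_mismatch_fraction >= 1) {
    abort("`max_mismatch_fraction` must be in [0, 1)")
  }
  structure(
    list(adapters = adapters, max_mismatch_fraction = max_mismatch_fraction),
    class = "adapter_set"
  )
}

#' @export
print.adapter_set <- function(x, ...) {
  cat(sprintf(
    "<adapter_set> %d adapter(s), max mismatch fraction %g\n",
    length(x$adapters), x$max_mismatch_fraction
  ))
  invisible(x)
}

as_adapter_set <- function(x) {
  if (inherits(x, "adapter_set")) return(x)
  adapter_set(x)
}

read_adapter_fasta <- function(path) {
  lines <- read_lines_auto(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    abort(sprintf("adapter file %s is not FASTA", path))
  }
  rec <- cumsum(startsWith(lines, ">"))
  seqs <- vapply(
    split(lines[!startsWith(lines, ">")], rec[!startsWith(lines, ">")]),
    paste0, character(1), collapse = ""
  )
  unname(seqs)
}

# earliest acceptable alignment of one adapter within one read, 0-based start
# position, or Inf when absent. A partial 3'-suffix overlap needs >= 5 aligned
# bases; exact-mode uses substring search, mismatch-mode scans positions.
match_one_adapter <- function(seq, rlen, adapter, alen, mmf) {
  if (rlen == 0L) return(Inf)
  if (mmf == 0) {
    if (rlen >= alen) {
      hit <- regexpr(adapter, seq, fixed = TRUE)
      if (hit > 0L) return(hit - 1L)
    }
    # 3' partial overlap: longest read-suffix == adapter-prefix wins the
    # smallest start position
    for (k in seq.int(min(alen - 1L, rlen), 5L)) {
      if (k < 5L) break
      if (substring(seq, rlen - k + 1L, rlen) ==
          substring(adapter, 1L, k)) {
        return(rlen - k)
      }
    }
    return(Inf)
  }
  rc <- strsplit(seq, "", fixed = TRUE)[[1]]
  ac <- strsplit(adapter, "", fixed = TRUE)[[1]]
  for (p in 0:(rlen - 1L)) {
    aligned <- min(alen, rlen - p)
    if (aligned < alen && aligned < 5L) break  # only shorter overlaps remain
    allowed <- floor(mmf * aligned)
    mism <- sum(rc[(p + 1L):(p + aligned)] != ac[seq_len(aligned)])
    if (mism <= allowed) return(p)
  }
  Inf
}

#' Locate the leftmost adapter occurrence in each read
#'
#' For every adapter the smallest start position is found at which it aligns
#' with Hamming mismatches at most `floor(max_mismatch_fraction *
#' aligned_length)`; an `N` in the read always counts as a mismatch. Partial
#' overlap hanging off the 3' end needs at least 5 aligned bases. Among
#' adapters, the smallest start wins; ties go to the earliest adapter in the
#' set.
#'
#' @param sequences Character vector of (uppercase) read sequences.
#' @param adapters An [adapter_set()] (or something coercible to one).
#' @return A tibble with one row per input sequence: `adapter` (index into
#'   the set, `NA` when absent), `start` (1-based position of the first
#'   adapter base, `NA` when absent) and `keep_length` (bases retained 5' of
#'   the match; the read length when absent).
#' @export
find_adapter <- function(sequences, adapters) {
  adapters <- as_adapter_set(adapters)
  ads <- adapters$adapters
  alens <- nchar(ads)
  mmf <- adapters$max_mismatch_fraction
  rlens <- nchar(sequences)
  n <- length(sequences)
  a_idx <- rep(NA_integer_, n)
  pos0 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    best_p <- Inf
    best_a <- NA_integer_
    for (ai in seq_along(ads)) {
      p <- match_one_adapter(sequences[i], rlens[i], ads[ai], alens[ai], mmf)
      if (p < best_p) {  # strict: earliest adapter wins ties
        best_p <- p
        best_a <- ai
      }
    }
    if (is.finite(best_p)) {
      a_idx[i] <- best_a
      pos0[i] <- best_p
    }
  }
  tibble(
    adapter = a_idx,
    start = ifelse(is.na(pos0), NA_integer_, as.integer(pos0 + 1)),
    keep_length = as.integer(ifelse(is.na(pos0), rlens, pos0))
  )
}

#' Trim adapter read-through from the 3' end of each read
#'
#' When an adapter match is found, the adapter and everything 3' of it are
#' removed (read-through model): sequence and quality are truncated to the
#' bases preceding the match. A match at position 1 empties the read, which
#' the downstream length filter then rejects.
#'
#' @param reads A reads tibble.
#' @param adapters An [adapter_set()].
#' @return The reads tibble with `sequence`/`quality` truncated and an
#'   `adapter_bases_removed` column added.
#' @export
trim_adapter <- function(reads, adapters) {
  assert_reads(reads)
  if (nrow(reads) == 0L) {
    reads$adapter_bases_removed <- integer()
    return(reads)
  }
  hits <- find_adapter(reads$sequence, adapters)
  old_len <- nchar(reads$sequence)
  keep <- hits$keep_length
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  reads$adapter_bases_removed <- old_len - keep
  reads
}

#' Trim the low-quality 3' suffix of each read
#'
#' Removes the maximal suffix in which every base scores below
#' `per_base_threshold`: scanning from the 3' end, bases are dropped while
#' their Phred score is below the threshold and scanning stops at the first
#' base at or above it. A fixed-threshold suffix rule (rather than a sliding
#' window) is deterministic and idempotent.
#'
#' @param reads A reads tibble.
#' @param per_base_threshold Phred threshold (>= 0).
#' @param encoding A [quality_encoding()].
#' @return The reads tibble with `sequence`/`quality` truncated and a
#'   `quality_bases_removed` column added.
#' @export
trim_quality_3prime <- function(reads, per_base_threshold, encoding) {
  assert_reads(reads)
  if (per_base_threshold < 0) abort("`per_base_threshold` must be >= 0")
  if (nrow(reads) == 0L) {
    reads$quality_bases_removed <- integer()
    return(reads)
  }
  scores <- phred_list(reads$quality, encoding, reads$read_id)
  keep <- vapply(scores, function(s) {
    ok <- which(s >= per_base_threshold)
    if (length(ok)) max(ok) else 0L
  }, integer(1))
  old_len <- nchar(reads$sequence)
  reads$sequence <- substr(reads$sequence, 1L, keep)
  reads$quality <- substr(reads$quality, 1L, keep)
  reads$quality_bases_removed <- old_len - keep
  reads
}
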