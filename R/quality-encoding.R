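ENCODING_NAMES <- c("sanger_illumina18", "solexa", "illumina13", "illumina15")

#' Construct a quality-encoding descriptor
#'
#' The four historical Illumina quality variants are supported:
#' Sanger / Illumina 1.8+ (Phred+33), Solexa (offset-64 log-odds scores),
#' Illumina 1.3 (Phred+64) and Illumina 1.5 (Phred+64).
#'
#' @param name One of `"sanger_illumina18"`, `"solexa"`, `"illumina13"`,
#'   `"illumina15"` (the alias `"sanger"` is accepted).
#' @return A `quality_encoding` object with fields `name`, `ascii_offset`
#'   and `is_solexa`.
#' @export
quality_encoding <- function(name) {
  if (identical(name, "sanger")) name <- "sanger_illumina18"
  name <- match.arg(name, ENCODING_NAMES)
  structure(
    list(
      name = name,
      ascii_offset = if (name == "sanger_illumina18") 33L else 64L,
      is_solexa = name == "solexa"
    ),
    class = "quality_encoding"
  )
}

#' @export
print.quality_encoding <- function(x, ...) {
  cat(sprintf(
    "<quality_encoding> %s (ASCII offset %d%s)\n",
    x$name, x$ascii_offset, if (x$is_solexa) ", Solexa log-odds" else ""
  ))
  invisible(x)
}

as_quality_encoding <- function(x) {
  if (inherits(x, "quality_encoding")) return(x)
  quality_encoding(x)
}

#' Detect the FASTQ quality encoding from a sample of reads
#'
#' Scans the quality characters of up to `sample_size` reads and classifies
#' the variant from the minimum ASCII code `m` observed, using the classical
#' range disambiguation: `m < 59` is Sanger/Illumina 1.8+, `59 <= m < 64` is
#' Solexa, `64 <= m < 66` is Illumina 1.3 and `m >= 66` is Illumina 1.5.
#' Data whose codes all fall in 66--74 are compatible with uniformly
#' high-quality offset-33 data too; a warning is emitted but the min-based
#' rule still returns Illumina 1.5 (use a forced encoding for such inputs).
#'
#' @param reads A reads tibble, or a character vector of quality strings.
#' @param sample_size Maximum number of reads inspected (default 100000).
#' @return A [quality_encoding()] object.
#' @export
detect_encoding <- function(reads, sample_size = 100000L) {
  quals <- if (is.data.frame(reads)) reads$quality else reads
  quals <- utils::head(quals, sample_size)
  bytes <- charToRaw(paste(quals, collapse = ""))
  if (length(bytes) == 0L) {
    abort("cannot detect encoding: no quality characters in the sample")
  }
  codes <- as.integer(bytes)
  m <- min(codes)
  M <- max(codes)
  name <-
    if (m < 59L) "sanger_illumina18"
    else if (m < 64L) "solexa"
    else if (m < 66L) "illumina13"
    else "illumina15"
  if (m >= 66L && M <= 74L) {
    warn(paste0(
      "quality codes all in 66-74: compatible with high-quality offset-33 ",
      "data as well as Illumina 1.5; returning illumina15 by the min-ASCII rule"
    ))
  }
  quality_encoding(name)
}

solexa_to_phred <- function(s) {
  10 * log10(10 ^ (s / 10) + 1)
}

#' Decode one quality string to per-base Phred scores
#'
#' For offset-33/64 encodings the score is `ascii(q) - offset`. Solexa
#' characters encode log-odds scores `s = ascii(q) - 64` (which may be as low
#' as -5) and are converted to the Phred scale by
#' `10 * log10(10^(s/10) + 1)`, reported unrounded.
#'
#' @param quality A single quality string.
#' @param encoding A [quality_encoding()] (or its name).
#' @return Numeric vector of Phred scores, one per base.
#' @export
decode_quality <- function(quality, encoding) {
  encoding <- as_quality_encoding(encoding)
  codes <- as.integer(charToRaw(quality))
  if (encoding$is_solexa) {
    s <- codes - 64L
    bad <- which(s < -5L)
    if (length(bad)) {
      abort(sprintf(
        "quality character '%s' at position %d is below the Solexa range",
        substr(quality, bad[1], bad[1]), bad[1]
      ))
    }
    return(solexa_to_phred(s))
  }
  scores <- codes - encoding$ascii_offset
  bad <- which(scores < 0L)
  if (length(bad)) {
    abort(sprintf(
      "quality character '%s' at position %d is below the ASCII offset %d (is the encoding forced correctly?)",
      substr(quality, bad[1], bad[1]), bad[1], encoding$ascii_offset
    ))
  }
  as.numeric(scores)
}

#' Mean of a read's Phred scores
#'
#' The per-read quality statistic used by the default filter is the
#' arithmetic mean of the per-base Phred scores.
#'
#' @param phred_scores Nonempty numeric vector of Phred scores.
#' @return The arithmetic mean.
#' @export
mean_quality <- function(phred_scores) {
  if (length(phred_scores) == 0L) {
    abort("mean_quality of a zero-length read is undefined; apply the length filter first")
  }
  mean(phred_scores)
}

# --- vectorized internals ---------------------------------------------------

# list of per-base score vectors, one element per read
phred_list <- function(qualities, encoding, read_ids = NULL) {
  encoding <- as_quality_encoding(encoding)
  offset <- if (encoding$is_solexa) 64L else encoding$ascii_offset
  floor_code <- if (encoding$is_solexa) 59L else encoding$ascii_offset
  out <- lapply(qualities, function(q) as.integer(charToRaw(q)))
  low <- vapply(out, function(v) length(v) > 0L && min(v) < floor_code, logical(1))
  if (any(low)) {
    i <- which(low)[1]
    id <- if (!is.null(read_ids)) read_ids[i] else sprintf("#%d", i)
    abort(sprintf(
      "read '%s' has a quality character below the detected encoding's range (%s)",
      id, encoding$name
    ))
  }
  if (encoding$is_solexa) {
    lapply(out, function(v) solexa_to_phred(v - 64L))
  } else {
    lapply(out, function(v) as.numeric(v - offset))
  }
}

# per-read mean Phred; NA for zero-length reads
mean_qualities <- function(qualities, encoding, read_ids = NULL) {
  scores <- phred_list(qualities, encoding, read_ids)
  vapply(scores, function(s) if (length(s)) mean(s) else NA_real_, double(1))
}
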