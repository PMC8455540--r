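#' Open a FASTQ/FASTA file as a text stream, decompressing gzip automatically
#'
#' Compression is detected from the gzip magic bytes (`0x1f 0x8b`), never from
#' the filename, so a gzip stream stored under a plain `.fastq` name is still
#' decompressed (and vice versa).
#'
#' @param path Path to an existing file.
#' @return An open read-mode text connection. The caller must `close()` it.
#' @examples
#' f <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), f)
#' con <- open_stream_auto(f)
#' readLines(con)
#' close(con)
#' @export
open_stream_auto <- function(path) {
  check_path_exists(path)
  if (is_gzip_file(path)) gzfile(path, "rt") else file(path, "rt")
}

# read all lines, decompressing by magic; rethrows decode failures as a
# corrupt-gzip error naming the path
read_lines_auto <- function(path, n_max = -1L) {
  con <- open_stream_auto(path)
  on.exit(close(con))
  tryCatch(
    readLines(con, n = n_max, warn = FALSE),
    error = function(e) {
      abort(sprintf("corrupt gzip stream in %s: %s", path, conditionMessage(e)))
    }
  )
}

# Validate and assemble 4-line FASTQ blocks into the reads tibble.
# `first_record` offsets the record index reported in error messages when
# parsing a byte-range chunk out of a larger file.
parse_fastq_lines <- function(lines, source = "<stream>", first_record = 1L) {
  n <- length(lines)
  if (n == 0L) return(new_reads())
  if (n %% 4L != 0L) {
    abort(sprintf(
      "truncated FASTQ record in %s: file ends mid-record at record %d",
      source, n %/% 4L + first_record
    ))
  }
  headers <- lines[seq.int(1L, n, by = 4L)]
  seqs    <- lines[seq.int(2L, n, by = 4L)]
  seps    <- lines[seq.int(3L, n, by = 4L)]
  quals   <- lines[seq.int(4L, n, by = 4L)]

  bad <- which(!startsWith(headers, "@"))
  if (length(bad)) {
    abort(sprintf(
      "malformed FASTQ in %s: header at line %d does not start with '@'",
      source, (bad[1] - 1L) * 4L + 1L
    ))
  }
  bad <- which(!startsWith(seps, "+"))
  if (length(bad)) {
    abort(sprintf(
      "malformed FASTQ in %s: separator at line %d does not start with '+'",
      source, (bad[1] - 1L) * 4L + 3L
    ))
  }

  seqs <- toupper(seqs)
  body <- substring(headers, 2L)
  read_id <- sub("^(\\S*).*$", "\\1", body)
  description <- sub("^\\S*[ \t]?", "", body)

  bad <- which(grepl("[^ACGTN]", seqs))
  if (length(bad)) {
    abort(sprintf(
      "invalid base in read '%s' in %s: sequence may only contain A, C, G, T or N",
      read_id[bad[1]], source
    ))
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort(sprintf(
      "length mismatch in read '%s' in %s: %d bases but %d quality characters",
      read_id[bad[1]], source, nchar(seqs[bad[1]]), nchar(quals[bad[1]])
    ))
  }
  bad <- which(grepl("[^\\x21-\\x7e]", quals, perl = TRUE))
  if (length(bad)) {
    abort(sprintf(
      "invalid quality character in read '%s' in %s: outside printable ASCII 33-126",
      read_id[bad[1]], source
    ))
  }
  new_reads(read_id, description, seqs, quals)
}

#' Read a FASTQ file into a tibble of reads
#'
#' Strictly 4-line records: header starting `@`, sequence over
#' `A/C/G/T/N` (lowercase uppercased on read), separator starting `+`, and a
#' quality string of printable ASCII (33--126) the same length as the
#' sequence. Wrapped multi-line FASTQ is rejected: Illumina writers emit
#' 4-line records and wrapping is ambiguous when quality strings start
#' with `@`. Gzip input is detected by magic bytes.
#'
#' @param path Path to a FASTQ file, plain or gzip.
#' @param n_max Maximum number of records to read (default all).
#' @return A tibble with columns `read_id`, `description`, `sequence`,
#'   `quality`, one row per read, in file order.
#' @seealso [write_fastq()], [read_paired()]
#' @export
read_fastq <- function(path, n_max = Inf) {
  line_cap <- if (is.finite(n_max)) as.integer(n_max) * 4L else -1L
  lines <- read_lines_auto(path, n_max = line_cap)
  parse_fastq_lines(lines, source = path)
}

fastq_block_lines <- function(reads) {
  header <- ifelse(
    !is.null(reads$description) & nzchar(reads$description %||% ""),
    paste0("@", reads$read_id, " ", reads$description),
    paste0("@", reads$read_id)
  )
  as.vector(rbind(header, reads$sequence, "+", reads$quality))
}

#' Write reads to a FASTQ file
#'
#' @param reads A reads tibble (see [read_fastq()]).
#' @param path Output path.
#' @param gzip_out Compress the output with gzip?
#' @return Invisibly, the number of records written.
#' @export
write_fastq <- function(reads, path, gzip_out = FALSE) {
  assert_reads(reads)
  con <- if (gzip_out) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(fastq_block_lines(reads), con, sep = "\n")
  }
  invisible(nrow(reads))
}

#' Write reads to a FASTA file (quality discarded)
#'
#' Each record becomes one `>` header line and one sequence line, in input
#' order, so the sequences match the corresponding FASTQ output exactly.
#'
#' @inheritParams write_fastq
#' @return Invisibly, the number of records written.
#' @export
write_fasta <- function(reads, path) {
  assert_reads(reads)
  header <- ifelse(
    !is.null(reads$description) & nzchar(reads$description %||% ""),
    paste0(">", reads$read_id, " ", reads$description),
    paste0(">", reads$read_id)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(as.vector(rbind(header, reads$sequence)), con, sep = "\n")
  }
  invisible(nrow(reads))
}

#' Strip the trailing mate designator from read identifiers
#'
#' Removes a trailing `/1` or `/2`. Casava 1.8-style headers
#' (`@id 1:N:0:...`) carry the mate number in the description, so both mates
#' already share an identical `read_id` and are returned unchanged.
#'
#' @param read_id Character vector of read identifiers.
#' @return Character vector of pair keys.
#' @export
pair_key <- function(read_id) {
  sub("/[12]$", "", read_id)
}

#' Read two FASTQ files as synchronized read pairs
#'
#' Records are paired in lockstep. A pair-key mismatch at any position, or
#' unequal record counts, is a fatal error: desynchronized input is never
#' silently repaired, dropped or reordered.
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files.
#' @return A tibble with `pair_key` plus the two mates' fields suffixed
#'   `_1` and `_2`.
#' @export
read_paired <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2)) {
    shorter <- if (nrow(r1) < nrow(r2)) path1 else path2
    abort(sprintf(
      "pair desynchronization: %s has %d records but %s has %d (input exhausted at the end of %s)",
      path1, nrow(r1), path2, nrow(r2), shorter
    ))
  }
  k1 <- pair_key(r1$read_id)
  k2 <- pair_key(r2$read_id)
  bad <- which(k1 != k2)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      "read pair mismatch at record %d: '%s' in %s does not pair with '%s' in %s",
      i, r1$read_id[i], path1, r2$read_id[i], path2
    ))
  }
  out <- tibble(
    pair_key = k1,
    read_id_1 = r1$read_id, description_1 = r1$description,
    sequence_1 = r1$sequence, quality_1 = r1$quality,
    read_id_2 = r2$read_id, description_2 = r2$description,
    sequence_2 = r2$sequence, quality_2 = r2$quality
  )
  out
}

# Scan forward from an arbitrary byte offset of a plain (decompressed) FASTQ
# file to the next true record boundary. A candidate line starting '@' is
# accepted only if the following 3 lines parse as a record body (sequence over
# ACGTN, separator starting '+', quality of equal length); this rejects
# quality lines that happen to begin with '@', because the line after a
# quality line is a header whose leading '@' is not a legal base.
next_record_start <- function(path, pos, fsize, window = 4L * 1024L^2L) {
  if (pos <= 0L) return(0)
  con <- file(path, "rb")
  on.exit(close(con))
  repeat {
    seek(con, pos)
    buf <- readBin(con, "raw", n = window)
    got <- length(buf)
    if (got == 0L) return(fsize)
    at_eof <- (pos + got) >= fsize
    txt <- rawToChar(buf)
    pieces <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    # byte offset (absolute) at which each piece begins; piece 1 is the tail
    # of the line containing `pos` and is never a candidate
    starts <- pos + c(0, cumsum(nchar(pieces, type = "bytes") + 1L))
    nlines <- length(pieces)
    for (i in seq_len(nlines)[-1]) {
      if (i + 3L > nlines) break
      line4_complete <- (i + 3L < nlines) || at_eof
      if (!line4_complete) break
      l1 <- pieces[i]
      if (!startsWith(l1, "@")) next
      l2 <- pieces[i + 1L]; l3 <- pieces[i + 2L]; l4 <- pieces[i + 3L]
      if (!startsWith(l3, "+")) next
      if (nchar(l2) != nchar(l4)) next
      if (grepl("[^ACGTNacgtn]", l2)) next
      return(starts[i])
    }
    if (at_eof) return(fsize)
    window <- window * 2L  # no boundary found in the window; widen and retry
  }
}

count_records_range <- function(path, start_byte, end_byte) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, start_byte)
  buf <- readBin(con, "raw", n = end_byte - start_byte)
  nl <- sum(buf == as.raw(10L))
  # tolerate a missing final newline at EOF
  if (length(buf) > 0L && buf[length(buf)] != as.raw(10L)) nl <- nl + 1L
  if (nl %% 4L != 0L) {
    abort(sprintf(
      "chunk of %s [%d, %d) does not hold whole FASTQ records",
      path, start_byte, end_byte
    ))
  }
  nl %/% 4L
}

# read the records inside one chunk byte-range of a plain FASTQ file
read_fastq_range <- function(path, start_byte, end_byte, first_record = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, start_byte)
  buf <- readBin(con, "raw", n = end_byte - start_byte)
  if (length(buf) == 0L) return(new_reads())
  txt <- rawToChar(buf)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  parse_fastq_lines(lines, source = path, first_record = first_record)
}

#' Split a FASTQ file into record-aligned byte chunks
#'
#' Produces at most `n_chunks` non-overlapping byte ranges that cover the file
#' exactly once and always fall on 4-line record boundaries, so reading the
#' chunks in order reproduces a single-pass read with no duplicates or gaps.
#' Boundaries are found by seeking to an approximate offset and scanning
#' forward to the next verifiable record start. Gzip inputs are first
#' decompressed to a temporary plain file (gzip streams are not byte-seekable
#' at record granularity); its path is returned in `source_path` and recorded
#' in the `"decompressed_tmp"` attribute so callers can delete it.
#'
#' @param path FASTQ file, plain or gzip.
#' @param n_chunks Desired number of chunks (positive integer).
#' @param tmpdir Directory for the decompressed copy of a gzip input.
#' @return A tibble with columns `source_path`, `start_byte`, `end_byte`,
#'   `record_count`.
#' @export
split_chunks <- function(path, n_chunks, tmpdir = tempdir()) {
  check_path_exists(path)
  if (!is.numeric(n_chunks) || length(n_chunks) != 1L || is.na(n_chunks) ||
      n_chunks < 1) {
    abort("`n_chunks` must be a positive integer")
  }
  n_chunks <- as.integer(n_chunks)

  tmp <- NULL
  src <- path
  if (is_gzip_file(path)) {
    tmp <- tempfile(fileext = ".fastq", tmpdir = tmpdir)
    lines <- read_lines_auto(path)
    writeLines(lines, tmp, sep = "\n")
    src <- tmp
  }
  fsize <- file.size(src)
  if (fsize == 0L) {
    out <- tibble(
      source_path = character(), start_byte = double(),
      end_byte = double(), record_count = integer()
    )
    attr(out, "decompressed_tmp") <- tmp
    return(out)
  }
  approx <- floor(fsize * seq_len(n_chunks - 1L) / n_chunks)
  cuts <- vapply(approx, next_record_start, double(1), path = src, fsize = fsize)
  starts <- sort(unique(c(0, cuts)))
  starts <- starts[starts < fsize]
  ends <- c(starts[-1], fsize)
  counts <- mapply(count_records_range, start_byte = starts, end_byte = ends,
                   MoreArgs = list(path = src))
  keep <- counts > 0L
  out <- tibble(
    source_path = src,
    start_byte = starts[keep],
    end_byte = ends[keep],
    record_count = as.integer(counts[keep])
  )
  attr(out, "decompressed_tmp") <- tmp
  out
}
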