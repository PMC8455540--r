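# small in-code builders shared across test files

mk_reads <- function(sequence, quality, read_id = NULL, description = NULL) {
  n <- length(sequence)
  tibble::tibble(
    read_id = read_id %||% sprintf("r%d", seq_len(n)),
    description = description %||% rep("", n),
    sequence = sequence,
    quality = quality
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quality string from integer Phred scores at a given offset
qstr <- function(scores, offset = 33L) intToUtf8(scores + offset)

write_tmp_fastq <- function(reads, gzip = FALSE, dir = tempdir()) {
  path <- tempfile(fileext = if (gzip) ".fastq.gz" else ".fastq",
                   tmpdir = dir)
  write_fastq(reads, path, gzip_out = gzip)
  path
}

read_lines_plain <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
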