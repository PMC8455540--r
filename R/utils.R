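#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# ASCII codes of the 5-letter read alphabet, in reporting order
BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L, N = 78L)

# gzip RFC 1952 magic bytes
is_gzip_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# "sample_R1.fastq.gz" -> "sample_R1"
strip_fastq_ext <- function(path) {
  stem <- basename(path)
  stem <- sub("\\.gz$", "", stem)
  sub("\\.(fastq|fq|fasta|fa|fas)$", "", stem)
}

check_path_exists <- function(path) {
  if (!is.character(path) || length(path) != 1L || is.na(path)) {
    abort("expected a single file path")
  }
  if (!file.exists(path)) {
    abort(sprintf("input file not found: %s", path))
  }
  invisible(path)
}

# shared constructor for the reads tibble used throughout the package
new_reads <- function(read_id = character(), description = character(),
                      sequence = character(), quality = character()) {
  tibble(
    read_id = read_id, description = description,
    sequence = sequence, quality = quality
  )
}

assert_reads <- function(reads, arg = "reads") {
  required <- c("read_id", "sequence", "quality")
  if (!is.data.frame(reads) || !all(required %in% names(reads))) {
    abort(sprintf(
      "`%s` must be a data frame with columns read_id, sequence and quality",
      arg
    ))
  }
  invisible(reads)
}
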