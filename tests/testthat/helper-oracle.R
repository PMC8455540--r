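# Independent brute-force re-computation of the trim + filter pipeline,
# working directly on the raw 4-line FASTQ text. Deliberately written as
# plain character-by-character loops, sharing no code with the package.

oracle_phred <- function(qual, offset = 33L, solexa = FALSE) {
  codes <- utf8ToInt(qual)
  if (solexa) 10 * log10(10 ^ ((codes - 64) / 10) + 1) else codes - offset
}

# leftmost position (0-based) where an adapter matches with at most
# floor(mmf * aligned) mismatches; full alignment or >= 5-base 3' overlap
oracle_adapter_pos <- function(seq, adapters, mmf = 0) {
  sc <- strsplit(seq, "")[[1]]
  rlen <- length(sc)
  best <- Inf
  for (ad in adapters) {
    ac <- strsplit(ad, "")[[1]]
    alen <- length(ac)
    for (p in 0:(rlen - 1)) {
      if (p >= best) break
      aligned <- min(alen, rlen - p)
      if (aligned < alen && aligned < 5) next
      mism <- 0
      for (j in seq_len(aligned)) {
        if (sc[p + j] != ac[j]) mism <- mism + 1
      }
      if (mism <= floor(mmf * aligned)) {
        best <- min(best, p)
        break
      }
    }
  }
  if (is.finite(best)) best else -1
}

# per-read verdicts for a whole raw FASTQ file under one configuration
oracle_evaluate_file <- function(path,
                                 min_mean_quality = 20,
                                 max_n = NULL,
                                 max_n_fraction = NULL,
                                 min_length = 0,
                                 trim_quality_threshold = NULL,
                                 adapters = NULL,
                                 adapter_mismatch = 0,
                                 offset = 33L, solexa = FALSE) {
  lines <- read_lines_plain(path)
  stopifnot(length(lines) %% 4 == 0)
  n <- length(lines) %/% 4
  out <- data.frame(
    read_id = character(n), status = character(n), reason = character(n),
    kept_length = integer(n), trimmed = logical(n),
    adapter_removed = integer(n), quality_removed = integer(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    hdr <- lines[4 * i - 3]
    seq <- toupper(lines[4 * i - 2])
    qual <- lines[4 * i]
    id <- sub("\\s.*$", "", substring(hdr, 2))
    orig_len <- nchar(seq)
    a_rm <- 0L
    if (!is.null(adapters)) {
      p <- oracle_adapter_pos(seq, adapters, adapter_mismatch)
      if (p >= 0) {
        a_rm <- nchar(seq) - p
        seq <- substring(seq, 1, p)
        qual <- substring(qual, 1, p)
      }
    }
    q_rm <- 0L
    if (!is.null(trim_quality_threshold) && nchar(qual) > 0) {
      ph <- oracle_phred(qual, offset, solexa)
      keep <- length(ph)
      while (keep > 0 && ph[keep] < trim_quality_threshold) keep <- keep - 1
      q_rm <- nchar(seq) - keep
      seq <- substring(seq, 1, keep)
      qual <- substring(qual, 1, keep)
    }
    len <- nchar(seq)
    nN <- sum(strsplit(seq, "")[[1]] == "N")
    reason <- "none"
    if (len < max(min_length, 1)) {
      reason <- "too_short"
    } else if (!is.null(max_n) && nN > max_n) {
      reason <- "too_many_n"
    } else if (!is.null(max_n_fraction) && nN / len > max_n_fraction) {
      reason <- "too_many_n"
    } else {
      ph <- oracle_phred(qual, offset, solexa)
      if (mean(ph) < min_mean_quality) reason <- "low_mean_quality"
    }
    out$read_id[i] <- id
    out$status[i] <- if (reason == "none") "pass" else "fail"
    out$reason[i] <- reason
    out$kept_length[i] <- len
    out$trimmed[i] <- (a_rm + q_rm) > 0
    out$adapter_removed[i] <- a_rm
    out$quality_removed[i] <- q_rm
  }
  out
}
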