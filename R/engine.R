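READ_COLS <- c("read_id", "description", "sequence", "quality")

tally_vector <- function(pass = 0L, too_short = 0L, too_many_n = 0L,
                         low_mean_quality = 0L, trimmed = 0L,
                         orphans_dropped = 0L) {
  c(pass = pass, too_short = too_short, too_many_n = too_many_n,
    low_mean_quality = low_mean_quality, trimmed = trimmed,
    orphans_dropped = orphans_dropped)
}

count_reason <- function(v, reason) sum(v$fail_reason == reason)

# Trim + filter + route one batch of reads (one chunk, or the whole file).
# Returns the routed read tibbles plus mergeable stats, tallies and base
# accounting. `stats_clean` covers every retained read, including orphans
# routed to the unpaired outputs.
process_reads <- function(r1, r2 = NULL, config = filter_config(),
                          encoding, keep_orphans = FALSE) {
  v1 <- evaluate_reads(r1, config, encoding)
  stats_raw <- qc_stats(r1, encoding)
  if (is.null(r2)) {
    retained <- v1$status == "pass"
    clean1 <- v1[retained, READ_COLS]
    rejects1 <- v1[!retained, READ_COLS]
    stats_clean <- qc_stats(clean1, encoding)
    tallies <- tally_vector(
      pass = sum(retained),
      too_short = count_reason(v1, "too_short"),
      too_many_n = count_reason(v1, "too_many_n"),
      low_mean_quality = count_reason(v1, "low_mean_quality"),
      trimmed = sum(retained & v1$was_trimmed)
    )
    bases <- c(
      adapter_removed = sum(v1$adapter_bases_removed[retained]),
      quality_removed = sum(v1$quality_bases_removed[retained]),
      rejected = sum(nchar(r1$sequence)[!retained])
    )
    return(list(
      clean1 = clean1, clean2 = NULL, orphan1 = NULL, orphan2 = NULL,
      rejects1 = rejects1, rejects2 = NULL,
      stats_raw = stats_raw, stats_clean = stats_clean,
      tallies = tallies, bases = bases
    ))
  }

  v2 <- evaluate_reads(r2, config, encoding)
  stats_raw <- merge_stats(stats_raw, qc_stats(r2, encoding))
  routing <- resolve_pair(v1, v2, keep_orphans)
  bp <- routing == "both_pass"
  retained1 <- bp | routing == "orphan_r1"
  retained2 <- bp | routing == "orphan_r2"
  clean1 <- v1[bp, READ_COLS]
  clean2 <- v2[bp, READ_COLS]
  orphan1 <- v1[routing == "orphan_r1", READ_COLS]
  orphan2 <- v2[routing == "orphan_r2", READ_COLS]
  rejects1 <- v1[!retained1, READ_COLS]
  rejects2 <- v2[!retained2, READ_COLS]
  stats_clean <- Reduce(merge_stats, list(
    qc_stats(clean1, encoding), qc_stats(clean2, encoding),
    qc_stats(orphan1, encoding), qc_stats(orphan2, encoding)
  ))
  tallies <- tally_vector(
    pass = sum(v1$status == "pass") + sum(v2$status == "pass"),
    too_short = count_reason(v1, "too_short") + count_reason(v2, "too_short"),
    too_many_n = count_reason(v1, "too_many_n") + count_reason(v2, "too_many_n"),
    low_mean_quality = count_reason(v1, "low_mean_quality") +
      count_reason(v2, "low_mean_quality"),
    trimmed = sum(retained1 & v1$was_trimmed) + sum(retained2 & v2$was_trimmed),
    orphans_dropped = sum(v1$status == "pass" & !retained1) +
      sum(v2$status == "pass" & !retained2)
  )
  bases <- c(
    adapter_removed = sum(v1$adapter_bases_removed[retained1]) +
      sum(v2$adapter_bases_removed[retained2]),
    quality_removed = sum(v1$quality_bases_removed[retained1]) +
      sum(v2$quality_bases_removed[retained2]),
    rejected = sum(nchar(r1$sequence)[!retained1]) +
      sum(nchar(r2$sequence)[!retained2])
  )
  list(
    clean1 = clean1, clean2 = clean2, orphan1 = orphan1, orphan2 = orphan2,
    rejects1 = rejects1, rejects2 = rejects2,
    stats_raw = stats_raw, stats_clean = stats_clean,
    tallies = tallies, bases = bases
  )
}

# reads + bases conservation; violated only by an internal defect
check_conservation <- function(stats_raw, stats_clean, tallies, bases,
                               keep_orphans) {
  t <- tallies
  lhs_reads <- stats_raw$n_reads
  rhs_reads <- t[["pass"]] + t[["too_short"]] + t[["too_many_n"]] +
    t[["low_mean_quality"]]
  retained <- t[["pass"]] - t[["orphans_dropped"]]
  ok_reads <- lhs_reads == rhs_reads && stats_clean$n_reads == retained
  # original bases of rejected reads = post-trim bases + their trimmed bases;
  # bases[["rejected"]] stores pre-trim lengths directly
  lhs_bases <- stats_raw$n_bases
  rhs_bases <- stats_clean$n_bases + bases[["rejected"]] +
    bases[["adapter_removed"]] + bases[["quality_removed"]]
  if (!ok_reads || lhs_bases != rhs_bases) {
    abort("internal accounting error: read/base conservation violated")
  }
  invisible(TRUE)
}

check_pair_sync_tibbles <- function(r1, r2, path1, path2,
                                    first_record = 1L) {
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf(
      "pair desynchronization: %s and %s hold different record counts", path1, path2
    ))
  }
  k1 <- pair_key(r1$read_id)
  k2 <- pair_key(r2$read_id)
  bad <- which(k1 != k2)
  if (length(bad)) {
    i <- bad[1]
    abort(sprintf(
      "read pair mismatch at record %d: '%s' in %s does not pair with '%s' in %s",
      first_record + i - 1L, r1$read_id[i], path1, r2$read_id[i], path2
    ))
  }
  invisible(TRUE)
}

resolve_encoding <- function(encoding, r1, n_records) {
  if (!identical(encoding, "auto")) return(as_quality_encoding(encoding))
  head_reads <- read_fastq(r1, n_max = 100000L)
  if (nrow(head_reads) == 0L) {
    # empty input: nothing to detect; offset-33 is the modern default
    return(quality_encoding("sanger_illumina18"))
  }
  detect_encoding(head_reads)
}

output_paths <- function(out_dir, stem1, stem2, gzip_out, fasta_out,
                         keep_orphans, save_rejects) {
  ext <- if (fasta_out) "fasta" else if (gzip_out) "fastq.gz" else "fastq"
  rext <- if (gzip_out) "fastq.gz" else "fastq"
  p <- list(clean1 = file.path(out_dir, paste0(stem1, "_clean.", ext)))
  if (!is.null(stem2)) {
    p$clean2 <- file.path(out_dir, paste0(stem2, "_clean.", ext))
    if (keep_orphans) {
      p$orphan1 <- file.path(out_dir, paste0(stem1, "_unpaired.", ext))
      p$orphan2 <- file.path(out_dir, paste0(stem2, "_unpaired.", ext))
    }
  }
  if (save_rejects) {
    p$rejects1 <- file.path(out_dir, paste0(stem1, "_rejected.", rext))
    if (!is.null(stem2)) {
      p$rejects2 <- file.path(out_dir, paste0(stem2, "_rejected.", rext))
    }
  }
  p
}

# rejects keep their quality strings for inspection, so they are always
# FASTQ even when the cleaned output is FASTA
write_reads_out <- function(reads, path, gzip_out, fasta_out, role = "clean") {
  if (fasta_out && !startsWith(role, "rejects")) write_fasta(reads, path)
  else write_fastq(reads, path, gzip_out = gzip_out)
}

finalize_result <- function(sample, files, enc, config, pr,
                            paired, keep_orphans, out_dir, plots) {
  check_conservation(pr$stats_raw, pr$stats_clean, pr$tallies, pr$bases,
                     keep_orphans)
  res <- new_qc_result(
    sample = sample, files = files, encoding = enc, config = config,
    stats_raw = pr$stats_raw, stats_clean = pr$stats_clean,
    tallies = pr$tallies, bases = pr$bases,
    paired = paired, keep_orphans = keep_orphans
  )
  res$files$summary <- render_summary(res, out_dir)
  res$files$tables <- render_plots(res, out_dir, png = plots)
  res
}

common_run_checks <- function(r1, r2, gzip_out, fasta_out) {
  check_path_exists(r1)
  if (!is.null(r2)) check_path_exists(r2)
  if (gzip_out && fasta_out) {
    abort("`gzip_out` and `fasta_out` are mutually exclusive")
  }
}

#' Run the full QC pipeline serially
#'
#' One pass over the input: the quality encoding is detected from the first
#' reads (unless forced), then every read is adapter-trimmed,
#' quality-trimmed, filtered and routed, QC statistics are accumulated for
#' the raw and retained streams, and the cleaned reads, summary table,
#' backing tables and plots are written.
#'
#' @param r1 Path to the (R1) FASTQ file, plain or gzip.
#' @param r2 Optional path to the R2 mate file for paired-end data.
#' @param config A [filter_config()].
#' @param out_dir Output directory; defaults to the input file's directory.
#' @param encoding `"auto"` (detect) or a forced encoding name.
#' @param gzip_out Gzip-compress the cleaned FASTQ output?
#' @param fasta_out Write cleaned reads as FASTA instead of FASTQ
#'   (exclusive with `gzip_out`)?
#' @param keep_orphans For paired input, write a passing mate whose partner
#'   failed to a separate `_unpaired` file instead of dropping the pair.
#' @param save_rejects Also write the discarded reads (post-trim) to a
#'   `_rejected` file.
#' @param plots Render the four PNG plots (the backing tables are always
#'   written)?
#' @param sample_name Sample label used for report file names; defaults to
#'   the R1 file stem.
#' @return A `qc_result` object.
#' @export
run_serial <- function(r1, r2 = NULL, config = filter_config(),
                       out_dir = NULL, encoding = "auto",
                       gzip_out = FALSE, fasta_out = FALSE,
                       keep_orphans = FALSE, save_rejects = FALSE,
                       plots = TRUE, sample_name = NULL) {
  common_run_checks(r1, r2, gzip_out, fasta_out)
  out_dir <- out_dir %||% dirname(r1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem1 <- strip_fastq_ext(r1)
  stem2 <- if (is.null(r2)) NULL else strip_fastq_ext(r2)
  sample <- sample_name %||% stem1

  enc <- resolve_encoding(encoding, r1, 100000L)
  reads1 <- read_fastq(r1)
  reads2 <- NULL
  if (!is.null(r2)) {
    reads2 <- read_fastq(r2)
    check_pair_sync_tibbles(reads1, reads2, r1, r2)
  }
  pr <- process_reads(reads1, reads2, config, enc, keep_orphans)

  paths <- output_paths(out_dir, stem1, stem2, gzip_out, fasta_out,
                        keep_orphans, save_rejects)
  for (role in names(paths)) {
    part <- pr[[role]]
    if (is.null(part)) part <- new_reads()
    write_reads_out(part, paths[[role]], gzip_out, fasta_out, role = role)
  }
  finalize_result(sample, paths, enc, config, pr,
                  paired = !is.null(r2), keep_orphans = keep_orphans,
                  out_dir = out_dir, plots = plots)
}

# byte offsets (0-based) of the given 1-based record indices in a plain file
record_byte_offsets <- function(path, record_idx) {
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", n = file.size(path))
  nl <- which(buf == as.raw(10L))
  vapply(record_idx, function(j) {
    if (j == 1L) 0 else as.double(nl[4L * (j - 1L)])
  }, double(1))
}

plain_copy <- function(path, tmpdir) {
  if (!is_gzip_file(path)) return(path)
  tmp <- tempfile(fileext = ".fastq", tmpdir = tmpdir)
  writeLines(read_lines_auto(path), tmp, sep = "\n")
  tmp
}

#' Run the QC pipeline chunk-parallel
#'
#' The input is split into at most `n_cpus` record-aligned chunks (paired
#' files are split at identical record indices), the encoding is detected
#' once on the file prefix and broadcast to all workers, each chunk is
#' processed independently with the same per-read pipeline as [run_serial()],
#' and chunk part-files are concatenated in chunk order. All final outputs,
#' tables and tallies are byte-identical to a serial run on the same input;
#' intermediate part-files and decompressed temporaries are deleted
#' automatically, on success and on failure.
#'
#' @inheritParams run_serial
#' @param n_cpus Number of worker processes / chunks (default 2).
#' @return A `qc_result` object.
#' @export
run_parallel <- function(r1, r2 = NULL, config = filter_config(),
                         out_dir = NULL, encoding = "auto",
                         n_cpus = 2L,
                         gzip_out = FALSE, fasta_out = FALSE,
                         keep_orphans = FALSE, save_rejects = FALSE,
                         plots = TRUE, sample_name = NULL) {
  common_run_checks(r1, r2, gzip_out, fasta_out)
  if (!is.numeric(n_cpus) || length(n_cpus) != 1L || is.na(n_cpus) ||
      n_cpus < 1) {
    abort("`n_cpus` must be a positive integer")
  }
  n_cpus <- as.integer(n_cpus)
  out_dir <- out_dir %||% dirname(r1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stem1 <- strip_fastq_ext(r1)
  stem2 <- if (is.null(r2)) NULL else strip_fastq_ext(r2)
  sample <- sample_name %||% stem1
  paths <- output_paths(out_dir, stem1, stem2, gzip_out, fasta_out,
                        keep_orphans, save_rejects)

  workdir <- tempfile("htsqc_work_")
  dir.create(workdir)
  on.exit(cleanup_intermediates(workdir), add = TRUE)

  # encoding is hoisted out of the workers: a chunk-local minimum could
  # classify differently and break serial/parallel equivalence
  enc <- resolve_encoding(encoding, r1, 100000L)

  chunks <- split_chunks(r1, n_cpus, tmpdir = workdir)
  n_chunk <- nrow(chunks)
  src2 <- NULL
  offsets2 <- NULL
  if (!is.null(r2)) {
    src2 <- plain_copy(r2, workdir)
    n2 <- count_records_range(src2, 0, file.size(src2))
    if (sum(chunks$record_count) != n2) {
      abort(sprintf(
        "pair desynchronization: %s has %d records but %s has %d",
        r1, sum(chunks$record_count), r2, n2
      ))
    }
    rec_starts <- cumsum(c(1L, chunks$record_count))
    offsets2 <- record_byte_offsets(src2, rec_starts)
  }

  roles <- names(paths)
  worker <- function(i) {
    first_rec <- sum(chunks$record_count[seq_len(i - 1L)]) + 1L
    reads1 <- read_fastq_range(chunks$source_path[i], chunks$start_byte[i],
                               chunks$end_byte[i], first_record = first_rec)
    reads2 <- NULL
    if (!is.null(src2)) {
      reads2 <- read_fastq_range(src2, offsets2[i], offsets2[i + 1L],
                                 first_record = first_rec)
      check_pair_sync_tibbles(reads1, reads2, r1, r2,
                              first_record = first_rec)
    }
    pr <- process_reads(reads1, reads2, config, enc, keep_orphans)
    parts <- list()
    for (role in roles) {
      part <- pr[[role]]
      if (is.null(part)) part <- new_reads()
      ppath <- file.path(workdir, sprintf("chunk%04d_%s_part", i, role))
      # parts carry the final record format; compression is applied once on
      # the merged stream so serial and parallel bytes agree
      write_reads_out(part, ppath, gzip_out = FALSE, fasta_out = fasta_out,
                      role = role)
      parts[[role]] <- ppath
    }
    list(stats_raw = pr$stats_raw, stats_clean = pr$stats_clean,
         tallies = pr$tallies, bases = pr$bases, parts = parts)
  }

  results <- if (n_chunk == 0L) {
    list()
  } else if (n_cpus > 1L && n_chunk > 1L) {
    parallel::mclapply(seq_len(n_chunk), function(i) {
      tryCatch(worker(i), error = function(e) e)
    }, mc.cores = min(n_cpus, n_chunk))
  } else {
    lapply(seq_len(n_chunk), function(i) {
      tryCatch(worker(i), error = function(e) e)
    })
  }
  failed <- vapply(results, function(r) inherits(r, "condition") ||
                     inherits(r, "try-error"), logical(1))
  if (any(failed)) {
    # remove any partial final outputs before propagating the worker error
    suppressWarnings(file.remove(unlist(paths)[file.exists(unlist(paths))]))
    e <- results[[which(failed)[1]]]
    msg <- if (inherits(e, "condition")) conditionMessage(e) else as.character(e)
    abort(sprintf("worker failed while processing chunk %d: %s",
                  which(failed)[1], msg))
  }

  # merge in chunk-index order
  pr <- list(
    stats_raw = Reduce(merge_stats,
                       lapply(results, `[[`, "stats_raw"), empty_qc_stats()),
    stats_clean = Reduce(merge_stats,
                         lapply(results, `[[`, "stats_clean"),
                         empty_qc_stats()),
    tallies = Reduce(`+`, lapply(results, `[[`, "tallies"), tally_vector()),
    bases = Reduce(`+`, lapply(results, `[[`, "bases"),
                   c(adapter_removed = 0, quality_removed = 0, rejected = 0))
  )
  for (role in roles) {
    parts <- vapply(results, function(r) r$parts[[role]], character(1))
    merged <- file.path(workdir, paste0("merged_", role))
    file.create(merged)
    if (length(parts)) file.append(merged, parts)
    if (gzip_out) {
      con <- gzfile(paths[[role]], "wb")
      lines <- readLines(merged, warn = FALSE)
      if (length(lines)) writeLines(lines, con, sep = "\n")
      close(con)
    } else {
      file.copy(merged, paths[[role]], overwrite = TRUE)
    }
  }
  finalize_result(sample, paths, enc, config, pr,
                  paired = !is.null(r2), keep_orphans = keep_orphans,
                  out_dir = out_dir, plots = plots)
}

#' Delete a run's intermediate files
#'
#' Best-effort, idempotent removal of the per-run working directory holding
#' chunk part-files and decompressed temporaries. Final outputs are never
#' touched (they live in the output directory, not the working directory).
#'
#' @param workdir The working directory of a completed or failed run.
#' @return Invisibly, `NULL`.
#' @export
cleanup_intermediates <- function(workdir) {
  if (!is.null(workdir) && dir.exists(workdir)) {
    unlink(workdir, recursive = TRUE, force = TRUE)
  }
  invisible(NULL)
}
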