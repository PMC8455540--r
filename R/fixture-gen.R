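#' Specify a seeded synthetic FASTQ fixture
#'
#' Defines reads with fully known ground truth for every pipeline feature:
#' a two-stratum per-read quality model (a fraction `f_low` of reads draw
#' per-base scores uniformly from `low_band`, the rest from `high_band`),
#' optional adapter read-through at a known position in a known fraction of
#' reads, optional uncalled-base spikes, and paired-end output with
#' independently drawn strata per mate. The same spec and seed always
#' produce byte-identical files.
#'
#' The default low band starts at Phred 2, except Illumina 1.3 (score 0)
#' and Solexa (score -5, in Solexa units), so that fixtures generated with
#' `f_low > 0` always contain the low quality codes that make the
#' min-ASCII encoding detection rule decide their variant correctly.
#'
#' @param n_reads Number of reads (per mate).
#' @param read_length Read length in bases. Default 100, a typical Illumina
#'   HiSeq length.
#' @param encoding Quality variant to emit (see [quality_encoding()]).
#' @param f_low Fraction of reads in the low-quality stratum.
#' @param low_band,high_band Integer score bands `c(min, max)` for the two
#'   strata (Solexa units for the Solexa encoding).
#' @param adapter Optional adapter sequence spiked into reads.
#' @param adapter_fraction Fraction of reads contaminated.
#' @param adapter_position Insertion point: number of template bases before
#'   the adapter, as a single value or a `c(min, max)` range to sample
#'   from. Default range `c(10, read_length - 5)` so at least 5 adapter
#'   bases land inside the read.
#' @param n_fraction Fraction of reads spiked with uncalled bases.
#' @param n_per_read Number of `N`s per spiked read.
#' @param paired Emit an R2 mate file with `/1`, `/2` read ids?
#' @param gzip Gzip-compress the FASTQ output?
#' @param name File stem for the generated files.
#' @param seed Integer seed; identical spec + seed gives identical files.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_reads,
                         read_length = 100L,
                         encoding = "sanger_illumina18",
                         f_low = 0,
                         low_band = NULL,
                         high_band = c(25L, 40L),
                         adapter = NULL,
                         adapter_fraction = 0,
                         adapter_position = NULL,
                         n_fraction = 0,
                         n_per_read = 2L,
                         paired = FALSE,
                         gzip = FALSE,
                         name = "fixture",
                         seed = 1L) {
  enc <- as_quality_encoding(encoding)
  low_band <- low_band %||% switch(
    enc$name,
    solexa = c(-5L, 10L),
    illumina13 = c(0L, 15L),
    c(2L, 15L)
  )
  if (n_reads < 0 || read_length < 1) {
    abort("`n_reads` must be >= 0 and `read_length` >= 1")
  }
  if (f_low < 0 || f_low > 1 || adapter_fraction < 0 || adapter_fraction > 1 ||
      n_fraction < 0 || n_fraction > 1) {
    abort("fractions must lie in [0, 1]")
  }
  min_score <- if (enc$is_solexa) -5L else 0L
  if (low_band[1] < min_score || high_band[1] < min_score) {
    abort(sprintf("score bands must not go below %d for encoding %s",
                  min_score, enc$name))
  }
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    if (grepl("[^ACGT]", adapter)) abort("adapter may only contain A, C, G, T")
    if (nchar(adapter) > read_length) {
      abort("adapter longer than the read length")
    }
    if (nchar(adapter) < 5L) abort("adapter must be at least 5 bases")
    adapter_position <- adapter_position %||% c(10L, read_length - 5L)
    if (length(adapter_position) == 1L) {
      adapter_position <- rep(adapter_position, 2L)
    }
    if (adapter_position[1] < 0L ||
        adapter_position[2] > read_length - 5L) {
      abort("`adapter_position` must lie in [0, read_length - 5]")
    }
  }
  structure(
    list(
      n_reads = as.integer(n_reads), read_length = as.integer(read_length),
      encoding = enc, f_low = f_low,
      low_band = as.integer(low_band), high_band = as.integer(high_band),
      adapter = adapter, adapter_fraction = adapter_fraction,
      adapter_position = adapter_position,
      n_fraction = n_fraction, n_per_read = as.integer(n_per_read),
      paired = isTRUE(paired), gzip = isTRUE(gzip),
      name = name, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat(sprintf(
    "<fixture_spec> %d %s reads of %d bp, %s, f_low=%g%s%s, seed %d\n",
    x$n_reads, if (x$paired) "paired" else "single-end", x$read_length,
    x$encoding$name, x$f_low,
    if (!is.null(x$adapter))
      sprintf(", adapter %.0f%%", 100 * x$adapter_fraction) else "",
    if (x$n_fraction > 0)
      sprintf(", N spikes %.0f%%", 100 * x$n_fraction) else "",
    x$seed
  ))
  invisible(x)
}

#' Build a fixture spec from a JSON file
#'
#' Field names mirror the [fixture_spec()] arguments.
#'
#' @param path Path to a JSON spec.
#' @return A `fixture_spec`.
#' @export
read_fixture_spec <- function(path) {
  check_path_exists(path)
  args <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(fixture_spec, args)
}

# plain exhaustive adapter scan used only to police the generator's own
# ground truth (leftmost exact hit incl. >=5-base 3' suffix overlap);
# deliberately simple and loop-based
scan_adapter_truth <- function(seq, adapter) {
  rlen <- nchar(seq)
  alen <- nchar(adapter)
  for (p in 0:(rlen - 1L)) {
    aligned <- min(alen, rlen - p)
    if (aligned < alen && aligned < 5L) break
    if (substring(seq, p + 1L, p + aligned) ==
        substring(adapter, 1L, aligned)) {
      return(p)
    }
  }
  -1L
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

generate_mate <- function(spec, mate) {
  n <- spec$n_reads
  len <- spec$read_length
  enc <- spec$encoding
  offset <- if (enc$is_solexa) 64L else enc$ascii_offset

  is_low <- stats::runif(n) < spec$f_low
  has_adapter <- if (is.null(spec$adapter)) rep(FALSE, n)
                 else stats::runif(n) < spec$adapter_fraction
  has_n <- if (spec$n_fraction > 0) stats::runif(n) < spec$n_fraction
           else rep(FALSE, n)

  sequence <- character(n)
  adapter_pos <- rep(NA_integer_, n)
  n_count <- integer(n)
  true_mean_q <- numeric(n)
  quality <- character(n)

  for (i in seq_len(n)) {
    if (has_adapter[i]) {
      pos <- if (spec$adapter_position[1] == spec$adapter_position[2]) {
        spec$adapter_position[1]
      } else {
        sample(spec$adapter_position[1]:spec$adapter_position[2], 1L)
      }
      alen <- min(nchar(spec$adapter), len - pos)
      fill <- len - pos - alen
      repeat {
        s <- paste0(random_bases(pos), substr(spec$adapter, 1L, alen),
                    random_bases(fill))
        if (scan_adapter_truth(s, spec$adapter) == pos) break
      }
      sequence[i] <- s
      adapter_pos[i] <- pos
    } else {
      repeat {
        s <- random_bases(len)
        if (is.null(spec$adapter) ||
            scan_adapter_truth(s, spec$adapter) < 0L) break
      }
      sequence[i] <- s
    }
    if (has_n[i]) {
      # keep N spikes out of the adapter region so the recorded match
      # position stays the truth
      limit <- if (!is.na(adapter_pos[i])) adapter_pos[i] else len
      k <- min(spec$n_per_read, limit)
      if (k > 0L) {
        at <- sample.int(limit, k)
        sc <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
        sc[at] <- "N"
        sequence[i] <- paste(sc, collapse = "")
        n_count[i] <- k
      }
    }
    band <- if (is_low[i]) spec$low_band else spec$high_band
    scores <- sample(band[1]:band[2], len, replace = TRUE)
    quality[i] <- intToUtf8(scores + offset)
    true_mean_q[i] <- if (enc$is_solexa) mean(solexa_to_phred(scores))
                      else mean(scores)
  }

  suffix <- if (spec$paired) paste0("/", mate) else ""
  tibble(
    mate = mate,
    read_id = sprintf("%s_read%06d%s", spec$name, seq_len(n), suffix),
    description = rep("", n),
    sequence = sequence,
    quality = quality,
    is_low = is_low,
    true_mean_quality = true_mean_q,
    adapter_pos = adapter_pos,
    n_count = n_count
  )
}

#' Generate a synthetic FASTQ fixture with a ground-truth sidecar
#'
#' Writes the FASTQ file(s) described by a [fixture_spec()] plus a
#' tab-separated sidecar table recording, per read, the quality stratum,
#' the true mean Phred, the adapter insertion position (0-based count of
#' template bases before the adapter; `NA` if uncontaminated) and the `N`
#' count -- so expected filter and trim outcomes are computable without
#' running the pipeline. Uncontaminated reads are resampled until they
#' contain no chance adapter hit (including 5-base 3' suffix overlaps), so
#' the sidecar's contamination flags are exact.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if missing).
#' @return A list with `files` (named vector: `r1`, optionally `r2`,
#'   `sidecar`) and `truth` (the sidecar tibble, one row per read per mate).
#' @export
generate_fixture <- function(spec, outdir) {
  if (!inherits(spec, "fixture_spec")) abort("`spec` must be a fixture_spec")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- withr::with_seed(spec$seed, {
    mates <- if (spec$paired) 1:2 else 1L
    dplyr::bind_rows(lapply(mates, function(m) generate_mate(spec, m)))
  })
  ext <- if (spec$gzip) ".fastq.gz" else ".fastq"
  files <- c()
  if (spec$paired) {
    f1 <- file.path(outdir, paste0(spec$name, "_R1", ext))
    f2 <- file.path(outdir, paste0(spec$name, "_R2", ext))
    write_fastq(truth[truth$mate == 1L, ], f1, gzip_out = spec$gzip)
    write_fastq(truth[truth$mate == 2L, ], f2, gzip_out = spec$gzip)
    files <- c(r1 = f1, r2 = f2)
  } else {
    f1 <- file.path(outdir, paste0(spec$name, ext))
    write_fastq(truth, f1, gzip_out = spec$gzip)
    files <- c(r1 = f1)
  }
  sidecar <- file.path(outdir, paste0(spec$name, "_truth.tsv"))
  readr::write_tsv(
    truth[, c("mate", "read_id", "is_low", "true_mean_quality",
              "adapter_pos", "n_count")],
    sidecar, progress = FALSE
  )
  files["sidecar"] <- sidecar
  list(files = files, truth = truth)
}
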