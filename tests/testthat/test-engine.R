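# shared fixture for the engine tests, built once per test run
engine_dir <- tempfile("engine_")
dir.create(engine_dir)
ENGINE_FX <- generate_fixture(
  fixture_spec(n_reads = 1000, read_length = 60, f_low = 0.3,
               adapter = "AGATCGGAAGAGC", adapter_fraction = 0.3,
               n_fraction = 0.15, n_per_read = 3, seed = 101,
               name = "engine"),
  engine_dir
)
ENGINE_CFG <- filter_config(
  trim_quality_threshold = 20,
  adapters = adapter_set("AGATCGGAAGAGC"),
  max_n = 2, min_length = 20
)

test_that("an empty input produces empty outputs and zero tallies", {
  d <- tempfile(); dir.create(d)
  f <- file.path(d, "empty.fastq")
  file.create(f)
  res <- run_serial(f, out_dir = d, plots = FALSE)
  expect_equal(res$stats_raw$n_reads, 0L)
  expect_equal(unname(res$tallies), rep(0L, 6))
  expect_true(file.exists(res$files$clean1))
  expect_equal(file.size(res$files$clean1), 0)
  s <- readr::read_tsv(res$files$summary, show_col_types = FALSE,
                       col_types = "cc", na = character())
  expect_equal(s$value[s$field == "raw_reads"], "0")
  expect_equal(s$value[s$field == "raw_mean_length"], "NA")

  # the parallel path degenerates identically
  d2 <- tempfile(); dir.create(d2)
  f2 <- file.path(d2, "empty.fastq"); file.create(f2)
  resp <- run_parallel(f2, out_dir = d2, n_cpus = 3, plots = FALSE)
  expect_equal(resp$stats_raw$n_reads, 0L)
  expect_true(file.exists(resp$files$clean1))
})

test_that("pipeline tallies equal the brute-force per-read oracle", {
  d <- tempfile()
  res <- run_serial(ENGINE_FX$files[["r1"]], config = ENGINE_CFG,
                    out_dir = d, plots = FALSE)
  orc <- oracle_evaluate_file(
    ENGINE_FX$files[["r1"]],
    min_mean_quality = 20, max_n = 2, min_length = 20,
    trim_quality_threshold = 20, adapters = "AGATCGGAAGAGC"
  )
  expect_equal(res$tallies[["pass"]], sum(orc$status == "pass"))
  expect_equal(res$tallies[["too_short"]], sum(orc$reason == "too_short"))
  expect_equal(res$tallies[["too_many_n"]], sum(orc$reason == "too_many_n"))
  expect_equal(res$tallies[["low_mean_quality"]],
               sum(orc$reason == "low_mean_quality"))
  expect_equal(res$tallies[["trimmed"]],
               sum(orc$trimmed & orc$status == "pass"))
  # and the cleaned file holds exactly the oracle's passing reads
  clean <- read_fastq(res$files$clean1)
  expect_equal(clean$read_id, orc$read_id[orc$status == "pass"])
  expect_equal(nchar(clean$sequence),
               orc$kept_length[orc$status == "pass"])
})

test_that("the same input run twice gives byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  run_serial(ENGINE_FX$files[["r1"]], config = ENGINE_CFG, out_dir = d1,
             plots = FALSE)
  run_serial(ENGINE_FX$files[["r1"]], config = ENGINE_CFG, out_dir = d2,
             plots = FALSE)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("parallel runs reproduce the serial run byte for byte", {
  ds <- tempfile()
  run_serial(ENGINE_FX$files[["r1"]], config = ENGINE_CFG, out_dir = ds,
             save_rejects = TRUE, plots = FALSE)
  serial_files <- list.files(ds, full.names = TRUE)
  for (ncpu in c(1, 3)) {
    dp <- tempfile()
    run_parallel(ENGINE_FX$files[["r1"]], config = ENGINE_CFG, out_dir = dp,
                 n_cpus = ncpu, save_rejects = TRUE, plots = FALSE)
    par_files <- list.files(dp, full.names = TRUE)
    expect_equal(basename(par_files), basename(serial_files))
    expect_equal(unname(tools::md5sum(par_files)),
                 unname(tools::md5sum(serial_files)),
                 info = paste("n_cpus =", ncpu))
  }
})

test_that("gzip input, gzip output and fasta output agree across modes", {
  d <- tempfile(); dir.create(d)
  gz_fx <- generate_fixture(
    fixture_spec(n_reads = 300, read_length = 50, f_low = 0.3, gzip = TRUE,
                 seed = 41, name = "gzfix"), d)
  ds <- tempfile(); dp <- tempfile()
  rs <- run_serial(gz_fx$files[["r1"]], out_dir = ds, gzip_out = TRUE,
                   plots = FALSE)
  rp <- run_parallel(gz_fx$files[["r1"]], out_dir = dp, gzip_out = TRUE,
                     n_cpus = 4, plots = FALSE)
  expect_equal(unname(tools::md5sum(rs$files$clean1)),
               unname(tools::md5sum(rp$files$clean1)))
  expect_equal(read_fastq(rs$files$clean1)$read_id,
               read_fastq(gz_fx$files[["r1"]])$read_id[
                 oracle_evaluate_file(gz_fx$files[["r1"]])$status == "pass"])

  # FASTA output carries the same sequences in the same order
  df <- tempfile()
  rf <- run_serial(gz_fx$files[["r1"]], out_dir = df, fasta_out = TRUE,
                   plots = FALSE)
  fasta <- read_lines_plain(rf$files$clean1)
  expect_equal(fasta[seq(2, length(fasta), 2)],
               read_fastq(rs$files$clean1)$sequence)
})

test_that("paired processing keeps mates in lockstep in every mode", {
  d <- tempfile(); dir.create(d)
  fx <- generate_fixture(
    fixture_spec(n_reads = 400, read_length = 50, f_low = 0.3,
                 paired = TRUE, seed = 57, name = "pairfix"), d)
  for (keep in c(FALSE, TRUE)) {
    ds <- tempfile()
    res <- run_serial(fx$files[["r1"]], fx$files[["r2"]], out_dir = ds,
                      keep_orphans = keep, plots = FALSE)
    c1 <- read_fastq(res$files$clean1)
    c2 <- read_fastq(res$files$clean2)
    expect_equal(nrow(c1), nrow(c2))
    expect_equal(pair_key(c1$read_id), pair_key(c2$read_id))
    if (keep) {
      o1 <- read_fastq(res$files$orphan1)
      o2 <- read_fastq(res$files$orphan2)
      expect_equal(res$tallies[["pass"]],
                   2L * nrow(c1) + nrow(o1) + nrow(o2))
      expect_equal(res$tallies[["orphans_dropped"]], 0L)
    } else {
      expect_gt(res$tallies[["orphans_dropped"]], 0L)
    }
    # parallel equivalence with paired chunking
    dp <- tempfile()
    run_parallel(fx$files[["r1"]], fx$files[["r2"]], out_dir = dp,
                 keep_orphans = keep, n_cpus = 3, plots = FALSE)
    expect_equal(
      unname(tools::md5sum(list.files(dp, full.names = TRUE))),
      unname(tools::md5sum(list.files(ds, full.names = TRUE)))
    )
  }
})

test_that("worker failure aborts the run and removes partial outputs", {
  d <- tempfile(); dir.create(d)
  # mate counts differ -> the run must fail, not emit partial files
  fx <- generate_fixture(
    fixture_spec(n_reads = 100, read_length = 40, paired = TRUE,
                 seed = 61, name = "desync"), d)
  lines <- readLines(fx$files[["r2"]])
  writeLines(lines[1:(length(lines) - 4)], fx$files[["r2"]])
  dp <- tempfile()
  expect_error(
    run_parallel(fx$files[["r1"]], fx$files[["r2"]], out_dir = dp,
                 n_cpus = 2, plots = FALSE),
    "desynchronization"
  )
  expect_false(any(grepl("_clean", list.files(dp))))
})

test_that("intermediate files are cleaned up after success and failure", {
  before <- list.files(tempdir(), pattern = "^htsqc_work_")
  d <- tempfile()
  run_parallel(ENGINE_FX$files[["r1"]], config = ENGINE_CFG, out_dir = d,
               n_cpus = 3, plots = FALSE)
  after <- list.files(tempdir(), pattern = "^htsqc_work_")
  expect_equal(after, before)
  # cleanup is idempotent
  wd <- tempfile("htsqc_work_"); dir.create(wd)
  cleanup_intermediates(wd)
  expect_no_error(cleanup_intermediates(wd))
  expect_false(dir.exists(wd))
})

test_that("tally and base conservation hold, chunked or not", {
  for (res in list(
    run_serial(ENGINE_FX$files[["r1"]], config = ENGINE_CFG,
               out_dir = tempfile(), plots = FALSE),
    run_parallel(ENGINE_FX$files[["r1"]], config = ENGINE_CFG,
                 out_dir = tempfile(), n_cpus = 4, plots = FALSE)
  )) {
    t <- res$tallies
    expect_equal(res$stats_raw$n_reads,
                 t[["pass"]] + t[["too_short"]] + t[["too_many_n"]] +
                   t[["low_mean_quality"]])
    expect_equal(res$stats_clean$n_reads, t[["pass"]])
    expect_equal(res$stats_raw$n_bases,
                 res$stats_clean$n_bases + res$bases[["rejected"]] +
                   res$bases[["adapter_removed"]] +
                   res$bases[["quality_removed"]])
  }
})
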