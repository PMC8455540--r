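test_that("read_fastq parses minimal records and normalizes case", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1 some description", "acgt", "+", "IIII",
               "@r2", "NNAA", "+x", "!!!!"), f)
  r <- read_fastq(f)
  expect_equal(nrow(r), 2L)
  expect_equal(r$read_id, c("r1", "r2"))
  expect_equal(r$description, c("some description", ""))
  expect_equal(r$sequence, c("ACGT", "NNAA"))
  expect_equal(r$quality, c("IIII", "!!!!"))
})

test_that("read_fastq yields zero records for an empty stream", {
  f <- tempfile(fileext = ".fastq")
  file.create(f)
  expect_equal(nrow(read_fastq(f)), 0L)
})

test_that("malformed FASTQ is rejected with a precise error", {
  f <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), f)
  expect_error(read_fastq(f), "r1.*4 bases.*3 quality")

  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f)
  expect_error(read_fastq(f), "truncated.*record 2")

  writeLines(c("r1", "ACGT", "+", "IIII"), f)
  expect_error(read_fastq(f), "line 1.*'@'")

  writeLines(c("@r1", "ACGT", "x", "IIII"), f)
  expect_error(read_fastq(f), "line 3.*'\\+'")

  writeLines(c("@r1", "ACGU", "+", "IIII"), f)
  expect_error(read_fastq(f), "invalid base.*r1")
})

test_that("gzip is detected by magic bytes, not filename", {
  reads <- mk_reads(c("ACGT", "GGCC"), c("IIII", "!!!!"))
  plain <- write_tmp_fastq(reads)
  gz_lines <- read_lines_plain(plain)

  # gzip content under a .fastq name: magic must win over extension
  misnamed <- tempfile(fileext = ".fastq")
  con <- gzfile(misnamed, "w")
  writeLines(gz_lines, con)
  close(con)
  expect_equal(read_fastq(misnamed), reads)

  con <- open_stream_auto(misnamed)
  expect_equal(readLines(con, warn = FALSE), gz_lines)
  close(con)

  expect_error(open_stream_auto(tempfile()), "not found")
})

test_that("FASTQ round-trips through plain and gzip writers", {
  reads <- mk_reads(
    sequence = c("ACGTACGT", "NNNNN", "GATTACA"),
    quality = c("IIIIIIII", "!!!!!", "#J<FFFA"),
    description = c("1:N:0:ATCACG", "", "x y z")
  )
  expect_equal(read_fastq(write_tmp_fastq(reads)), reads)
  expect_equal(read_fastq(write_tmp_fastq(reads, gzip = TRUE)), reads)
  empty <- write_tmp_fastq(reads[0, ])
  expect_equal(file.size(empty), 0)
})

test_that("FASTA output preserves order and drops quality", {
  reads <- mk_reads(c("ACGT", "GGGG"), c("IIII", "JJJJ"),
                    read_id = c("a", "b"), description = c("d1", ""))
  f <- tempfile(fileext = ".fasta")
  expect_equal(write_fasta(reads, f), 2L)
  expect_equal(read_lines_plain(f), c(">a d1", "ACGT", ">b", "GGGG"))
})

test_that("read_paired pairs in lockstep and rejects desynchronized input", {
  r1 <- mk_reads(c("ACGT", "AAAA"), c("IIII", "IIII"),
                 read_id = c("a/1", "b/1"))
  r2 <- mk_reads(c("TTTT", "CCCC"), c("IIII", "IIII"),
                 read_id = c("a/2", "b/2"))
  p <- read_paired(write_tmp_fastq(r1), write_tmp_fastq(r2))
  expect_equal(p$pair_key, c("a", "b"))

  # no mate suffix at all is a valid pair
  r1b <- mk_reads("ACGT", "IIII", read_id = "x")
  p2 <- read_paired(write_tmp_fastq(r1b), write_tmp_fastq(r1b))
  expect_equal(p2$pair_key, "x")

  bad2 <- mk_reads("TTTT", "IIII", read_id = "z/2")
  expect_error(
    read_paired(write_tmp_fastq(r1b), write_tmp_fastq(bad2)),
    "record 1.*'x'.*'z/2'"
  )
  expect_error(
    read_paired(write_tmp_fastq(r1), write_tmp_fastq(r2[1, ])),
    "desynchronization"
  )
})

test_that("split_chunks partitions exactly with no gaps or duplicates", {
  set.seed(11)
  reads <- mk_reads(
    sequence = replicate(100, paste(sample(c("A", "C", "G", "T"), 30,
                                           TRUE), collapse = "")),
    quality = replicate(100, qstr(sample(2:40, 30, TRUE)))
  )
  f <- write_tmp_fastq(reads)

  one <- split_chunks(f, 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$record_count, 100L)

  for (k in c(2, 4, 7)) {
    ch <- split_chunks(f, k)
    expect_lte(nrow(ch), k)
    expect_equal(sum(ch$record_count), 100L)
    expect_equal(ch$start_byte[-1], ch$end_byte[-nrow(ch)])  # contiguous
    got <- dplyr::bind_rows(lapply(seq_len(nrow(ch)), function(i) {
      htsqc:::read_fastq_range(ch$source_path[i], ch$start_byte[i],
                               ch$end_byte[i])
    }))
    expect_equal(got, reads)
  }
  expect_error(split_chunks(f, 0), "positive")
})

test_that("chunk boundaries survive quality lines that start with '@'", {
  # every quality line begins '@' (Phred 31 at offset 33)
  reads <- mk_reads(
    sequence = rep("ACGTACGTAC", 60),
    quality = rep(paste0("@", qstr(rep(30, 9))), 60)
  )
  f <- write_tmp_fastq(reads)
  ch <- split_chunks(f, 3)
  got <- dplyr::bind_rows(lapply(seq_len(nrow(ch)), function(i) {
    htsqc:::read_fastq_range(ch$source_path[i], ch$start_byte[i],
                             ch$end_byte[i])
  }))
  expect_equal(got, reads)
})

test_that("gzip input is split via a decompressed temporary", {
  reads <- mk_reads(rep("ACGT", 40), rep("IIII", 40))
  f <- write_tmp_fastq(reads, gzip = TRUE)
  ch <- split_chunks(f, 2)
  expect_false(identical(ch$source_path[1], f))
  expect_equal(sum(ch$record_count), 40L)
  tmp <- attr(ch, "decompressed_tmp")
  expect_true(file.exists(tmp))
  unlink(tmp)
})
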