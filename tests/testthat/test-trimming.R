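ILLUMINA_AD <- "AGATCGGAAGAGC"

test_that("adapter sets validate and parse their three input forms", {
  a <- adapter_set(c("ACGTA", "TTTTT"))
  expect_equal(a$adapters, c("ACGTA", "TTTTT"))
  expect_equal(adapter_set("acgta,ggggg")$adapters, c("ACGTA", "GGGGG"))
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ad1", "ACGTA", ">ad2", "GGG", "GG"), fa)
  expect_equal(adapter_set(fa)$adapters, c("ACGTA", "GGGGG"))
  expect_error(adapter_set("ACG"), "at least 5")
  expect_error(adapter_set("ACGTN"), "A, C, G, T")
  expect_error(adapter_set("ACGTA", 1), "\\[0, 1\\)")
})

test_that("find_adapter locates exact internal matches", {
  hit <- find_adapter("ACGTACGTAGATCGGAAGAGC", ILLUMINA_AD)
  expect_equal(hit$adapter, 1L)
  expect_equal(hit$keep_length, 8L)   # match begins after 8 bases
  expect_equal(hit$start, 9L)

  none <- find_adapter("ACGTACGT", ILLUMINA_AD)
  expect_true(is.na(none$adapter))
  expect_equal(none$keep_length, 8L)
})

test_that("smallest position wins across adapters, list order breaks ties", {
  hit <- find_adapter("ACGTTTTT", c("TTTTT", "ACGTT"))
  expect_equal(hit$adapter, 2L)   # ACGTT at 0 beats TTTTT at 3
  expect_equal(hit$keep_length, 0L)
  # at equal positions, the first-listed adapter is reported
  tie <- find_adapter("ACGTACGTAA", c("ACGTA", "ACGTAC"))
  expect_equal(tie$adapter, 1L)
  expect_equal(tie$keep_length, 0L)
})

test_that("3' partial overlap needs at least five aligned bases", {
  # 6-base suffix overlap: read ends with the adapter's first 6 bases
  hit <- find_adapter(paste0("CCCCCCCCCC", substr(ILLUMINA_AD, 1, 6)),
                      ILLUMINA_AD)
  expect_equal(hit$keep_length, 10L)
  # 4-base suffix overlap: below the minimum, no match
  none <- find_adapter(paste0("CCCCCCCCCC", substr(ILLUMINA_AD, 1, 4)),
                       ILLUMINA_AD)
  expect_true(is.na(none$adapter))
})

test_that("N in the read counts as a mismatch", {
  contaminated <- paste0("AAAA", ILLUMINA_AD)
  broken <- sub("GGAA", "GGNA", contaminated)
  expect_false(is.na(find_adapter(contaminated, ILLUMINA_AD)$adapter))
  expect_true(is.na(find_adapter(broken, ILLUMINA_AD)$adapter))
  # ... unless the mismatch budget covers it
  a10 <- adapter_set(ILLUMINA_AD, max_mismatch_fraction = 0.1)
  expect_equal(find_adapter(broken, a10)$keep_length, 4L)
})

test_that("mismatch-tolerant matching agrees with the brute-force oracle", {
  set.seed(71)
  ads <- c("AGATCGGAAGAGC", "CTGTCTCTTATACACATCT")
  for (mmf in c(0, 0.1, 0.2)) {
    aset <- adapter_set(ads, max_mismatch_fraction = mmf)
    for (rep in 1:40) {
      len <- sample(20:60, 1)
      s <- paste(sample(c("A", "C", "G", "T", "N"), len, TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
      if (rep %% 2 == 0) {  # spike an adapter so hits are common
        p <- sample(0:(len - 6), 1)
        ad <- sample(ads, 1)
        s <- paste0(substr(s, 1, p),
                    substr(ad, 1, min(nchar(ad), len - p)))
        s <- substr(s, 1, len)
      }
      got <- find_adapter(s, aset)$keep_length
      want <- oracle_adapter_pos(s, ads, mmf)
      if (want < 0) want <- nchar(s)
      expect_equal(got, as.integer(want), info = s)
    }
  }
})

test_that("trim_adapter truncates sequence and quality together", {
  reads <- mk_reads(
    c("ACGTACGTAGATCGGAAGAGC", "ACGTACGT", ILLUMINA_AD),
    c(qstr(rep(40, 21)), qstr(rep(40, 8)), qstr(rep(40, 13)))
  )
  out <- trim_adapter(reads, ILLUMINA_AD)
  expect_equal(out$sequence, c("ACGTACGT", "ACGTACGT", ""))
  expect_equal(nchar(out$quality), c(8L, 8L, 0L))
  expect_equal(out$adapter_bases_removed, c(13L, 0L, 13L))
})

test_that("3' quality trimming removes the maximal low-quality suffix", {
  enc <- quality_encoding("sanger_illumina18")
  reads <- mk_reads(
    c("ACGT", "ACG", "AC", "ACGTA"),
    c(qstr(c(40, 40, 2, 2)), qstr(c(40, 40, 40)), qstr(c(2, 2)),
      qstr(c(2, 2, 40, 2, 2)))  # low bases 5' of a good base survive
  )
  out <- trim_quality_3prime(reads, 20, enc)
  expect_equal(out$sequence, c("AC", "ACG", "", "ACG"))
  expect_equal(out$quality_bases_removed, c(2L, 0L, 2L, 2L))
  expect_equal(nchar(out$sequence), nchar(out$quality))
})

test_that("quality trimming is idempotent", {
  set.seed(5)
  reads <- mk_reads(
    sequence = replicate(50, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                                   collapse = "")),
    quality = replicate(50, qstr(sample(2:40, 30, TRUE)))
  )
  enc <- quality_encoding("sanger_illumina18")
  once <- trim_quality_3prime(reads, 20, enc)
  twice <- trim_quality_3prime(once[, 1:4], 20, enc)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(twice$quality, once$quality)
  expect_true(all(twice$quality_bases_removed == 0L))
})
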