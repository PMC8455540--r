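Package: htsqc
Title: One-Step Quality Control for Illumina FASTQ Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A single-run quality-control engine for Illumina-style FASTQ
    data. Detects the quality-score encoding automatically, trims adapter
    contamination and low-quality 3' ends, filters reads on mean Phred
    quality, uncalled-base content and minimum length, preserves paired-end
    synchronization, and runs chunk-parallel with output identical to a
    serial run. Emits cleaned reads (FASTQ, gzip FASTQ or FASTA) together
    with summary statistics, backing tables and QC plots, and supports
    batch processing of many samples from a manifest. Includes a seeded
    synthetic-read generator that records per-read ground truth for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
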