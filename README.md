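# htsqc

One-step quality control for Illumina-style FASTQ data, as an R package
with a matching `htsqc` command-line tool.

Raw high-throughput sequencing reads carry three recurring artifacts that
must be removed before alignment or quantification: low-quality base calls
(especially toward the 3' end), adapter read-through (the sequencer reading
past a short insert into the library adapter), and uncalled bases (`N`).
`htsqc` performs detection, trimming and filtering in a single run over one
file, a pair of mate files, or a whole batch of samples, and reports summary
statistics and QC plots for the raw and cleaned data side by side. It is
aimed at anyone who processes Illumina FASTQ files and wants one
deterministic, scriptable step between the sequencer and the aligner.

## What it computes

* **Quality-encoding detection.** Phred scores Q = −10·log₁₀(*p*~error~) are
  stored as ASCII characters at an offset that changed across Illumina
  chemistry versions. From the minimum code *m* in a sample of reads, the
  variant is classified as Sanger/Illumina 1.8+ (offset 33) when *m* < 59,
  Solexa when 59 ≤ *m* < 64, Illumina 1.3 when 64 ≤ *m* < 66, and
  Illumina 1.5 when *m* ≥ 66. Solexa log-odds scores *s* are converted by
  Q = 10·log₁₀(10^(s/10) + 1).
* **Adapter trimming.** For each read, the leftmost position where any
  configured adapter aligns with Hamming mismatches ≤
  ⌊f·aligned_length⌋ (partial 3' overlap allowed from 5 bases); the
  adapter and everything 3' of it are removed.
* **3' quality trimming.** The maximal suffix in which every base scores
  below a per-base threshold is removed.
* **Filtering.** Post-trim reads fail, in this order, on minimum length, on
  uncalled-base content (count or fraction), or on mean Phred quality — by
  default only the quality filter is active, discarding reads with mean
  Q < 20 (< 99% base-call accuracy). Each read gets exactly one fail
  reason, so the tallies partition the input.
* **Paired-end synchronization.** Mates are evaluated together; the cleaned
  R1/R2 files always hold the same pairs at the same positions, with
  survivors of broken pairs either dropped (default) or routed to
  `_unpaired` files.
* **Chunk-parallel execution.** The input is split into record-aligned byte
  chunks processed by worker processes; merged output is byte-identical to
  a serial run, and intermediate files are cleaned up automatically.

## Worked example

Generate a synthetic 2,000-read sample with a known 25% low-quality
fraction and 15% adapter read-through, then clean it:

```r
library(htsqc)

spec <- fixture_spec(n_reads = 2000, read_length = 100, f_low = 0.25,
                     adapter = "AGATCGGAAGAGC", adapter_fraction = 0.15,
                     seed = 42, name = "demo")
fx <- generate_fixture(spec, "demo")

cfg <- filter_config(min_mean_quality = 20, trim_quality_threshold = 20,
                     adapters = adapter_set("AGATCGGAAGAGC"))
res <- run_parallel(fx$files[["r1"]], config = cfg, out_dir = "demo/qc",
                    n_cpus = 2, plots = FALSE)
res
#> <qc_result> sample 'demo' (single-end)
#>   quality format:    sanger_illumina18
#>   reads in:          2000
#>   reads retained:    1471
#>   failed: 529 too short, 0 too many N, 0 low mean quality
#>   trimmed (retained): 208
```

The 529 "too short" failures are the low-quality stratum: with a 3' quality
trim at Q20, reads whose bases are uniformly Q2–15 are trimmed to length
zero and fail the length check before the mean-quality check ever runs.
The 208 trimmed-but-retained reads are the adapter-contaminated good reads.
`glance()` returns the full one-row summary:

```r
glance(res)[, c("raw_reads", "clean_reads", "raw_mean_quality",
                "clean_mean_quality", "reads_trimmed")]
#>   raw_reads clean_reads raw_mean_quality clean_mean_quality reads_trimmed
#> 1      2000        1471          26.1464           32.49419           208
```

`demo/qc/` then holds `demo_clean.fastq`, `demo_summary.tsv` and the four
backing tables for the QC plots (`autoplot(res, "gc")` etc. draw them).

The same run from a shell:

```sh
htsqc run -a demo/demo.fastq --trim-qual 20 --adapters AGATCGGAAGAGC \
      --out-dir demo/qc --cpus 2
```

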