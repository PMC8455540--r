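---
title: "Methods: one-step FASTQ quality control in htsqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-step FASTQ quality control in htsqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htsqc)
```

## The problem and the processing model

Illumina base callers emit FASTQ: four lines per read, with per-base
quality encoded as printable ASCII. Before alignment, three artifacts need
removing — adapter read-through at the 3' end, low-quality 3' tails, and
reads that are globally poor or rich in uncalled bases. `htsqc` applies a
single fixed pipeline to every read:

1. **Adapter trimming** (if adapters are configured): find the leftmost
   adapter occurrence, remove it and everything 3' of it.
2. **3' quality trimming** (if a threshold is configured): remove the
   maximal suffix in which every base is below the per-base threshold.
3. **Filtering of the post-trim read**, in fixed order: length, uncalled
   bases, mean Phred quality. The first failing check records the read's
   single fail reason and later checks are skipped.

Checks run on the post-trim read because trimming feeds filtering in one
pass; a read whose informative prefix is good should survive a bad tail.
The fixed check order (cheapest first) makes the per-reason tallies well
defined: every input read lands in exactly one of
`pass / too_short / too_many_n / low_mean_quality`, which the engine
asserts as a conservation identity on every run, per chunk and after
merging, together with the base-level identity
`raw bases = clean bases + bases of rejected reads + bases trimmed from
retained reads`.

## Quality encodings

Four historical variants are distinguished. Detection scans the quality
characters of up to 100,000 reads (one bounded streaming pass) and uses
the minimum ASCII code `m`: offset-33 Sanger/Illumina 1.8+ when `m < 59`,
Solexa when `59 <= m < 64`, Illumina 1.3 when `64 <= m < 66`, Illumina 1.5
otherwise. These cut points are the classical range disambiguation — the
legal code ranges of the variants overlap only above 59/64/66, so the
minimum statistic is the decisive one. Uniformly high-quality data
(all codes in 66–74) is genuinely ambiguous; `htsqc` warns and applies the
min-rule answer (Illumina 1.5), and a forced `--qual-format` bypasses
detection for such inputs. The detected encoding is fixed for the whole
file: a later character below the assumed offset is a fatal error rather
than a re-detection trigger, keeping single-pass semantics deterministic.
Solexa characters are log-odds scores `s = ascii - 64` (down to −5) and are
converted to Phred by `10·log10(10^(s/10) + 1)`, unrounded.

A read's quality statistic is the unweighted arithmetic mean of its
per-base Phred scores, matching the per-read filtering rule (mean < 20
fails by default; a read at exactly the threshold passes — the comparison
is strictly "less than").

## Adapter matching

The matcher targets the dominant Illumina scenario: read-through into the
3' adapter. For each adapter, the smallest start `p` is sought at which the
adapter aligns with Hamming mismatches ≤ `floor(f · aligned_length)`, where
`aligned_length = min(adapter length, read length − p)`. Partial overlap
hanging off the 3' end is accepted from 5 aligned bases (shorter overlaps
match too often by chance). `N` always counts as a mismatch so N-rich reads
cannot match every adapter. Among adapters the smallest `p` wins, ties
going to the earliest adapter in the user's list. Trimming removes the
match and everything 3' of it — under read-through, everything from the
adapter onward is technical sequence. 5' trimming is deliberately not
performed, and adapters must be ≥ 5 bases (shorter "adapters" degenerate
into chance-level matching).

Quality trimming uses a fixed per-base threshold on the 3' suffix rather
than a sliding window: it is deterministic, order-independent and
idempotent (trimming twice equals trimming once), which the test suite
checks as a property.

## Paired-end policy

Cleaned R1/R2 files must stay in lockstep for downstream aligners, so a
pair survives intact only if both mates pass. By default a passing mate
whose partner failed is dropped with it; with `keep_orphans` it is written
to a `_unpaired` file instead. Retained-read statistics cover the paired
*and* unpaired outputs, and the engine additionally reports
`orphans_dropped` so that read conservation stays exact in the default
mode. Desynchronized input (mismatched pair keys or unequal counts) is a
fatal error at read time — silent re-pairing is out of scope. Pair keys
strip a trailing `/1`/`/2`; Casava 1.8-style headers already share the
identifier between mates.

## Chunk-parallel execution

`run_parallel()` splits the input into at most `n_cpus` record-aligned
byte chunks (equal record counts per worker, the simplest deterministic
policy). Boundaries are found by seeking to an approximate offset and
scanning to the next verifiable record start: a candidate header line is
accepted only when the following three lines parse as a record body, which
correctly rejects quality lines that begin with `@`. Gzip inputs are
decompressed to a temporary plain copy first (gzip streams are not
byte-seekable); paired files are split at identical record indices.

Encoding detection is hoisted out of the workers — a chunk-local minimum
could classify differently and break serial/parallel equivalence. Workers
write plain-text part files; the merge concatenates them in chunk order
and applies gzip compression (if requested) once, through the same writer
the serial path uses, so outputs are byte-identical to `run_serial()` for
every worker count. QC statistics are mergeable accumulators: merging is
associative and commutative with the empty accumulator as identity, and
merged chunk statistics equal whole-stream statistics exactly (integer
counters; the only floating-point field is a sum, merged by addition).
Intermediate part files and decompressed temporaries live in a per-run
working directory that is removed on success and on failure.

## Report statistics

For raw and cleaned streams the accumulator tracks read/base counts,
length extremes, per-position quality sums and base composition over the
5-letter alphabet, a per-read GC histogram and a per-read mean-quality
histogram. Numerical conventions, chosen once for determinism:

* GC percent is `100·(G+C)/(A+C+G+T)` — `N` excluded from both numerator
  and denominator; reads with no called base are excluded from the GC
  histogram and counted separately.
* GC bins are 1 percentage point wide, assigned by round-half-up; quality
  bins are 1 Phred point wide, assigned by floor and clamped to 0–60.
* "Average quality" of a stream is the unweighted mean over reads of the
  per-read mean Phred, matching the filtering statistic.
* Zero-length raw reads (legal FASTQ) carry no quality signal and are
  placed in quality bin 0.

Each of the four plots (mean quality by position, read-quality
distribution, GC distribution, base composition) is backed by a
tab-separated table with its exact numeric content, because image bytes
are not a stable verification surface.

## The synthetic-read generator

`fixture_spec()`/`generate_fixture()` produce the test inputs: reads of
fixed length whose per-base qualities are uniform within one of two
strata (a fraction `f_low` of reads in a low band, the rest in a high
band), optional adapter insertion at a known position in a known fraction
of reads, optional `N` spikes, and paired output with independently drawn
strata per mate. Defaults are 100 bp reads, low band Phred 2–15, high band
25–40 — bands that straddle the default Q20 filter so both verdicts occur.
For Illumina 1.3 the default low band starts at score 0 and for Solexa at
−5 (Solexa units): these variants are only distinguishable by codes below
66/64, so the generator's defaults keep its own files decidable by the
detection rule.

Two details make the sidecar ground truth exact rather than merely likely:
uncontaminated reads are resampled until they contain no chance adapter
hit (a random 50-mer has roughly a 1-in-800 chance of a spurious ≥ 5-base
3' suffix overlap, so thousand-read fixtures would otherwise contain about
one), and `N` spikes are kept out of the adapter region so they cannot
destroy an intended match. The generator emulates controlled quality
strata, contamination and correlated mate failure — not platform error
profiles, quality-by-cycle decay, or sequence composition bias. Passing
tests therefore demonstrate the pipeline's accounting and determinism on
decidable inputs, not biological realism.

## Problem sizes and other choices

The shipped tests and the acceptance script use fixtures between 300 and
10,000 reads: large enough that every verdict class, chunk boundary and
histogram bin is populated many times over, while the full suite still
runs in well under a minute. Batch mode runs each manifest row through the
chunk-parallel engine, scaling per-sample workers down so total workers
stay near `--cpus`; a failing sample is reported in the combined summary
and does not abort the batch (exit status 1 signals it). Rejected reads,
when saved, are written post-trim in FASTQ even when the cleaned output is
FASTA, since their qualities are exactly what one inspects. Empty input is
not an error: outputs exist and are empty, every tally is zero, and the
summary reports undefined length/quality fields as `NA`.

Known limitations: no sliding-window quality trimming, no 5' trimming, no
poly-A/G tail handling, no duplicate-read removal, no overlap-based paired
adapter detection, no interleaved FASTQ, and no re-pairing of
pre-desynchronized files. Multi-line (wrapped) FASTQ is rejected by design
— Illumina writers emit strict 4-line records, and wrapping is ambiguous
when quality lines can begin with `@`.
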