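# slowfive

Nanopore sequencers record, for every read, a raw time series of ionic
current — thousands of 16-bit ADC samples per read, terabytes per large
project.  The vendor's FAST5 container (HDF5) makes this signal awkward to
store and, above all, awkward to read in parallel.  `slowfive` is an R
implementation of the SLOW5 format family designed to fix that:

* **SLOW5** — a human-readable tab-separated encoding: a header
  (`#`-prefixed structural rows, `@`-prefixed run attributes with one value
  per read group) followed by one read per line with eight fixed primary
  columns (`read_id`, `read_group`, `digitisation`, `offset`, `range`,
  `sampling_rate`, `len_raw_signal`, `raw_signal`) plus optional typed
  auxiliary columns.
* **BLOW5** — a compact binary container, analogous to BAM for SAM:
  length-prefixed, *independently compressed* record frames between a magic
  number and an end-of-file sentinel.  Record-level compression is zlib or
  Zstandard; the signal itself can first be packed with a
  delta → zigzag → StreamVByte codec.  Zstandard on top of StreamVByte is
  the `vbz` preset.
* **Index** — a binary sidecar mapping each `read_id` to the byte offset
  and byte length of its record.  Because every frame is an independent
  compression stream, any number of workers can fetch reads from one shared
  file with no locking, and the result is identical whatever the worker
  count.

Raw ADC values convert to picoamperes as

```
pA[i] = (raw[i] + offset) * range / digitisation
```

The package also provides merge/split/convert/stats tooling, lossless
conversion to and from multi-read FAST5 (through a small `h5py` bridge run
by the system `python`), a deterministic synthetic-read generator, and a
benchmark harness reporting reads/s, normalized CPU utilization
`cpu_time / (wall_time × n_threads) × 100` and core-hours
`n_threads × wall_hours`.

## Worked example

```r
library(slowfive)

s5 <- table1Example()          # the canonical single-read-group example
s5
#> Slow5Header v1.0.0, 1 read group(s), 4 attribute(s), 0 aux column(s)
#> 3 record(s)

r0 <- s5[["read0"]]
r0
#> Slow5Record 'read0' (group 0): 123456 samples @ 4000 Hz
head(toPicoamps(r0), 3)        # (raw + 6) * 1467.6 / 8192
#> [1] 90.29180 89.21689 89.21689

ascii <- tempfile(fileext = ".slow5")
blow  <- tempfile(fileext = ".blow5")
writeSlow5(s5, ascii)                       # ASCII: 514211 bytes
writeSlow5(s5, blow, "blow5", vbzConfig())  # vbz:       569 bytes

buildIndex(blow)
idx <- loadIndex(blow)
adcOffset(getRead(idx, "read1"))
#> [1] 5

accessBenchmark(idx, nWorkers = 2, seed = 1)
#> BenchReport: 3 reads, 2 worker(s)
#>   ...
#>   checksum   : c9bf533bc197315b
```

The 123456-sample `read0` signal is highly repetitive in this example
(padded from its printed prefix), hence the extreme vbz ratio; on realistic
random-walk signals (`generateRecords()`) vbz files are roughly half the
size of zlib-only files.

## Command line

A thin `Rscript` front end over the same functions ships in
`inst/scripts/s5.R`:

```sh
s5=$(Rscript -e 'cat(system.file("scripts", "s5.R", package = "slowfive"))')
Rscript "$s5" view  reads.slow5 reads.blow5 --vbz --to blow5
Rscript "$s5" index reads.blow5
Rscript "$s5" stats reads.blow5 --json
Rscript "$s5" bench reads.blow5 --threads 4 --sample 1000 --seed 1 --json
```

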