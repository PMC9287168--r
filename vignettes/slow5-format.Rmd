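---
title: "The slowfive formats: design, codecs and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The slowfive formats: design, codecs and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowfive)
```

## The data model

A nanopore read is a time series of 16-bit ADC values plus four calibration
constants: `digitisation` (the number of quantisation levels), `offset` (an
additive correction in ADC units), `range` (the picoampere span) and
`sampling_rate` (samples per second).  Current in picoamperes is
`(raw + offset) * range / digitisation`.  Reads sharing one sequencing
run's metadata (flow cell, ASIC, start time, ...) form a *read group*; a
file holds one or more groups, and each header attribute carries exactly
one value per group.  These are the invariants `validateRecord()` checks;
violations are returned as data rather than thrown, so malformed input can
be inspected rather than merely rejected.

The eight primary columns are fixed by the format.  Auxiliary columns are
deliberately generic — any of the signed/unsigned fixed-width integer
types, `float`/`double`, `char`, strings, and array forms of the numeric
types — because run software adds fields freely (channel number, start
time, ...).  A missing auxiliary value renders as `"."` in ASCII: a
printable token that cannot be confused with a number.

## ASCII dialect decisions

Tabs separate cells, `\n` terminates rows (CRLF is tolerated on input,
never produced), signal samples are comma-separated, and an empty signal is
an empty cell.  `read_id` may not contain tab, newline or comma — the three
delimiters — and doubles are written with their *shortest exact decimal
rendering* (the shortest string that parses back to the identical IEEE
double).  That last choice is what makes whole-file round trips
byte-identical and lets conversion chains be tested with `identical()`
rather than with tolerances.

## The BLOW5 container

The binary layout is deliberately simple (all integers little-endian):

```
magic "BLOW5" 01 00 00 | version triple | record-method byte |
signal-method byte | u32 group count | u32 header length | ASCII header |
{ u64 frame length | compressed record payload } ... | EOF sentinel
```

The header block is stored as its ASCII rendering, uncompressed: one
serializer, trivially diffable.  The EOF sentinel is the magic reversed, so
truncation is always detectable.  Each record payload is one independent
compression stream — decoding frame *k* needs no bytes from any other
frame — which is the property that makes index-based parallel access work.
The signal blob inside a frame carries its own length so frames can be
skipped without decoding signal.  Readers reject container major versions
above their own.  This byte layout is this package's own, version-tagged in
the magic; no compatibility with files produced by other SLOW5
implementations is claimed, though the ASCII form is interchangeable by
construction.

## The signal codec

Nanopore current is locally smooth, so consecutive deltas are small.  The
codec chain is **delta → zigzag → StreamVByte**, then optionally zlib or
zstd over the whole record; zstd-over-StreamVByte is the `vbz` preset.

Three choices deserve explanation:

* **Wrapping deltas.**  A difference of two arbitrary int16 values needs 17
  bits, but the downstream stages operate on 16-bit words.  Deltas are
  therefore computed modulo 2^16 (wrapped back into int16), which makes the
  chain total and exactly invertible for *every* int16 input while changing
  nothing for realistic signals, whose steps are tiny.
* **One control bit per value.**  Classic StreamVByte spends 2 control bits
  per 32-bit value (four width classes).  Our inputs are 16-bit, so two
  width classes (1 or 2 data bytes) suffice; control bits are packed
  LSB-first and the value count is stored explicitly so trailing control
  bits are ignorable.  The encoded size is exactly
  `ceil(n/8) + n + popcount(control)` bytes, an identity the tests assert
  on every block.
* **zstd level 1 by default.**  The format's goal is parallel *access*;
  compression speed matters more than the last few percent of ratio.  The
  level is configurable via `CompressionConfig()`.

The codec is validated two independent ways: against a naive per-value
reference codec written separately in the test helpers, and by exhaustive
round trip of the zigzag map over all 65,536 16-bit values.

## Index and the parallel-access contract

`buildIndex()` scans a file once and records, per read, the byte offset and
length of its ASCII line (newline included) or binary frame (length prefix
included).  The sidecar stores the data file's size and a 64-bit FNV-1a
checksum of its header block; `loadIndex()` refuses a stale index.  Lookup
is a hashed environment: O(1) expected.

The contract `getRead()`/`getReads()` honour is positional: every access
supplies its own offset, no reader mutates shared state, so workers need no
mutual exclusion and the retrieved record *set* is invariant to worker
count and scheduling.  Tests assert that invariance through an
order-invariant checksum (per-record FNV digests, sorted, re-hashed) rather
than through timing.

## Merge, split, conversion

Merging collapses read groups with identical attribute maps and numbers
distinct groups by first occurrence in input order — a deterministic rule
that makes `merge(split(x, "group"))` reproduce `x`'s content exactly.
Auxiliary schemas are unioned; one name with two types is an error.
Duplicate read identifiers across inputs are an error (uniqueness is
enforced at file level, not at record construction, so streaming producers
are never blocked).  All tooling — including the `s5` command line, a thin
script over the exported functions — never touches signal values, which the
tests pin with checksums of concatenated signals.

## FAST5 conversion

FAST5 is an HDF5 container; no R HDF5 interface is imported here.  Instead
a small bridge script (`inst/python/fast5_bridge.py`, run by the system
`python` with `h5py`) shuttles bytes between HDF5 and SLOW5 ASCII; all
format logic stays in R.  The bridge targets the documented multi-read
layout (`read_<id>` groups with `channel_id` calibration attributes and a
`Raw/Signal` int16 dataset) plus an attribute-spelling map users can
extend.  Single-read FAST5 is rejected explicitly.  Losslessness is tested
as a fixed point: `f2s(s2f(f2s(x)))` equals `f2s(x)` down to every sample
and calibration constant.  `f2s` partitions work per input file across
workers; the merged result is asserted identical for 1 and 4 workers.

## Benchmark harness

`cpuUtilisation()` and `coreHours()` implement the standard normalized
formulas (`cpu/(wall × threads) × 100`; `threads × wall-hours`, constant
under ideal scaling).  `accessBenchmark()` times indexed retrieval across
workers but *asserts nothing about timing*: correctness is the checksum,
reported alongside the hardware-dependent rates.  Clearing the OS page
cache portably is not possible from a library, so repeated runs measure a
warm cache; a `preRunHook` lets users drop caches themselves when cold
numbers are wanted.

## The synthetic generator, and what passing tests do not show

`generateRecords()` produces integer random walks
(`s[i] = s[i-1] + round(N(0, 5))`, started near `N(500, 30)`, clipped to
int16) with lengths `N(2000, 200)` and per-group calibration
(digitisation 8192, range in 1300–1600 pA, offsets −10..10, 4 kHz).  The
walk reproduces the one statistical property the codec relies on — local
smoothness — so the vbz-beats-zlib ordering is exercised honestly; the
defaults are desk-scale stand-ins for a sequencing run's reads.  It does
*not* simulate pore chemistry: no event structure, adapter or stall
segments, and no basecall-relevant signal.  Passing tests therefore
demonstrate format correctness and codec behaviour on realistic
*statistics*, not biological fidelity, and compression ratios on real
datasets will differ in level (though not, in our measurements, in
ordering).  The worked example's printed signals are truncated at two
values; the built-in fixture pads them with the last printed value to the
declared lengths, and exposes the printed prefixes separately so
value-exact tests never rely on padding.

Test and acceptance problem sizes — 1000 reads of mean length 2000 for
round-trip and compression checks, 10,000 random sequences for the codec
oracle, 65,536 values for the exhaustive zigzag sweep — were chosen as the
smallest scales at which the properties are meaningfully exercised, and
run in well under a minute each on a laptop-class machine.

## Known limitations

* Byte-level compatibility with other SLOW5/BLOW5 implementations and with
  ONT's `vbz` plugin streams is not claimed; the ASCII form is the
  interchange surface.
* `uint64` quantities are carried as R doubles; values above 2^53 are not
  representable (no practical file approaches this).
* Parallel workers use `parallel::mclapply` and fall back to sequential
  execution on non-Unix platforms; the correctness contract is unchanged.
* FAST5 conversion requires an external `python` with `h5py`
  (`hdf5BridgeAvailable()` probes it; `SLOWFIVE_PYTHON` overrides the
  interpreter).
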