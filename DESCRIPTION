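Package: slowfive
Title: Read, Write, Index and Compress Nanopore Raw-Signal Data in SLOW5/BLOW5 Format
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An implementation of the SLOW5 file format family for nanopore
    raw current signal: the tab-separated human-readable SLOW5 ASCII encoding,
    the compact BLOW5 binary container with per-record compression (zlib,
    Zstandard) and a delta/zigzag/StreamVByte signal codec composing to the
    'vbz' preset, a binary byte-offset index keyed by read identifier that
    supports lock-free parallel random access, merge/split/convert/stats
    tooling, lossless conversion to and from multi-read FAST5 containers, and
    a benchmarking harness reporting throughput, normalized CPU utilization
    and core-hours. A deterministic synthetic-read generator makes every
    component testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, parallel, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
SystemRequirements: libzstd
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
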