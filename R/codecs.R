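# Signal codec pipeline (delta -> zigzag -> StreamVByte) and per-record
# compression (zlib via memCompress, zstd via libzstd).  Composing svb with
# zstd gives the vbz preset.

#' Delta-encode / decode a 16-bit signal
#'
#' `deltaEncode` replaces each sample by its difference from the previous
#' one (the first sample is kept as-is).  Differences are computed with
#' wrapping modulo-2^16 arithmetic so that every encoded value again fits a
#' signed 16-bit integer — a difference of two arbitrary int16 values spans
#' 17 bits, and the downstream zigzag/StreamVByte stages operate on 16-bit
#' words.  `deltaDecode` inverts exactly for any int16 input.
#'
#' @param signal integer vector of int16 samples.
#' @param deltas integer vector produced by `deltaEncode`.
#' @return integer vector of the same length.
#' @examples
#' deltaEncode(c(498L, 492L))   # 498 -6
#' deltaDecode(deltaEncode(c(5L, 5L, 5L)))
#' @export
deltaEncode <- function(signal) {
    n <- length(signal)
    if (n == 0L) return(integer())
    if (!.is_int16(signal))
        s5_stop("slow5_width_error", "signal values must fit int16")
    d <- c(signal[1L], diff(signal))
    as.integer(((d + 32768) %% 65536) - 32768)
}

#' @rdname deltaEncode
#' @export
deltaDecode <- function(deltas) {
    n <- length(deltas)
    if (n == 0L) return(integer())
    as.integer(((cumsum(as.numeric(deltas)) + 32768) %% 65536) - 32768)
}

#' Zigzag-map signed integers to unsigned and back
#'
#' Interleaves signed values onto the unsigned axis so small magnitudes get
#' small codes: non-negative `v` maps to `2 v`, negative `v` to `-2 v - 1`
#' (equivalently `(v << 1) XOR (v >> (bits - 1))` with an arithmetic
#' shift).
#'
#' @param v integer vector of signed values.
#' @param z integer vector of unsigned codes.
#' @param bits word width the values must fit (default 16).
#' @return integer vector.
#' @examples
#' zigzagEncode(c(0L, -6L, 498L))  # 0 11 996
#' @export
zigzagEncode <- function(v, bits = 16L) {
    if (length(v) == 0L) return(integer())
    lo <- -2^(bits - 1L); hi <- 2^(bits - 1L) - 1
    if (anyNA(v) || any(v < lo | v > hi))
        s5_stop("slow5_width_error",
                "value outside signed %d-bit range", bits)
    as.integer(ifelse(v >= 0L, 2 * as.numeric(v), -2 * as.numeric(v) - 1))
}

#' @rdname zigzagEncode
#' @export
zigzagDecode <- function(z, bits = 16L) {
    if (length(z) == 0L) return(integer())
    if (anyNA(z) || any(z < 0 | z > 2^bits - 1))
        s5_stop("slow5_width_error",
                "code outside unsigned %d-bit range", bits)
    z <- as.numeric(z)
    as.integer(ifelse(z %% 2 == 0, z / 2, -(z + 1) / 2))
}

#' StreamVByte block for 16-bit values
#'
#' Byte-aligned variable-width encoding in the Group Varint family,
#' specialised to 16-bit inputs: one control bit per value (packed
#' LSB-first), 0 meaning one data byte, 1 meaning two little-endian data
#' bytes.  The encoded size is always
#' `ceil(n / 8) + n + popcount(control)` bytes.
#'
#' @slot count number of encoded values.
#' @slot control raw vector of bit-packed width flags.
#' @slot data raw vector of variable-width payload bytes.
#' @export
setClass("SvbBlock",
    representation(count = "numeric", control = "raw", data = "raw"),
    prototype(count = 0, control = raw(), data = raw()))

setMethod("show", "SvbBlock", function(object) {
    cat("SvbBlock:", object@count, "values,", length(object@control),
        "control +", length(object@data), "data bytes\n")
})

#' Encode / decode unsigned 16-bit values with StreamVByte
#'
#' @param values integer vector, each in `[0, 65535]`.
#' @param block an [SvbBlock-class] produced by `svbEncode`.
#' @return `svbEncode` returns an [SvbBlock-class]; `svbDecode` returns the
#'   original integer vector.
#' @examples
#' b <- svbEncode(c(1L, 300L))
#' as.integer(b@control)        # 2 = 0b00000010
#' svbDecode(b)
#' @export
svbEncode <- function(values) {
    enc <- .Call(C_svb_encode, as.integer(values))
    new("SvbBlock", count = length(values), control = enc$control,
        data = enc$data)
}

#' @rdname svbEncode
#' @export
svbDecode <- function(block) {
    .Call(C_svb_decode, block@control, block@data, block@count)
}

# ---- signal-level serialization ---------------------------------------------

#' Compress / decompress a raw signal
#'
#' The `svb` path runs delta encoding, 16-bit zigzag, then StreamVByte and
#' serializes the block as an 8-byte little-endian count followed by the
#' control and data streams.  The `none` path stores the samples as raw
#' little-endian int16.  Both invert exactly.
#'
#' @param signal integer vector of int16 samples.
#' @param bytes raw vector produced by `compressSignal`.
#' @param method `"none"` or `"svb"`.
#' @return `compressSignal` returns a raw vector; `decompressSignal` the
#'   original integer signal.
#' @export
compressSignal <- function(signal, method = c("svb", "none")) {
    method <- match.arg(method)
    if (method == "none")
        return(.pack_int16(signal))
    block <- svbEncode(zigzagEncode(deltaEncode(signal)))
    c(.pack_u64(block@count), block@control, block@data)
}

#' @rdname compressSignal
#' @export
decompressSignal <- function(bytes, method = c("svb", "none")) {
    method <- match.arg(method)
    if (method == "none")
        return(.unpack_int16(bytes))
    if (length(bytes) < 8L)
        s5_stop("slow5_decode_error",
                "svb payload truncated at byte %d: missing count",
                length(bytes))
    n <- .unpack_uint(bytes[1:8])
    ncontrol <- ceiling(n / 8)
    if (length(bytes) < 8 + ncontrol)
        s5_stop("slow5_decode_error",
                "svb payload truncated at byte %d: control stream short",
                length(bytes))
    control <- bytes[seq_len(ncontrol) + 8L]
    data <- bytes[-seq_len(8L + ncontrol)]
    z <- tryCatch(
        .Call(C_svb_decode, control, data, n),
        error = function(e) s5_stop("slow5_decode_error", "%s",
                                    conditionMessage(e)))
    deltaDecode(zigzagDecode(z))
}

# ---- record-level compression ------------------------------------------------

#' Compress / decompress a serialized record payload
#'
#' Applies the record-level method to an opaque byte payload.  Every record
#' is an independent compression stream: decompressing one record never
#' needs bytes from any other, which is what allows index-based parallel
#' decoding.
#'
#' @param payload raw vector (the serialized record).
#' @param method `"none"`, `"zlib"` or `"zstd"`.
#' @param level zstd compression level (ignored by the other methods).
#' @return raw vector.
#' @export
compressRecordPayload <- function(payload,
                                  method = c("none", "zlib", "zstd"),
                                  level = 1L) {
    method <- match.arg(method)
    switch(method,
        none = payload,
        zlib = memCompress(payload, type = "gzip"),
        zstd = .Call(C_zstd_compress, payload, as.integer(level)))
}

#' @rdname compressRecordPayload
#' @export
decompressRecordPayload <- function(payload,
                                    method = c("none", "zlib", "zstd")) {
    method <- match.arg(method)
    tryCatch(switch(method,
        none = payload,
        zlib = memDecompress(payload, type = "gzip"),
        zstd = .Call(C_zstd_decompress, payload)),
        error = function(e) {
            if (inherits(e, "slow5_error")) stop(e)
            s5_stop("slow5_decode_error", "record payload decode failed: %s",
                    conditionMessage(e))
        })
}
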