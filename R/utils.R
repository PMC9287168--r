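# Internal helpers: typed conditions, little-endian byte packing, shortest
# round-trip double formatting, FNV-1a checksums.

s5_stop <- function(class, msg, ...) {
    stop(structure(class = c(class, "slow5_error", "error", "condition"),
                   list(message = sprintf(msg, ...), call = sys.call(-1))))
}

INT16_MIN <- -32768L
INT16_MAX <- 32767L

.is_int16 <- function(x) {
    !anyNA(x) && all(x >= INT16_MIN & x <= INT16_MAX)
}

# ---- little-endian packing (values carried as doubles; exact below 2^53) ----

.pack_u16 <- function(x) {
    x <- as.integer(x)
    as.raw(c(x %% 256L, x %/% 256L))
}

.pack_u32 <- function(x) {
    x <- as.numeric(x)
    as.raw((x %/% 256^(0:3)) %% 256)
}

.pack_u64 <- function(x) {
    x <- as.numeric(x)
    as.raw((x %/% 256^(0:7)) %% 256)
}

.unpack_uint <- function(bytes) {
    sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1L))
}

.pack_doubles <- function(x) {
    writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
}

.unpack_doubles <- function(bytes) {
    readBin(bytes, "numeric", n = length(bytes) %/% 8L, size = 8L,
            endian = "little")
}

.pack_int16 <- function(x) {
    writeBin(as.integer(x), raw(), size = 2L, endian = "little")
}

.unpack_int16 <- function(bytes) {
    readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
            signed = TRUE, endian = "little")
}

# ---- shortest round-trip rendering of doubles --------------------------------

.fmt_double <- function(x) {
    vapply(x, function(v) {
        if (is.na(v)) return("NA")
        if (v == trunc(v) && abs(v) < 1e15) {
            s <- sprintf("%.0f", v)
            return(s)
        }
        for (d in 1:17) {
            s <- sprintf("%.*g", d, v)
            if (as.numeric(s) == v) return(s)
        }
        sprintf("%.17g", v)
    }, character(1))
}

# ---- FNV-1a ------------------------------------------------------------------

fnv64 <- function(bytes) .Call(C_fnv1a64, bytes)

fnv64_hex <- function(bytes) paste(format(rev(fnv64(bytes))), collapse = "")

#' Order-invariant checksum of a set of records
#'
#' Hashes each record's identity-defining content (read id, group,
#' calibration, signal), sorts the per-record digests and hashes the
#' concatenation, so the result does not depend on record order or on how
#' the records were retrieved.
#'
#' @param records list of [Slow5Record-class] objects.
#' @return hex string (16 characters).
#' @export
recordSetChecksum <- function(records) {
    digests <- vapply(records, function(r) {
        payload <- c(charToRaw(r@readID), .pack_u32(r@readGroup),
                     .pack_doubles(c(r@digitisation, r@offset, r@range,
                                     r@samplingRate)),
                     .pack_u64(r@lenRawSignal), .pack_int16(r@signal))
        fnv64_hex(payload)
    }, character(1))
    fnv64_hex(charToRaw(paste(sort(digests), collapse = "")))
}
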