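# Independent reference implementations and comparison helpers.

# Naive one-value-at-a-time StreamVByte reference codec: same byte layout
# as the package codec (1 control bit per value, LSB-first; 1 or 2
# little-endian data bytes) but computed value by value with no shared
# code.
oracle_svb_encode <- function(values) {
    n <- length(values)
    control <- raw(ceiling(n / 8))
    data <- vector("list", n)
    for (i in seq_len(n)) {
        v <- values[[i]]
        stopifnot(v >= 0, v <= 65535)
        if (v > 255) {
            byte_i <- (i - 1) %/% 8 + 1
            bit_i <- (i - 1) %% 8
            control[byte_i] <- as.raw(bitwOr(as.integer(control[byte_i]),
                                             bitwShiftL(1L, bit_i)))
            data[[i]] <- as.raw(c(v %% 256, v %/% 256))
        } else {
            data[[i]] <- as.raw(v)
        }
    }
    list(control = control, data = do.call(c, c(list(raw()), data)))
}

oracle_svb_decode <- function(control, data, n) {
    out <- integer(n)
    k <- 1L
    for (i in seq_len(n)) {
        two <- bitwAnd(bitwShiftR(as.integer(control[(i - 1) %/% 8 + 1]),
                                  (i - 1) %% 8), 1L)
        v <- as.integer(data[k]); k <- k + 1L
        if (two == 1L) {
            v <- v + 256L * as.integer(data[k]); k <- k + 1L
        }
        out[i] <- v
    }
    stopifnot(k == length(data) + 1L)
    out
}

popcount_bytes <- function(bytes) {
    sum(vapply(as.integer(bytes), function(b)
        sum(bitwAnd(bitwShiftR(b, 0:7), 1L)), integer(1)))
}

# canonical slot list for exact record comparison
rec_canon <- function(r) {
    list(id = readID(r), group = readGroup(r), dig = digitisation(r),
         off = adcOffset(r), rng = adcRange(r), rate = samplingRate(r),
         len = lenRawSignal(r), signal = rawSignal(r), aux = auxValues(r))
}

sets_equal <- function(x, y) {
    rx <- slow5Records(x); ry <- slow5Records(y)
    if (length(rx) != length(ry)) return(FALSE)
    all(mapply(function(a, b) identical(rec_canon(a), rec_canon(b)),
               rx, ry))
}

all_configs <- function() {
    out <- list()
    for (rm in c("none", "zlib", "zstd"))
        for (sm in c("none", "svb"))
            out[[paste(rm, sm, sep = "+")]] <- CompressionConfig(rm, sm)
    out
}

write_table1_file <- function(path) {
    writeSlow5(table1Example(), path, format = "slow5")
    path
}
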