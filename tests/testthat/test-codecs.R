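test_that("delta coding matches the closed form and inverts for all int16", {
    expect_identical(deltaEncode(integer()), integer())
    expect_identical(deltaEncode(c(498L, 492L)), c(498L, -6L))
    expect_identical(deltaEncode(c(5L, 5L, 5L)), c(5L, 0L, 0L))

    # wrap-around: a jump wider than int16 still round-trips
    extremes <- c(-32768L, 32767L, -32768L, 0L, 32767L)
    expect_identical(deltaDecode(deltaEncode(extremes)), extremes)
    expect_true(all(deltaEncode(extremes) >= -32768L &
                    deltaEncode(extremes) <= 32767L))

    set.seed(1)
    for (i in 1:25) {
        s <- as.integer(sample(-32768:32767, sample(0:300, 1),
                               replace = TRUE))
        expect_identical(deltaDecode(deltaEncode(s)), s)
    }
})

test_that("zigzag matches its closed form and is exhaustively invertible", {
    expect_identical(zigzagEncode(0L), 0L)
    expect_identical(zigzagEncode(c(-6L, 498L)), c(11L, 996L))
    expect_identical(zigzagDecode(c(11L, 996L)), c(-6L, 498L))

    all16 <- -32768:32767
    z <- zigzagEncode(all16)
    expect_true(all(z >= 0L & z <= 65535L))
    expect_identical(zigzagDecode(z), all16)
    expect_identical(sort(z), 0:65535)  # bijection onto the unsigned range

    expect_error(zigzagEncode(40000L), class = "slow5_width_error")
    expect_error(zigzagDecode(-1L), class = "slow5_width_error")
})

test_that("svb block layout matches the hand-computed example", {
    b0 <- svbEncode(integer())
    expect_identical(length(b0@control), 0L)
    expect_identical(length(b0@data), 0L)

    b <- svbEncode(c(1L, 300L))
    expect_identical(as.integer(b@control), 2L)            # 0b00000010
    expect_identical(as.integer(b@data), c(0x01L, 0x2CL, 0x01L))
    expect_identical(svbDecode(b), c(1L, 300L))

    expect_error(svbEncode(70000L), "width")
})

test_that("svb agrees with the naive per-value oracle and the size formula", {
    set.seed(2024)
    n_cases <- 400L
    for (i in seq_len(n_cases)) {
        n <- sample(0:120, 1)
        v <- as.integer(sample(0:65535, n, replace = TRUE))
        if (i %% 3 == 0)  # skew toward 1-byte values
            v <- as.integer(sample(0:255, n, replace = TRUE))
        b <- svbEncode(v)
        o <- oracle_svb_encode(v)
        expect_identical(b@control, o$control)
        expect_identical(b@data, o$data)
        expect_identical(svbDecode(b), v)
        expect_identical(oracle_svb_decode(b@control, b@data, n), v)
        expect_identical(length(b@control) + length(b@data),
                         as.integer(ceiling(n / 8) + n +
                                    popcount_bytes(b@control)))
    }
})

test_that("compressSignal chains delta/zigzag/svb and inverts exactly", {
    expect_identical(decompressSignal(compressSignal(integer())), integer())
    expect_identical(length(compressSignal(integer())), 8L)  # count only

    const8 <- rep(100L, 8L)
    payload <- compressSignal(const8)
    # after delta/zigzag: 200,0,...,0 -> all control bits clear, data C8 00x7
    expect_identical(payload[9], as.raw(0))                  # control byte
    expect_identical(payload[10:17], as.raw(c(0xC8, rep(0, 7))))
    expect_identical(decompressSignal(payload), const8)

    set.seed(5)
    for (i in 1:20) {
        s <- as.integer(cumsum(c(500, round(rnorm(199, 0, 5)))))
        expect_identical(decompressSignal(compressSignal(s)), s)
        expect_identical(decompressSignal(compressSignal(s, "none"), "none"),
                         s)
    }
    expect_error(decompressSignal(as.raw(1:4)),
                 class = "slow5_decode_error")
})

test_that("record payload compression is lossless and per-record independent", {
    set.seed(6)
    p1 <- as.raw(sample(0:255, 400, replace = TRUE))
    p2 <- charToRaw(paste(rep("squiggle", 50), collapse = " "))

    expect_identical(compressRecordPayload(raw(), "none"), raw())
    for (m in c("none", "zlib", "zstd")) {
        c1 <- compressRecordPayload(p1, m)
        c2 <- compressRecordPayload(p2, m)
        # second stream decodes alone, with no bytes from the first
        expect_identical(decompressRecordPayload(c2, m), p2)
        expect_identical(decompressRecordPayload(c1, m), p1)
    }
    expect_error(decompressRecordPayload(as.raw(c(1, 2, 3)), "zstd"),
                 class = "slow5_decode_error")
    expect_error(decompressRecordPayload(as.raw(c(1, 2, 3)), "zlib"),
                 class = "slow5_decode_error")
})

test_that("vbz payloads beat zlib-alone on random-walk signals in aggregate", {
    s <- generateRecords(200, meanLength = 500, sigmaStep = 5, seed = 99,
                         withAux = FALSE)
    vbz <- 0; zlib_only <- 0
    for (r in slow5Records(s)) {
        sig <- rawSignal(r)
        vbz <- vbz + length(compressRecordPayload(compressSignal(sig, "svb"),
                                                  "zstd"))
        zlib_only <- zlib_only +
            length(compressRecordPayload(compressSignal(sig, "none"), "zlib"))
    }
    expect_lte(vbz, zlib_only)
})
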