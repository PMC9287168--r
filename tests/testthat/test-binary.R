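test_that("an empty container is magic + header block + sentinel", {
    p <- tempfile(fileext = ".blow5")
    h <- Slow5Header(attributes = list(run_id = "x"))
    out <- writeBlow5(h, list(), p)
    expect_identical(out$records, 0L)
    expect_identical(out$bytes, as.numeric(file.size(p)))

    got <- readBlow5(p)
    expect_length(slow5Records(got$set), 0L)
    expect_true(identical(slow5Header(got$set), h))

    bytes <- readBin(p, "raw", file.size(p))
    expect_identical(tail(bytes, 8), rev(head(bytes, 8)))  # EOF sentinel
})

test_that("binary round trip is exact under every compression config", {
    s <- generateRecords(40, nReadGroups = 2L, meanLength = 150, seed = 12)
    for (cfg in all_configs()) {
        p <- tempfile(fileext = ".blow5")
        writeBlow5(slow5Header(s), slow5Records(s), p, cfg)
        got <- readBlow5(p)
        expect_true(sets_equal(got$set, s))
        expect_identical(got$config@recordMethod, cfg@recordMethod)
        expect_identical(got$config@signalMethod, cfg@signalMethod)
    }
})

test_that("worked-example records survive the uncompressed binary container", {
    s <- table1Example()
    p <- tempfile(fileext = ".blow5")
    writeBlow5(s, NULL, p, CompressionConfig("none", "none"))
    expect_true(sets_equal(readBlow5(p)$set, s))
})

test_that("malformed containers raise typed errors", {
    ascii <- tempfile(fileext = ".slow5")
    writeSlow5(table1Example(), ascii)
    expect_error(readBlow5(ascii), class = "slow5_not_blow5")

    p <- tempfile(fileext = ".blow5")
    s <- generateRecords(3, meanLength = 30, seed = 1)
    writeSlow5(s, p, "blow5")

    truncated <- tempfile(fileext = ".blow5")
    bytes <- readBin(p, "raw", file.size(p))
    writeBin(bytes[1:(length(bytes) - 20)], truncated)
    expect_error(readBlow5(truncated), class = "slow5_truncated")

    corrupt <- tempfile(fileext = ".blow5")
    # overwrite the first frame's length prefix with nonsense
    hlen <- sum(nchar(writeSlow5Header(slow5Header(s)),
                      type = "bytes") + 1L)
    off <- 8L + 3L + 2L + 8L + hlen
    bytes2 <- bytes
    bytes2[off + 1:8] <- as.raw(c(255, 255, 255, 255, 0, 0, 0, 0))
    writeBin(bytes2, corrupt)
    expect_error(readBlow5(corrupt), class = "slow5_truncated")

    future <- tempfile(fileext = ".blow5")
    bytes3 <- bytes
    bytes3[6] <- as.raw(9)  # container major version beyond this reader
    writeBin(bytes3, future)
    expect_error(readBlow5(future), class = "slow5_version_error")

    badmethod <- tempfile(fileext = ".blow5")
    bytes4 <- bytes
    bytes4[12] <- as.raw(7)  # record-method byte
    writeBin(bytes4, badmethod)
    expect_error(readBlow5(badmethod),
                 class = "slow5_unsupported_compression")
})

test_that("conversion chains preserve content; identity conversion is byte-identical", {
    s <- generateRecords(25, nReadGroups = 2L, meanLength = 120, seed = 21)
    ascii <- tempfile(fileext = ".slow5")
    writeSlow5(s, ascii)

    blow <- tempfile(fileext = ".blow5")
    convertSlow5(ascii, blow, "blow5", vbzConfig())
    back <- tempfile(fileext = ".slow5")
    convertSlow5(blow, back, "slow5")
    expect_identical(readBin(back, "raw", file.size(back)),
                     readBin(ascii, "raw", file.size(ascii)))

    ident <- tempfile(fileext = ".slow5")
    convertSlow5(ascii, ident, "slow5")
    expect_identical(readBin(ident, "raw", file.size(ident)),
                     readBin(ascii, "raw", file.size(ascii)))

    # recompressing zlib-only as vbz keeps content, shrinks random-walk data
    z <- tempfile(fileext = ".blow5")
    convertSlow5(ascii, z, "blow5", CompressionConfig("zlib", "none"))
    v <- tempfile(fileext = ".blow5")
    convertSlow5(z, v, "blow5", vbzConfig())
    expect_true(sets_equal(readSlow5(v), s))
    expect_lte(file.size(v), file.size(z))
})
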