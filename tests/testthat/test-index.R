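test_that("a header-only file yields an empty index", {
    for (fmt in c("slow5", "blow5")) {
        p <- tempfile(fileext = paste0(".", fmt))
        writeSlow5(Slow5Set(Slow5Header()), p, fmt)
        entries <- buildIndex(p)
        expect_identical(nrow(entries), 0L)
        idx <- loadIndex(p)
        expect_identical(length(idx), 0L)
    }
})

test_that("every index entry reparses to exactly its record (both formats)", {
    s <- table1Example()
    for (fmt in c("slow5", "blow5")) {
        p <- tempfile(fileext = paste0(".", fmt))
        writeSlow5(s, p, fmt, vbzConfig())
        entries <- buildIndex(p)
        expect_identical(nrow(entries), 3L)
        expect_true(all(entries$offset + entries$length <= file.size(p)))

        idx <- loadIndex(p)
        for (i in seq_len(nrow(entries))) {
            rec <- getRead(idx, entries$read_id[[i]])
            expect_identical(readID(rec), entries$read_id[[i]])
        }
        # Table 1 read1 has offset calibration 5
        expect_identical(adcOffset(getRead(idx, "read1")), 5)
    }
})

test_that("duplicate read ids abort indexing with the offending id", {
    s <- generateRecords(2, meanLength = 20, seed = 8)
    recs <- slow5Records(s)
    recs[[2]]@readID <- readID(recs[[1]])
    p <- tempfile(fileext = ".slow5")
    writeSlow5(Slow5Set(slow5Header(s), recs), p)
    err <- tryCatch(buildIndex(p), error = identity)
    expect_s3_class(err, "slow5_duplicate_id")
    expect_match(conditionMessage(err), readID(recs[[1]]), fixed = TRUE)
})

test_that("a regenerated data file makes the old index stale", {
    s <- generateRecords(5, meanLength = 30, seed = 4)
    p <- tempfile(fileext = ".slow5")
    writeSlow5(s, p)
    buildIndex(p)
    expect_s4_class(loadIndex(p), "Slow5Index")

    s2 <- generateRecords(6, meanLength = 30, seed = 5)
    writeSlow5(s2, p)
    expect_error(loadIndex(p), class = "slow5_stale_index")
})

test_that("lookup of an absent id is a not-found error", {
    p <- tempfile(fileext = ".blow5")
    writeSlow5(generateRecords(3, meanLength = 20, seed = 2), p, "blow5")
    buildIndex(p)
    idx <- loadIndex(p)
    expect_error(getRead(idx, "nope"), class = "slow5_not_found")
})

test_that("random access equals the sequential scan and scales to many entries", {
    s <- generateRecords(500, meanLength = 40, seed = 77)
    p <- tempfile(fileext = ".blow5")
    writeSlow5(s, p, "blow5", vbzConfig())
    buildIndex(p)
    idx <- loadIndex(p)
    expect_identical(length(idx), 500L)

    ids <- vapply(slow5Records(s), readID, character(1))
    fetched <- getReads(idx, sample(ids))   # shuffled access order
    expect_identical(recordSetChecksum(fetched),
                     recordSetChecksum(slow5Records(s)))
})

test_that("disjoint id partitions fetched by parallel workers union to the full set", {
    s <- generateRecords(200, meanLength = 30, seed = 13)
    p <- tempfile(fileext = ".blow5")
    writeSlow5(s, p, "blow5", vbzConfig())
    buildIndex(p)
    idx <- loadIndex(p)
    ids <- vapply(slow5Records(s), readID, character(1))
    quarters <- split(ids, rep(1:4, length.out = length(ids)))
    got <- parallel::mclapply(quarters, function(q) getReads(idx, q),
                              mc.cores = if (.Platform$OS.type == "unix")
                                  4L else 1L)
    union_recs <- unlist(got, recursive = FALSE, use.names = FALSE)
    expect_identical(recordSetChecksum(union_recs),
                     recordSetChecksum(slow5Records(s)))
})
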