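test_that("merging one file is the identity on content", {
    s <- generateRecords(8, meanLength = 40, seed = 31)
    p <- tempfile(fileext = ".slow5")
    writeSlow5(s, p)
    m <- mergeSlow5(p)
    expect_true(sets_equal(m, s))
})

test_that("distinct run metadata yields new groups with remapped records", {
    a <- generateRecords(3, meanLength = 30, seed = 41, idPrefix = "a")
    b <- generateRecords(2, meanLength = 30, seed = 42, idPrefix = "b")
    m <- mergeSlow5(list(a, b))
    expect_identical(numReadGroups(slow5Header(m)), 2L)
    groups <- vapply(slow5Records(m), readGroup, integer(1))
    expect_identical(groups, c(0L, 0L, 0L, 1L, 1L))
    # group 1 carries the second file's attribute values
    expect_identical(headerAttributes(slow5Header(m))$run_id[[2]],
                     headerAttributes(slow5Header(b))$run_id)
})

test_that("identical attribute maps collapse into one group", {
    a <- generateRecords(3, meanLength = 30, seed = 43, idPrefix = "a")
    b <- Slow5Set(slow5Header(a),
                  slow5Records(generateRecords(2, meanLength = 30,
                                               seed = 44, idPrefix = "b")))
    m <- mergeSlow5(list(a, b))
    expect_identical(numReadGroups(slow5Header(m)), 1L)
    expect_true(all(vapply(slow5Records(m), readGroup, integer(1)) == 0L))
})

test_that("merge rejects duplicate ids and mixed major versions", {
    a <- generateRecords(2, meanLength = 20, seed = 45)
    expect_error(mergeSlow5(list(a, a)), class = "slow5_duplicate_id")

    b <- generateRecords(2, meanLength = 20, seed = 46, idPrefix = "b")
    b@header@slow5Version <- "2.0.0"
    expect_error(mergeSlow5(list(a, b)), class = "slow5_version_error")
})

test_that("split by group resets read_group and inverts under merge", {
    s <- generateRecords(5, nReadGroups = 2L, meanLength = 30, seed = 47)
    d <- tempfile()
    paths <- splitSlow5(s, d, "group")
    expect_length(paths, 2L)
    per_group <- lapply(paths, readSlow5)
    for (g in per_group) {
        expect_identical(numReadGroups(slow5Header(g)), 1L)
        expect_true(all(vapply(slow5Records(g), readGroup,
                               integer(1)) == 0L))
    }
    counts <- vapply(per_group, length, integer(1))
    expect_identical(sum(counts), 5L)

    m <- mergeSlow5(paths)
    expect_identical(numReadGroups(slow5Header(m)), 2L)
    expect_identical(recordSetChecksum(slow5Records(m)),
                     recordSetChecksum(slow5Records(s)))
})

test_that("split by reads makes files of n records, last smaller", {
    s <- generateRecords(5, meanLength = 30, seed = 48)
    d <- tempfile()
    paths <- splitSlow5(s, d, "reads", n = 2L)
    expect_length(paths, 3L)
    expect_identical(vapply(paths, function(p) length(readSlow5(p)),
                            integer(1), USE.NAMES = FALSE),
                     c(2L, 2L, 1L))
    m <- mergeSlow5(paths)
    expect_true(sets_equal(m, s))
})

test_that("split by group on a record-less file emits header-only outputs", {
    h <- Slow5Header(numReadGroups = 2L,
                     attributes = list(run_id = c("x", "y")))
    d <- tempfile()
    paths <- splitSlow5(Slow5Set(h), d, "group")
    expect_length(paths, 2L)
    expect_identical(vapply(paths, function(p) length(readSlow5(p)),
                            integer(1), USE.NAMES = FALSE), c(0L, 0L))
})

test_that("stats reports exact counts and reflects encoding size differences", {
    ho <- tempfile(fileext = ".slow5")
    writeSlow5(Slow5Set(Slow5Header()), ho)
    expect_identical(slow5Stats(ho)$records, 0L)

    t1 <- tempfile(fileext = ".slow5")
    writeSlow5(table1Example(), t1)
    st <- slow5Stats(t1)
    expect_identical(st$records, 3L)
    expect_identical(st$readGroups, 1L)
    expect_identical(st$totalSamples, 123456 + 2000 + 3000)

    s <- generateRecords(50, meanLength = 300, seed = 51)
    pa <- tempfile(fileext = ".slow5"); writeSlow5(s, pa)
    pb <- tempfile(fileext = ".blow5"); writeSlow5(s, pb, "blow5",
                                                   vbzConfig())
    sa <- slow5Stats(pa); sb <- slow5Stats(pb)
    expect_identical(sa$records, sb$records)
    expect_identical(sa$totalSamples, sb$totalSamples)
    expect_lt(sb$bytes, sa$bytes)
    expect_identical(sb$compression, "zstd/svb")
})

test_that("the s5 command line mirrors the library operations", {
    script <- system.file("scripts", "s5.R", package = "slowfive")
    expect_true(nzchar(script))
    rscript <- file.path(R.home("bin"), "Rscript")
    run_s5 <- function(..., stdout = FALSE) {
        system2(rscript, c(script, ...), stdout = stdout, stderr = FALSE,
                env = paste0("R_LIBS=",
                             shQuote(paste(.libPaths(), collapse = ":"))))
    }

    src <- tempfile(fileext = ".slow5")
    writeSlow5(generateRecords(6, meanLength = 40, seed = 52), src)
    dst <- tempfile(fileext = ".blow5")
    expect_identical(run_s5("view", src, dst, "--vbz", "--to", "blow5"), 0L)
    expect_true(sets_equal(readSlow5(dst), readSlow5(src)))

    expect_identical(run_s5("index", dst), 0L)
    expect_true(file.exists(paste0(dst, ".idx")))

    out <- tempfile()
    expect_identical(run_s5("stats", dst, "--json", stdout = out), 0L)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        js <- jsonlite::fromJSON(paste(readLines(out), collapse = ""))
        expect_identical(js$records, 6L)
    }

    expect_identical(run_s5("stats", tempfile()), 1L)
    expect_identical(run_s5("frobnicate"), 2L)
})
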