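test_that("parseSlow5Header reads the worked-example header", {
    lines <- writeSlow5Header(slow5Header(table1Example()))
    out <- parseSlow5Header(lines)
    h <- out$header
    expect_identical(slow5Version(h), "1.0.0")
    expect_identical(numReadGroups(h), 1L)
    expect_identical(headerAttributes(h)$asic_id, "0004A30B00232BEC")
    expect_identical(headerAttributes(h)$flow_cell_id, "FAH00000")
    expect_identical(out$consumed, length(lines))
})

test_that("attribute rows carry one value per read group", {
    lines <- c("#slow5_version\t1.0.0", "#num_read_groups\t2",
               "@asic_id\tA\tB",
               paste0("#", paste(c("char*", "uint32_t", "double", "double",
                                   "double", "double", "uint64_t",
                                   "int16_t*"), collapse = "\t")),
               paste0("#", paste(c("read_id", "read_group", "digitisation",
                                   "offset", "range", "sampling_rate",
                                   "len_raw_signal", "raw_signal"),
                                 collapse = "\t")))
    h <- parseSlow5Header(lines)$header
    expect_identical(headerAttributes(h)$asic_id, c("A", "B"))

    bad <- lines
    bad[3] <- "@exp_start_time\tonly-one"
    expect_error(parseSlow5Header(bad), class = "slow5_group_arity")
})

test_that("malformed headers raise typed errors", {
    good <- writeSlow5Header(Slow5Header())
    expect_error(parseSlow5Header(good[-1]), class = "slow5_malformed_header")
    expect_error(parseSlow5Header(good[-4]), class = "slow5_malformed_header")
    shortened <- good
    shortened[3] <- sub("\tint16_t\\*$", "", shortened[3])  # type row loses a cell
    expect_error(parseSlow5Header(shortened), class = "slow5_schema_error")
    swapped <- good
    swapped[4] <- sub("read_id", "id_read", swapped[4])
    expect_error(parseSlow5Header(swapped), class = "slow5_schema_error")
})

test_that("writeSlow5Header emits the minimal 4-line block and round-trips", {
    minimal <- Slow5Header(numReadGroups = 1L)
    expect_length(writeSlow5Header(minimal), 4L)

    h <- slow5Header(table1Example())
    expect_true(identical(parseSlow5Header(writeSlow5Header(h))$header, h))

    # zero groups cannot carry attribute values: rejected at construction
    expect_error(Slow5Header(numReadGroups = 0L, attributes = list(a = "x")),
                 "read group")
})

test_that("parseSlow5Record parses the worked-example row exactly", {
    s <- table1Example()
    h <- slow5Header(s)
    line <- writeSlow5Record(s[["read1"]], h)
    r <- parseSlow5Record(line, h)
    expect_identical(readID(r), "read1")
    expect_identical(samplingRate(r), 4000)
    expect_identical(adcOffset(r), 5)
    expect_identical(digitisation(r), 8192)
    expect_identical(lenRawSignal(r), 2000)
})

test_that("empty signal cells, bad lengths and bad cells are handled", {
    h <- Slow5Header()
    r <- parseSlow5Record("r\t0\t1\t0\t1\t1\t0\t", h)
    expect_identical(rawSignal(r), integer())
    expect_identical(lenRawSignal(r), 0)

    expect_error(parseSlow5Record("r\t0\t1\t0\t1\t1\t2\t1,2,3", h),
                 class = "slow5_length_error")
    expect_error(parseSlow5Record("r\t0\t1\t0\t1\t1\t1", h),
                 class = "slow5_column_count")
    expect_error(parseSlow5Record("r\t0\tabc\t0\t1\t1\t1\t7", h),
                 class = "slow5_type_error")
})

test_that("record write/parse round trip is the identity, incl. aux values", {
    set.seed(7)
    s <- generateRecords(20, nReadGroups = 2L, meanLength = 80,
                         seed = 7)
    h <- slow5Header(s)
    for (r in slow5Records(s)) {
        line <- writeSlow5Record(r, h)
        expect_identical(rec_canon(parseSlow5Record(line, h)), rec_canon(r))
    }
    r2 <- slow5Records(s)[[1]]
    r2@signal <- c(498L, 492L); r2@lenRawSignal <- 2
    expect_match(writeSlow5Record(r2, h), "\t2\t498,492\t")
    r3 <- r2; r3@readID <- "bad\tid"
    expect_error(writeSlow5Record(r3, h), class = "slow5_validation_error")
})

test_that("whole-file round trip reproduces the set; CRLF is tolerated on read", {
    s <- generateRecords(30, nReadGroups = 3L, meanLength = 60, seed = 3)
    p <- tempfile(fileext = ".slow5")
    writeSlow5(s, p)
    expect_true(sets_equal(readSlow5(p), s))

    # the written bytes use bare "\n"; a CRLF copy parses identically
    crlf <- tempfile(fileext = ".slow5")
    txt <- readChar(p, file.size(p), useBytes = TRUE)
    expect_false(grepl("\r", txt, fixed = TRUE))
    writeBin(charToRaw(gsub("\n", "\r\n", txt, fixed = TRUE)), crlf)
    expect_true(sets_equal(readSlow5(crlf), s))
})

test_that("the streaming reader yields records one at a time in file order", {
    s <- generateRecords(10, meanLength = 50, seed = 9)
    p <- tempfile(fileext = ".slow5")
    writeSlow5(s, p)
    reader <- slow5Open(p)
    on.exit(slow5Close(reader))
    got <- list()
    repeat {
        r <- slow5ReadNext(reader)
        if (is.null(r)) break
        got[[length(got) + 1L]] <- r
    }
    expect_identical(lapply(got, rec_canon),
                     lapply(slow5Records(s), rec_canon))
})
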