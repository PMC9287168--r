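# Byte-offset index: read_id -> (offset, length).
#
# Index file layout (little-endian):
#   magic "S5IDX" + 1 version byte
#   u64 data file size, 8-byte FNV-1a checksum of the header block
#   per entry: u16 id length, id bytes, u64 offset, u64 length
#   trailing u64 entry count
#
# For ASCII files an entry covers the record's full line including its
# newline; for BLOW5 it covers the whole frame including the 8-byte length
# prefix, so seeking to `offset` and reading `length` bytes always yields a
# self-contained decodable unit.

S5IDX_MAGIC <- c(charToRaw("S5IDX"), as.raw(0x01))

.header_block_bytes <- function(path, format) {
    if (format == "blow5") {
        con <- file(path, "rb")
        on.exit(close(con), add = TRUE)
        .read_blow5_preamble(con)$header_bytes
    } else {
        reader <- slow5Open(path)
        on.exit(slow5Close(reader), add = TRUE)
        charToRaw(paste0(paste(writeSlow5Header(reader$header),
                               collapse = "\n"), "\n"))
    }
}

.scan_offsets <- function(path) {
    format <- sniffSlow5(path)
    ids <- character(); offs <- numeric(); lens <- numeric()
    if (format == "blow5") {
        con <- file(path, "rb")
        on.exit(close(con), add = TRUE)
        pre <- .read_blow5_preamble(con)
        pos <- 8 + 3 + 2 + 8 + length(pre$header_bytes)
        repeat {
            lenb <- readBin(con, "raw", 8L)
            if (length(lenb) < 8L)
                s5_stop("slow5_truncated",
                        "file ends without the EOF sentinel")
            if (identical(lenb, BLOW5_EOF)) break
            flen <- .unpack_uint(lenb)
            if (flen > file.size(path) - seek(con, NA))
                s5_stop("slow5_truncated",
                        "frame length %.0f exceeds the remaining file at offset %.0f",
                        flen, pos)
            payload <- readBin(con, "raw", flen)
            if (length(payload) < flen)
                s5_stop("slow5_truncated",
                        "record frame truncated at offset %.0f", pos)
            rec <- .decode_record_payload(payload, pre$header, pre$config)
            ids <- c(ids, rec@readID)
            offs <- c(offs, pos)
            lens <- c(lens, 8 + flen)
            pos <- pos + 8 + flen
        }
    } else {
        lines <- readLines(path)
        nheader <- parseSlow5Header(lines)$consumed
        header <- parseSlow5Header(lines)$header
        pos <- sum(nchar(lines[seq_len(nheader)], type = "bytes") + 1L)
        for (ln in lines[-seq_len(nheader)]) {
            nb <- nchar(ln, type = "bytes") + 1L
            if (nzchar(sub("\r$", "", ln))) {
                rec <- parseSlow5Record(ln, header)
                ids <- c(ids, rec@readID)
                offs <- c(offs, pos)
                lens <- c(lens, nb)
            }
            pos <- pos + nb
        }
    }
    dup <- anyDuplicated(ids)
    if (dup)
        s5_stop("slow5_duplicate_id",
                "duplicate read id '%s' in %s", ids[dup], path)
    list(format = format, ids = ids, offsets = offs, lengths = lens)
}

#' Build the random-access index of a SLOW5/BLOW5 file
#'
#' Scans the data file end to end, records each read's byte offset and
#' byte length, and writes the binary index next to the data file (default
#' `<path>.idx`).  The index stores the data file's size and a 64-bit
#' checksum of its header block so a stale index is detected on load.
#'
#' @param path data file path.
#' @param indexPath output index path; default appends `.idx`.
#' @return invisibly, a data.frame of entries (read_id, offset, length).
#' @export
buildIndex <- function(path, indexPath = paste0(path, ".idx")) {
    scan <- .scan_offsets(path)
    hchk <- fnv64(.header_block_bytes(path, scan$format))
    con <- file(indexPath, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(S5IDX_MAGIC, con)
    writeBin(.pack_u64(file.size(path)), con)
    writeBin(hchk, con)
    for (i in seq_along(scan$ids)) {
        id <- charToRaw(scan$ids[[i]])
        writeBin(c(.pack_u16(length(id)), id,
                   .pack_u64(scan$offsets[[i]]),
                   .pack_u64(scan$lengths[[i]])), con)
    }
    writeBin(.pack_u64(length(scan$ids)), con)
    invisible(data.frame(read_id = scan$ids, offset = scan$offsets,
                         length = scan$lengths))
}

#' Load an index into memory
#'
#' Reads the binary index into a hashed environment keyed by read
#' identifier (O(1) expected lookup) and caches the data file's parsed
#' header and compression configuration.  Loading fails with a staleness
#' error if the data file's size or header checksum no longer match what
#' the index recorded.
#'
#' @param path data file path.
#' @param indexPath index file path; default `<path>.idx`.
#' @return a [Slow5Index-class].
#' @export
loadIndex <- function(path, indexPath = paste0(path, ".idx")) {
    if (!file.exists(indexPath))
        s5_stop("slow5_io_error", "no index file at %s", indexPath)
    bytes <- readBin(indexPath, "raw", file.size(indexPath))
    if (length(bytes) < 30L || !identical(bytes[1:6], S5IDX_MAGIC))
        s5_stop("slow5_decode_error", "not a SLOW5 index file: %s", indexPath)
    stored_size <- .unpack_uint(bytes[7:14])
    stored_chk <- bytes[15:22]
    format <- sniffSlow5(path)
    if (!isTRUE(file.size(path) == stored_size))
        s5_stop("slow5_stale_index",
                "index is stale: data file size changed (%s)", path)
    hbytes <- .header_block_bytes(path, format)
    if (!identical(fnv64(hbytes), stored_chk))
        s5_stop("slow5_stale_index",
                "index is stale: data file header changed (%s)", path)
    n_entries <- .unpack_uint(bytes[length(bytes) - 7:0])
    env <- new.env(hash = TRUE, parent = emptyenv(),
                   size = max(29L, n_entries))
    ids <- character(n_entries)
    off <- 22L
    for (i in seq_len(n_entries)) {
        idlen <- .unpack_uint(bytes[off + 1:2]); off <- off + 2L
        id <- rawToChar(bytes[off + seq_len(idlen)]); off <- off + idlen
        entry <- c(.unpack_uint(bytes[off + 1:8]),
                   .unpack_uint(bytes[off + 9:16]))
        off <- off + 16L
        assign(id, entry, envir = env)
        ids[i] <- id
    }
    if (off + 8L != length(bytes))
        s5_stop("slow5_decode_error", "index file has trailing garbage")
    hlines <- strsplit(rawToChar(hbytes), "\n", fixed = TRUE)[[1L]]
    header <- parseSlow5Header(hlines)$header
    config <- if (format == "blow5") {
        con <- file(path, "rb")
        on.exit(close(con), add = TRUE)
        .read_blow5_preamble(con)$config
    } else CompressionConfig()
    new("Slow5Index", dataPath = path, format = format, header = header,
        config = config, entries = env, readIDs = ids)
}

setMethod("show", "Slow5Index", function(object) {
    cat("Slow5Index of ", object@dataPath, " (", object@format, "): ",
        length(object@readIDs), " read(s)\n", sep = "")
})

#' @describeIn loadIndex number of indexed reads.
#' @param x a `Slow5Index`.
#' @export
setMethod("length", "Slow5Index", function(x) length(x@readIDs))

.decode_at <- function(con, index, entry) {
    seek(con, entry[1L])
    bytes <- readBin(con, "raw", entry[2L])
    if (length(bytes) < entry[2L])
        s5_stop("slow5_decode_error",
                "short read at offset %.0f of %s", entry[1L],
                index@dataPath)
    if (index@format == "blow5") {
        flen <- .unpack_uint(bytes[1:8])
        if (flen != entry[2L] - 8)
            s5_stop("slow5_decode_error",
                    "frame length mismatch at offset %.0f", entry[1L])
        .decode_record_payload(bytes[-(1:8)], index@header, index@config)
    } else {
        line <- sub("\r?\n?$", "", rawToChar(bytes))
        parseSlow5Record(line, index@header)
    }
}

#' Random access to single reads
#'
#' `getRead` fetches one record by identifier; `getReads` fetches several
#' through one connection.  Each call supplies its own byte offset from the
#' loaded index, so any number of concurrent workers (each holding its own
#' connection to the same file) can fetch reads with no locking, and the
#' result never depends on how many workers share the file.
#'
#' @param index a [Slow5Index-class] from [loadIndex()].
#' @param readID read identifier (one for `getRead`, a vector for
#'   `getReads`).
#' @return `getRead`: a [Slow5Record-class]. `getReads`: a named list of
#'   records.
#' @export
getRead <- function(index, readID) {
    entry <- get0(readID, envir = index@entries)
    if (is.null(entry))
        s5_stop("slow5_not_found", "read id '%s' not in index", readID)
    con <- file(index@dataPath, "rb")
    on.exit(close(con), add = TRUE)
    .decode_at(con, index, entry)
}

#' @rdname getRead
#' @export
getReads <- function(index, readID) {
    con <- file(index@dataPath, "rb")
    on.exit(close(con), add = TRUE)
    out <- vector("list", length(readID))
    for (i in seq_along(readID)) {
        entry <- get0(readID[[i]], envir = index@entries)
        if (is.null(entry))
            s5_stop("slow5_not_found", "read id '%s' not in index",
                    readID[[i]])
        out[[i]] <- .decode_at(con, index, entry)
    }
    names(out) <- readID
    out
}
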