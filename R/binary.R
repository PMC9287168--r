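# BLOW5 binary container.
#
# Layout (all integers little-endian):
#   magic            8 bytes: "BLOW5" 0x01 0x00 0x00
#   version          3 bytes: major, minor, patch of slow5_version
#   record_method    1 byte : 0 none, 1 zlib, 2 zstd
#   signal_method    1 byte : 0 none, 1 svb
#   num_read_groups  4 bytes
#   header_length    4 bytes, then the ASCII header text, uncompressed
#   frames           per record: 8-byte payload length + payload
#   EOF sentinel     8 bytes: the magic reversed
#
# Record payload before record-level compression:
#   u16 id length, id bytes, u32 read_group,
#   doubles digitisation/offset/range/sampling_rate,
#   u64 len_raw_signal, u64 signal blob length, signal blob
#   (per signal_method), u16 aux count, then per aux cell:
#   u32 length + ASCII cell bytes (rendered exactly as in the ASCII format).

BLOW5_MAGIC <- as.raw(c(0x42, 0x4C, 0x4F, 0x57, 0x35, 0x01, 0x00, 0x00))
BLOW5_EOF <- rev(BLOW5_MAGIC)
BLOW5_WRITER_MAJOR <- 1L

.method_codes <- c(none = 0L, zlib = 1L, zstd = 2L)
.signal_codes <- c(none = 0L, svb = 1L)

.version_triple <- function(version) {
    p <- suppressWarnings(as.integer(strsplit(version, ".",
                                              fixed = TRUE)[[1L]]))
    p <- p[!is.na(p)]
    as.integer(c(p, 0L, 0L, 0L)[1:3])
}

.encode_record_payload <- function(record, header, config) {
    id <- charToRaw(record@readID)
    blob <- compressSignal(record@signal, config@signalMethod)
    aux <- raw()
    if (length(header@auxNames)) {
        cells <- vapply(seq_along(header@auxNames), function(j) {
            nm <- header@auxNames[[j]]
            val <- if (nm %in% names(record@aux)) record@aux[[nm]] else NA
            .write_aux_cell(val, header@auxTypes[[j]])
        }, character(1))
        aux <- do.call(c, lapply(cells, function(cell) {
            b <- charToRaw(cell)
            c(.pack_u32(length(b)), b)
        }))
    }
    payload <- c(.pack_u16(length(id)), id,
                 .pack_u32(record@readGroup),
                 .pack_doubles(c(record@digitisation, record@offset,
                                 record@range, record@samplingRate)),
                 .pack_u64(record@lenRawSignal),
                 .pack_u64(length(blob)), blob,
                 .pack_u16(length(header@auxNames)), aux)
    compressRecordPayload(payload, config@recordMethod, config@zstdLevel)
}

.decode_record_payload <- function(bytes, header, config) {
    p <- decompressRecordPayload(bytes, config@recordMethod)
    need <- function(k, off) {
        if (off + k > length(p))
            s5_stop("slow5_decode_error",
                    "record payload truncated at byte %d", off)
    }
    off <- 0L
    need(2L, off); idlen <- .unpack_uint(p[off + 1:2]); off <- off + 2L
    need(idlen, off)
    id <- rawToChar(p[off + seq_len(idlen)]); off <- off + idlen
    need(4L, off); rg <- .unpack_uint(p[off + 1:4]); off <- off + 4L
    need(32L, off); cal <- .unpack_doubles(p[off + 1:32]); off <- off + 32L
    need(8L, off); len <- .unpack_uint(p[off + 1:8]); off <- off + 8L
    need(8L, off); bloblen <- .unpack_uint(p[off + 1:8]); off <- off + 8L
    need(bloblen, off)
    signal <- decompressSignal(p[off + seq_len(bloblen)],
                               config@signalMethod)
    off <- off + bloblen
    need(2L, off); naux <- .unpack_uint(p[off + 1:2]); off <- off + 2L
    if (naux != length(header@auxNames))
        s5_stop("slow5_decode_error",
                "record carries %d aux cell(s) but header declares %d",
                naux, length(header@auxNames))
    aux <- list()
    if (naux > 0L) {
        aux <- vector("list", naux)
        for (j in seq_len(naux)) {
            need(4L, off); clen <- .unpack_uint(p[off + 1:4]); off <- off + 4L
            need(clen, off)
            cell <- if (clen) rawToChar(p[off + seq_len(clen)]) else ""
            off <- off + clen
            aux[[j]] <- .parse_aux_cell(cell, header@auxTypes[[j]])
        }
        names(aux) <- header@auxNames
    }
    Slow5Record(readID = id, readGroup = rg, digitisation = cal[1L],
                offset = cal[2L], range = cal[3L], samplingRate = cal[4L],
                signal = signal, lenRawSignal = len, aux = aux)
}

#' Write a BLOW5 binary file
#'
#' Streams records one frame at a time: each record is serialized,
#' optionally signal- and record-compressed, length-prefixed and appended;
#' the file ends with an 8-byte end-of-file sentinel so truncation is
#' detectable.
#'
#' @param header a [Slow5Header-class].
#' @param records list of [Slow5Record-class] objects, or a
#'   [Slow5Set-class].
#' @param path output file path.
#' @param config a [CompressionConfig-class].
#' @return invisibly, a list with `records` written and total `bytes`.
#' @export
writeBlow5 <- function(header, records, path, config = CompressionConfig()) {
    if (is(header, "Slow5Set")) {
        records <- header@records
        header <- header@header
    }
    validObject(config)
    hv <- validObject(header, test = TRUE)
    if (!isTRUE(hv))
        s5_stop("slow5_schema_error", "invalid header: %s", hv[1L])
    header_text <- paste0(paste(writeSlow5Header(header), collapse = "\n"),
                          "\n")
    hbytes <- charToRaw(header_text)
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(BLOW5_MAGIC, con)
    writeBin(as.raw(.version_triple(header@slow5Version)), con)
    writeBin(as.raw(.method_codes[[config@recordMethod]]), con)
    writeBin(as.raw(.signal_codes[[config@signalMethod]]), con)
    writeBin(.pack_u32(header@numReadGroups), con)
    writeBin(.pack_u32(length(hbytes)), con)
    writeBin(hbytes, con)
    nbytes <- 8 + 3 + 2 + 8 + length(hbytes)
    nrec <- 0L
    for (rec in records) {
        viol <- validateRecord(rec, header)
        if (length(viol))
            s5_stop("slow5_validation_error", "invalid record '%s': %s",
                    rec@readID, viol[1L])
        payload <- .encode_record_payload(rec, header, config)
        writeBin(c(.pack_u64(length(payload)), payload), con)
        nbytes <- nbytes + 8 + length(payload)
        nrec <- nrec + 1L
    }
    writeBin(BLOW5_EOF, con)
    invisible(list(records = nrec, bytes = nbytes + 8))
}

.read_blow5_preamble <- function(con) {
    magic <- readBin(con, "raw", 8L)
    if (length(magic) < 8L || !identical(magic[1:5], BLOW5_MAGIC[1:5]))
        s5_stop("slow5_not_blow5", "file does not start with the BLOW5 magic")
    if (as.integer(magic[6L]) > BLOW5_WRITER_MAJOR)
        s5_stop("slow5_version_error",
                "container major version %d is newer than this reader",
                as.integer(magic[6L]))
    readBin(con, "raw", 3L)  # file format version triple (informational)
    rm_code <- as.integer(readBin(con, "raw", 1L))
    sm_code <- as.integer(readBin(con, "raw", 1L))
    if (!rm_code %in% .method_codes || !sm_code %in% .signal_codes)
        s5_stop("slow5_unsupported_compression",
                "unknown compression method byte (record %d, signal %d)",
                rm_code, sm_code)
    readBin(con, "raw", 4L)  # num_read_groups; authoritative copy is in text
    hlen <- .unpack_uint(readBin(con, "raw", 4L))
    hbytes <- readBin(con, "raw", hlen)
    if (length(hbytes) < hlen)
        s5_stop("slow5_truncated", "header block truncated")
    hlines <- strsplit(rawToChar(hbytes), "\n", fixed = TRUE)[[1L]]
    header <- parseSlow5Header(hlines)$header
    config <- CompressionConfig(
        names(.method_codes)[match(rm_code, .method_codes)],
        names(.signal_codes)[match(sm_code, .signal_codes)])
    list(header = header, config = config, header_bytes = hbytes)
}

#' Read a BLOW5 binary file
#'
#' @param path path to a `.blow5` file.
#' @return a list with elements `set` (a [Slow5Set-class]) and `config`
#'   (the file's [CompressionConfig-class]).
#' @export
readBlow5 <- function(path) {
    fsize <- file.size(path)
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    pre <- .read_blow5_preamble(con)
    records <- list()
    repeat {
        lenb <- readBin(con, "raw", 8L)
        if (length(lenb) < 8L)
            s5_stop("slow5_truncated",
                    "file ends without the EOF sentinel (offset %.0f)",
                    seek(con, NA))
        if (identical(lenb, BLOW5_EOF)) break
        flen <- .unpack_uint(lenb)
        if (flen > fsize - seek(con, NA))
            s5_stop("slow5_truncated",
                    "frame length %.0f exceeds the remaining file (offset %.0f)",
                    flen, seek(con, NA) - 8)
        payload <- readBin(con, "raw", flen)
        if (length(payload) < flen)
            s5_stop("slow5_truncated",
                    "record frame truncated at offset %.0f",
                    seek(con, NA) - length(payload))
        records[[length(records) + 1L]] <-
            .decode_record_payload(payload, pre$header, pre$config)
    }
    list(set = Slow5Set(pre$header, records), config = pre$config)
}
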