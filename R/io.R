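# Format-agnostic entry points: sniff ASCII vs binary, stream records, read
# or write whole files, convert between encodings.

#' Detect whether a file is SLOW5 ASCII or BLOW5 binary
#'
#' @param path file path.
#' @return `"slow5"` or `"blow5"`.
#' @export
sniffSlow5 <- function(path) {
    if (!file.exists(path))
        s5_stop("slow5_io_error", "no such file: %s", path)
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    head8 <- readBin(con, "raw", 8L)
    if (length(head8) >= 5L && identical(head8[1:5], BLOW5_MAGIC[1:5]))
        "blow5" else "slow5"
}

#' Stream records from a SLOW5/BLOW5 file one at a time
#'
#' `slow5Open` parses the header and positions a connection at the first
#' record; `slow5ReadNext` yields the next [Slow5Record-class] or `NULL`
#' at end of file; `slow5Close` releases the connection.  Memory use is
#' one record regardless of file size.
#'
#' @param path file path (either encoding; sniffed from the magic bytes).
#' @param reader object returned by `slow5Open`.
#' @return `slow5Open`: a reader object with elements `header`, `config`
#'   and `format`.
#' @export
slow5Open <- function(path) {
    fmt <- sniffSlow5(path)
    env <- new.env(parent = emptyenv())
    env$format <- fmt
    env$size <- file.size(path)
    if (fmt == "blow5") {
        env$con <- file(path, "rb")
        pre <- .read_blow5_preamble(env$con)
        env$header <- pre$header
        env$config <- pre$config
    } else {
        env$con <- file(path, "r")
        lines <- character()
        repeat {
            ln <- readLines(env$con, n = 1L)
            if (!length(ln))
                s5_stop("slow5_malformed_header",
                        "file ended inside the header")
            lines <- c(lines, ln)
            # the header ends at the second '#'-prefixed schema row
            if (startsWith(ln, "#") &&
                !startsWith(ln, "#slow5_version") &&
                !startsWith(ln, "#num_read_groups") &&
                sum(startsWith(lines, "#")) >= 4L)
                break
        }
        env$header <- parseSlow5Header(lines)$header
        env$config <- CompressionConfig()
    }
    structure(list(env = env, header = env$header, config = env$config,
                   format = fmt, path = path),
              class = "slow5_reader")
}

#' @rdname slow5Open
#' @export
slow5ReadNext <- function(reader) {
    env <- reader$env
    if (env$format == "blow5") {
        lenb <- readBin(env$con, "raw", 8L)
        if (length(lenb) < 8L)
            s5_stop("slow5_truncated", "file ends without the EOF sentinel")
        if (identical(lenb, BLOW5_EOF)) return(NULL)
        flen <- .unpack_uint(lenb)
        if (flen > env$size - seek(env$con, NA))
            s5_stop("slow5_truncated",
                    "frame length %.0f exceeds the remaining file", flen)
        payload <- readBin(env$con, "raw", flen)
        if (length(payload) < flen)
            s5_stop("slow5_truncated", "record frame truncated")
        .decode_record_payload(payload, env$header, env$config)
    } else {
        repeat {
            ln <- readLines(env$con, n = 1L)
            if (!length(ln)) return(NULL)
            if (nzchar(sub("\r$", "", ln)))
                return(parseSlow5Record(ln, env$header))
        }
    }
}

#' @rdname slow5Open
#' @export
slow5Close <- function(reader) {
    close(reader$env$con)
    invisible(NULL)
}

#' Read a whole SLOW5/BLOW5 file into memory
#'
#' The encoding is sniffed from the leading bytes, so one reader serves
#' both formats.
#'
#' @param path file path.
#' @return a [Slow5Set-class]; its `config` attribute (accessible with
#'   `attr(x, "config")`) records the compression the file used.
#' @export
readSlow5 <- function(path) {
    reader <- slow5Open(path)
    on.exit(slow5Close(reader), add = TRUE)
    records <- list()
    repeat {
        rec <- slow5ReadNext(reader)
        if (is.null(rec)) break
        records[[length(records) + 1L]] <- rec
    }
    out <- Slow5Set(reader$header, records)
    attr(out, "config") <- reader$config
    out
}

#' Write a SLOW5/BLOW5 file
#'
#' @param x a [Slow5Set-class].
#' @param path output path.
#' @param format `"slow5"` (ASCII) or `"blow5"` (binary).
#' @param config a [CompressionConfig-class]; only used for `"blow5"`.
#' @return invisibly, the output path.
#' @export
writeSlow5 <- function(x, path, format = c("slow5", "blow5"),
                       config = CompressionConfig()) {
    format <- match.arg(format)
    if (format == "blow5") {
        writeBlow5(x@header, x@records, path, config)
    } else {
        lines <- c(writeSlow5Header(x@header),
                   vapply(x@records, writeSlow5Record, character(1),
                          header = x@header))
        con <- file(path, "wb")  # binary mode: exact "\n" terminators
        on.exit(close(con), add = TRUE)
        writeLines(lines, con, sep = "\n", useBytes = TRUE)
    }
    invisible(path)
}

#' Convert between SLOW5 encodings
#'
#' Streams the source file record by record into the target encoding.
#' Conversion is lossless: header and records are equal after any chain of
#' conversions (doubles are rendered with their shortest exact decimal
#' form in ASCII).
#'
#' @param input source file (either encoding).
#' @param output target path.
#' @param format target encoding, `"slow5"` or `"blow5"`.
#' @param config target [CompressionConfig-class] (blow5 only).
#' @return invisibly, the output path.
#' @export
convertSlow5 <- function(input, output, format = c("slow5", "blow5"),
                         config = CompressionConfig()) {
    format <- match.arg(format)
    set <- readSlow5(input)
    writeSlow5(set, output, format = format, config = config)
    invisible(output)
}
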