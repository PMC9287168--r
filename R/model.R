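# Domain model: constructors, accessors, validation, pA conversion.

#' @rdname Slow5Header-class
#' @param slow5Version dotted version string.
#' @param numReadGroups number of read groups.
#' @param attributes named list of per-group attribute value vectors.
#' @param auxNames,auxTypes auxiliary column schema.
#' @export
Slow5Header <- function(slow5Version = "1.0.0", numReadGroups = 1L,
                        attributes = list(), auxNames = character(),
                        auxTypes = character()) {
    attributes <- lapply(attributes, as.character)
    new("Slow5Header", slow5Version = as.character(slow5Version),
        numReadGroups = as.integer(numReadGroups), attributes = attributes,
        auxNames = as.character(auxNames), auxTypes = as.character(auxTypes))
}

#' @rdname Slow5Record-class
#' @param readID read identifier.
#' @param readGroup zero-based read-group index.
#' @param digitisation,offset,range,samplingRate calibration constants.
#' @param signal integer vector of raw ADC values.
#' @param lenRawSignal declared signal length; defaults to `length(signal)`.
#' @param aux named list of auxiliary values (missing = `NA`).
#' @export
Slow5Record <- function(readID, readGroup = 0L, digitisation = 1,
                        offset = 0, range = 1, samplingRate = 1,
                        signal = integer(), lenRawSignal = length(signal),
                        aux = list()) {
    new("Slow5Record", readID = as.character(readID),
        readGroup = as.integer(readGroup),
        digitisation = as.numeric(digitisation), offset = as.numeric(offset),
        range = as.numeric(range), samplingRate = as.numeric(samplingRate),
        lenRawSignal = as.numeric(lenRawSignal),
        signal = as.integer(signal), aux = aux)
}

#' @rdname CompressionConfig-class
#' @param recordMethod record-level compression method.
#' @param signalMethod signal-level compression method.
#' @param zstdLevel zstd compression level.
#' @export
CompressionConfig <- function(recordMethod = c("none", "zlib", "zstd"),
                              signalMethod = c("none", "svb"),
                              zstdLevel = 1L) {
    new("CompressionConfig", recordMethod = match.arg(recordMethod),
        signalMethod = match.arg(signalMethod),
        zstdLevel = as.integer(zstdLevel))
}

#' @rdname CompressionConfig-class
#' @details `vbzConfig()` returns the `vbz` preset: StreamVByte on the
#'   signal, then Zstandard on the whole record.
#' @export
vbzConfig <- function(zstdLevel = 1L) {
    CompressionConfig("zstd", "svb", zstdLevel = zstdLevel)
}

#' @rdname Slow5Set-class
#' @param header a [Slow5Header-class].
#' @param records list of [Slow5Record-class] objects.
#' @export
Slow5Set <- function(header = Slow5Header(), records = list()) {
    new("Slow5Set", header = header, records = records)
}

# ---- accessors ---------------------------------------------------------------

#' @rdname Slow5Header-class
#' @param x object.
#' @export
setMethod("slow5Version", "Slow5Header", function(x) x@slow5Version)
#' @rdname Slow5Header-class
#' @export
setMethod("numReadGroups", "Slow5Header", function(x) x@numReadGroups)
#' @rdname Slow5Header-class
#' @export
setMethod("headerAttributes", "Slow5Header", function(x) x@attributes)
#' @rdname Slow5Header-class
#' @export
setMethod("auxSchema", "Slow5Header", function(x)
    data.frame(name = x@auxNames, type = x@auxTypes))

#' @rdname Slow5Record-class
#' @param x object.
#' @export
setMethod("readID", "Slow5Record", function(x) x@readID)
#' @rdname Slow5Record-class
#' @export
setMethod("readGroup", "Slow5Record", function(x) x@readGroup)
#' @rdname Slow5Record-class
#' @export
setMethod("digitisation", "Slow5Record", function(x) x@digitisation)
#' @rdname Slow5Record-class
#' @export
setMethod("adcOffset", "Slow5Record", function(x) x@offset)
#' @rdname Slow5Record-class
#' @export
setMethod("adcRange", "Slow5Record", function(x) x@range)
#' @rdname Slow5Record-class
#' @export
setMethod("samplingRate", "Slow5Record", function(x) x@samplingRate)
#' @rdname Slow5Record-class
#' @export
setMethod("lenRawSignal", "Slow5Record", function(x) x@lenRawSignal)
#' @rdname Slow5Record-class
#' @export
setMethod("rawSignal", "Slow5Record", function(x) x@signal)
#' @rdname Slow5Record-class
#' @export
setMethod("auxValues", "Slow5Record", function(x) x@aux)

#' @rdname Slow5Set-class
#' @param x object.
#' @export
setMethod("slow5Header", "Slow5Set", function(x) x@header)
#' @rdname Slow5Set-class
#' @export
setMethod("slow5Records", "Slow5Set", function(x) x@records)
#' @rdname Slow5Set-class
#' @export
setMethod("length", "Slow5Set", function(x) length(x@records))
#' @rdname Slow5Set-class
#' @param i record index or read id.
#' @export
setMethod("[[", "Slow5Set", function(x, i) {
    if (is.character(i)) {
        hit <- which(vapply(x@records, readID, character(1)) == i)
        if (!length(hit))
            s5_stop("slow5_not_found", "read id '%s' not in set", i)
        i <- hit[1L]
    }
    x@records[[i]]
})

# ---- show --------------------------------------------------------------------

setMethod("show", "Slow5Header", function(object) {
    cat("Slow5Header v", object@slow5Version, ", ",
        object@numReadGroups, " read group(s), ",
        length(object@attributes), " attribute(s), ",
        length(object@auxNames), " aux column(s)\n", sep = "")
})

setMethod("show", "Slow5Record", function(object) {
    cat("Slow5Record '", object@readID, "' (group ", object@readGroup,
        "): ", object@lenRawSignal, " samples @ ", object@samplingRate,
        " Hz\n", sep = "")
})

setMethod("show", "Slow5Set", function(object) {
    show(object@header)
    cat(length(object@records), "record(s)\n")
})

setMethod("show", "CompressionConfig", function(object) {
    preset <- if (object@recordMethod == "zstd" &&
                  object@signalMethod == "svb") " [vbz]" else ""
    cat("CompressionConfig: record=", object@recordMethod, " signal=",
        object@signalMethod, preset, "\n", sep = "")
})

# ---- validation --------------------------------------------------------------

#' Validate a record against a header
#'
#' Checks every record invariant and returns the violations as data rather
#' than raising: the declared signal length must match the stored signal,
#' the read-group index must exist in the header, every signal value must
#' fit a signed 16-bit integer, calibration constants must be in range, and
#' auxiliary values must match the header's auxiliary schema.
#'
#' @param record a [Slow5Record-class].
#' @param header a [Slow5Header-class].
#' @return character vector of violation messages; empty when valid.
#' @examples
#' h <- Slow5Header()
#' validateRecord(Slow5Record("r1", signal = c(1L, 2L)), h)
#' @export
validateRecord <- function(record, header) {
    v <- character()
    if (!nzchar(record@readID) || is.na(record@readID))
        v <- c(v, "read_id must be a non-empty string")
    if (grepl("[\t\n,]", record@readID))
        v <- c(v, "read_id must not contain tab, newline or comma")
    if (is.na(record@lenRawSignal) ||
        record@lenRawSignal != length(record@signal))
        v <- c(v, sprintf(
            "len_raw_signal (%s) does not match signal length (%d)",
            format(record@lenRawSignal), length(record@signal)))
    if (is.na(record@readGroup) || record@readGroup < 0L ||
        record@readGroup >= header@numReadGroups)
        v <- c(v, sprintf(
            "read_group %d outside [0, %d)", record@readGroup,
            header@numReadGroups))
    if (length(record@signal) && !.is_int16(record@signal))
        v <- c(v, "raw_signal values must fit a signed 16-bit integer")
    if (is.na(record@digitisation) || record@digitisation <= 0)
        v <- c(v, "digitisation must be positive")
    if (is.na(record@range) || record@range <= 0)
        v <- c(v, "range must be positive")
    if (is.na(record@samplingRate) || record@samplingRate <= 0)
        v <- c(v, "sampling_rate must be positive")
    extra <- setdiff(names(record@aux), header@auxNames)
    if (length(extra))
        v <- c(v, paste0("auxiliary value(s) not in header schema: ",
                         paste(extra, collapse = ", ")))
    v
}

#' @rdname toPicoamps
#' @export
setMethod("toPicoamps", "Slow5Record", function(x) {
    if (is.na(x@digitisation) || x@digitisation <= 0)
        s5_stop("slow5_invalid_calibration",
                "digitisation must be positive, got %s",
                format(x@digitisation))
    (as.numeric(x@signal) + x@offset) * x@range / x@digitisation
})
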