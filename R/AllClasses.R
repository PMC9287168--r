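#' @import methods
NULL

# Fixed primary column schema: every SLOW5 file has exactly these eight
# columns, in this order, with these type tags.
PRIMARY_COLUMNS <- c("read_id", "read_group", "digitisation", "offset",
                     "range", "sampling_rate", "len_raw_signal", "raw_signal")
PRIMARY_TYPES <- c("char*", "uint32_t", "double", "double", "double",
                   "double", "uint64_t", "int16_t*")

AUX_SCALAR_TYPES <- c("int8_t", "int16_t", "int32_t", "int64_t",
                      "uint8_t", "uint16_t", "uint32_t", "uint64_t",
                      "float", "double", "char", "string", "char*")
AUX_TYPES <- c(AUX_SCALAR_TYPES,
               paste0(setdiff(AUX_SCALAR_TYPES, c("char", "string", "char*")), "*"))

#' Global metadata of a SLOW5/BLOW5 file
#'
#' A `Slow5Header` holds the file-level metadata: the format version, the
#' number of read groups (sequencing runs) the file contains, an ordered map
#' of run attributes with one value per read group, and the auxiliary-column
#' schema.  The eight primary columns are fixed by the format and are not
#' stored.
#'
#' @slot slow5Version dotted version string, e.g. `"1.0.0"`.
#' @slot numReadGroups integer, number of read groups (>= 1 once the file
#'   holds records).
#' @slot attributes named list; each element is a character vector of length
#'   `numReadGroups` giving that attribute's value per group.
#' @slot auxNames,auxTypes character vectors (possibly empty) describing the
#'   auxiliary columns appended after the primary eight.
#'
#' @examples
#' h <- Slow5Header(numReadGroups = 1L,
#'                  attributes = list(run_id = "a1b2"))
#' numReadGroups(h)
#' @export
setClass("Slow5Header",
    representation(slow5Version = "character",
                   numReadGroups = "integer",
                   attributes = "list",
                   auxNames = "character",
                   auxTypes = "character"),
    prototype(slow5Version = "1.0.0", numReadGroups = 1L,
              attributes = list(), auxNames = character(),
              auxTypes = character()))

setValidity("Slow5Header", function(object) {
    msgs <- character()
    if (length(object@slow5Version) != 1L ||
        !grepl("^[0-9]+(\\.[0-9]+)*$", object@slow5Version))
        msgs <- c(msgs, "slow5Version must be a dotted version string")
    if (length(object@numReadGroups) != 1L || is.na(object@numReadGroups) ||
        object@numReadGroups < 0L)
        msgs <- c(msgs, "numReadGroups must be a single non-negative integer")
    if (length(object@attributes) > 0L &&
        (is.null(names(object@attributes)) || any(names(object@attributes) == "")))
        msgs <- c(msgs, "attributes must be a named list")
    bad <- vapply(object@attributes, function(v)
        !is.character(v) || length(v) != object@numReadGroups, logical(1))
    if (any(bad))
        msgs <- c(msgs, sprintf(
            "attribute '%s' must have exactly %d value(s), one per read group",
            names(object@attributes)[which(bad)[1L]], object@numReadGroups))
    if (length(object@auxNames) != length(object@auxTypes))
        msgs <- c(msgs, "auxNames and auxTypes must have equal length")
    unknown <- setdiff(object@auxTypes, AUX_TYPES)
    if (length(unknown))
        msgs <- c(msgs, paste0("unsupported auxiliary type tag: ",
                               unknown[1L]))
    if (length(msgs)) msgs else TRUE
})

#' One nanopore read: raw signal plus calibration
#'
#' A `Slow5Record` stores one read's identifier, its read-group index, the
#' four ADC calibration constants, the raw 16-bit signal, and any auxiliary
#' values.  `lenRawSignal` is carried as its own slot so that a length that
#' disagrees with the stored signal can be represented and reported by
#' [validateRecord()] instead of being silently repaired.
#'
#' @slot readID non-empty string, unique within a file.
#' @slot readGroup zero-based read-group index.
#' @slot digitisation number of ADC quantisation levels (> 0).
#' @slot offset ADC offset, in ADC units.
#' @slot range full picoampere span of the ADC (> 0).
#' @slot samplingRate samples per second (> 0).
#' @slot lenRawSignal declared number of signal samples.
#' @slot signal integer vector of raw ADC values, each in the signed 16-bit
#'   range.
#' @slot aux named list of auxiliary values; a missing value is `NA`.
#' @export
setClass("Slow5Record",
    representation(readID = "character", readGroup = "integer",
                   digitisation = "numeric", offset = "numeric",
                   range = "numeric", samplingRate = "numeric",
                   lenRawSignal = "numeric", signal = "integer",
                   aux = "list"),
    prototype(readID = "read", readGroup = 0L, digitisation = 1,
              offset = 0, range = 1, samplingRate = 1,
              lenRawSignal = 0, signal = integer(), aux = list()))

setValidity("Slow5Record", function(object) {
    # structural checks only: semantic invariants are reported, not thrown,
    # by validateRecord() so malformed data can be inspected
    msgs <- character()
    for (s in c("readID", "readGroup", "digitisation", "offset", "range",
                "samplingRate", "lenRawSignal"))
        if (length(slot(object, s)) != 1L)
            msgs <- c(msgs, paste0(s, " must have length 1"))
    if (length(msgs)) msgs else TRUE
})

#' Compression configuration for a BLOW5 file
#'
#' Pairs a record-level method (`none`, `zlib` or `zstd`, applied to the
#' whole serialized record) with a signal-level method (`none` or `svb`,
#' applied to the raw signal alone before record compression).  The
#' combination zstd + svb is the `vbz` preset.
#'
#' @slot recordMethod one of `"none"`, `"zlib"`, `"zstd"`.
#' @slot signalMethod one of `"none"`, `"svb"`.
#' @slot zstdLevel integer zstd compression level (default 1, speed-oriented).
#' @export
setClass("CompressionConfig",
    representation(recordMethod = "character", signalMethod = "character",
                   zstdLevel = "integer"),
    prototype(recordMethod = "none", signalMethod = "none", zstdLevel = 1L))

setValidity("CompressionConfig", function(object) {
    msgs <- character()
    if (!object@recordMethod %in% c("none", "zlib", "zstd"))
        msgs <- c(msgs, "recordMethod must be one of none, zlib, zstd")
    if (!object@signalMethod %in% c("none", "svb"))
        msgs <- c(msgs, "signalMethod must be one of none, svb")
    if (length(msgs)) msgs else TRUE
})

#' A header plus an ordered set of records
#'
#' In-memory image of a whole SLOW5/BLOW5 file.
#'
#' @slot header a [Slow5Header-class].
#' @slot records list of [Slow5Record-class] objects in file order.
#' @export
setClass("Slow5Set",
    representation(header = "Slow5Header", records = "list"),
    prototype(records = list()))

setValidity("Slow5Set", function(object) {
    ok <- vapply(object@records, is, logical(1), "Slow5Record")
    if (all(ok)) TRUE else "records must all be Slow5Record objects"
})

#' Loaded random-access index of a SLOW5/BLOW5 file
#'
#' Maps each read identifier to the byte offset and byte length of its
#' record inside the data file, loaded into a hashed environment for O(1)
#' expected lookup.  Also caches the parsed header and compression
#' configuration so [getRead()] can decode frames without re-reading the
#' file header.
#'
#' @slot dataPath path of the indexed data file.
#' @slot format `"slow5"` (ASCII) or `"blow5"` (binary).
#' @slot header the file's [Slow5Header-class].
#' @slot config the file's [CompressionConfig-class] (ASCII files: none/none).
#' @slot entries hashed environment: read_id -> c(offset, length).
#' @slot readIDs read identifiers in file order.
#' @export
setClass("Slow5Index",
    representation(dataPath = "character", format = "character",
                   header = "Slow5Header", config = "CompressionConfig",
                   entries = "environment", readIDs = "character"))

#' Result of a timed random-access benchmark
#'
#' @slot nThreads number of parallel workers used.
#' @slot wallSeconds wall-clock seconds, one value per repetition.
#' @slot cpuSeconds total CPU seconds (user + system, self + children),
#'   one value per repetition.
#' @slot readsAccessed number of records fetched per repetition.
#' @slot readsPerSecond mean access rate over repetitions.
#' @slot cpuUtilisationPct normalized CPU utilization percentage (mean).
#' @slot coreHours worker count times mean wall-clock hours.
#' @slot checksum order-invariant checksum of the retrieved record set.
#' @slot notFound read identifiers that were requested but absent.
#' @slot seed seed used to sample read identifiers (NA if none).
#' @export
setClass("BenchReport",
    representation(nThreads = "integer", wallSeconds = "numeric",
                   cpuSeconds = "numeric", readsAccessed = "integer",
                   readsPerSecond = "numeric", cpuUtilisationPct = "numeric",
                   coreHours = "numeric", checksum = "character",
                   notFound = "character", seed = "numeric"))
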