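# SLOW5 ASCII dialect: tab-separated cells, newline-terminated rows,
# '#'-prefixed structural header rows, '@'-prefixed run attributes, comma
# separated signal samples.  Missing auxiliary values render as ".".

# split that keeps a trailing empty cell (strsplit drops them)
.split_tsv <- function(line) {
    parts <- strsplit(paste0(line, "\x1f"), "\t", fixed = TRUE)[[1L]]
    np <- length(parts)
    parts[np] <- substr(parts[np], 1L, nchar(parts[np]) - 1L)
    parts
}

.parse_num <- function(cell, what) {
    v <- suppressWarnings(as.numeric(cell))
    if (is.na(v))
        s5_stop("slow5_type_error", "non-numeric value '%s' for %s",
                cell, what)
    v
}

.aux_is_array <- function(type) endsWith(type, "*") && type != "char*"
.aux_is_string <- function(type) type %in% c("char*", "string")
.aux_is_integer <- function(type) grepl("^u?int[0-9]+_t", type)

.parse_aux_cell <- function(cell, type) {
    if (cell == ".") return(NA)
    if (.aux_is_string(type)) return(cell)
    if (type == "char") {
        if (nchar(cell) != 1L)
            s5_stop("slow5_type_error", "char cell '%s' is not one character",
                    cell)
        return(cell)
    }
    parts <- if (.aux_is_array(type)) {
        if (cell == "") character() else
            strsplit(cell, ",", fixed = TRUE)[[1L]]
    } else cell
    v <- suppressWarnings(as.numeric(parts))
    if (anyNA(v))
        s5_stop("slow5_type_error", "non-numeric cell '%s' for %s type",
                cell, type)
    if (.aux_is_integer(type)) {
        if (any(v != trunc(v)))
            s5_stop("slow5_type_error", "non-integer cell '%s' for %s type",
                    cell, type)
        if (all(abs(v) <= .Machine$integer.max)) v <- as.integer(v)
    }
    v
}

.write_aux_cell <- function(value, type) {
    if (length(value) == 1L && is.na(value) && !.aux_is_string(type))
        return(".")
    if (length(value) == 0L)
        return(if (.aux_is_array(type)) "" else ".")
    if (is.na(value[1L]) && .aux_is_string(type)) return(".")
    if (.aux_is_string(type) || type == "char") return(as.character(value))
    cells <- if (.aux_is_integer(type)) sprintf("%.0f", as.numeric(value))
             else .fmt_double(as.numeric(value))
    paste(cells, collapse = if (.aux_is_array(type)) "," else "")
}

# ---- header ------------------------------------------------------------------

#' Render / parse the SLOW5 ASCII header
#'
#' `writeSlow5Header` renders a header as the ASCII block: the
#' `#slow5_version` and `#num_read_groups` rows, one `@`-prefixed row per
#' attribute with one tab-separated value per read group, the `#`-prefixed
#' column-type row, and the `#`-prefixed column-name row.
#' `parseSlow5Header` consumes those rows from a character vector of lines
#' and returns the header plus the number of lines consumed.
#'
#' @param header a [Slow5Header-class].
#' @param lines character vector of file lines starting at the file start.
#' @return `writeSlow5Header`: character vector of header lines.
#'   `parseSlow5Header`: list with elements `header` and `consumed`.
#' @export
writeSlow5Header <- function(header) {
    v <- validObject(header, test = TRUE)
    if (!isTRUE(v))
        s5_stop("slow5_schema_error", "invalid header: %s", v[1L])
    attrs <- vapply(names(header@attributes), function(nm)
        paste(c(paste0("@", nm), header@attributes[[nm]]), collapse = "\t"),
        character(1))
    types <- c(PRIMARY_TYPES, header@auxTypes)
    names_ <- c(PRIMARY_COLUMNS, header@auxNames)
    c(paste0("#slow5_version\t", header@slow5Version),
      paste0("#num_read_groups\t", header@numReadGroups),
      unname(attrs),
      paste0("#", paste(types, collapse = "\t")),
      paste0("#", paste(names_, collapse = "\t")))
}

#' @rdname writeSlow5Header
#' @export
parseSlow5Header <- function(lines) {
    i <- 1L
    n <- length(lines)
    version <- NULL; ngroups <- NULL
    attr_names <- character(); attr_vals <- list()
    type_row <- NULL; name_row <- NULL
    while (i <= n) {
        line <- sub("\r$", "", lines[[i]])
        first <- substr(line, 1L, 1L)
        if (first == "@") {
            cells <- .split_tsv(line)
            attr_names <- c(attr_names, substring(cells[1L], 2L))
            attr_vals <- c(attr_vals, list(cells[-1L]))
        } else if (first == "#") {
            cells <- .split_tsv(line)
            key <- cells[1L]
            if (key == "#slow5_version") {
                version <- cells[2L]
            } else if (key == "#num_read_groups") {
                ngroups <- suppressWarnings(as.integer(cells[2L]))
            } else if (is.null(type_row)) {
                type_row <- c(substring(cells[1L], 2L), cells[-1L])
            } else {
                name_row <- c(substring(cells[1L], 2L), cells[-1L])
                i <- i + 1L
                break
            }
        } else {
            break  # first data row (or stray line) ends the header
        }
        i <- i + 1L
    }
    if (is.null(version) || is.null(ngroups) || is.na(ngroups))
        s5_stop("slow5_malformed_header",
                "header is missing a #slow5_version or #num_read_groups row")
    if (is.null(type_row) || is.null(name_row))
        s5_stop("slow5_malformed_header",
                "header is missing the column type/name rows")
    if (length(type_row) != length(name_row))
        s5_stop("slow5_schema_error",
                "column type row has %d cells but name row has %d",
                length(type_row), length(name_row))
    if (length(name_row) < 8L ||
        !identical(name_row[1:8], PRIMARY_COLUMNS) ||
        !identical(type_row[1:8], PRIMARY_TYPES))
        s5_stop("slow5_schema_error",
                "primary columns must be exactly the eight standard columns")
    bad <- which(lengths(attr_vals) != ngroups)
    if (length(bad))
        s5_stop("slow5_group_arity",
                "attribute '%s' has %d value(s) but the file declares %d read group(s)",
                attr_names[bad[1L]], lengths(attr_vals)[bad[1L]], ngroups)
    attributes <- stats::setNames(attr_vals, attr_names)
    header <- Slow5Header(slow5Version = version, numReadGroups = ngroups,
                          attributes = attributes,
                          auxNames = name_row[-(1:8)],
                          auxTypes = type_row[-(1:8)])
    list(header = header, consumed = i - 1L)
}

# ---- records -----------------------------------------------------------------

#' Render / parse one SLOW5 ASCII data row
#'
#' A data row holds the eight primary cells (read_id, read_group,
#' digitisation, offset, range, sampling_rate, len_raw_signal, raw_signal)
#' followed by one cell per auxiliary column.  The signal cell is a
#' comma-separated run of integers; an empty signal is an empty cell.
#' Doubles are written with their shortest exact decimal rendering so a
#' write/parse round trip reproduces the record bit-for-bit.
#'
#' @param record a [Slow5Record-class].
#' @param header the file's [Slow5Header-class].
#' @param line one complete data row, without its trailing newline.
#' @return `writeSlow5Record`: a single string. `parseSlow5Record`: a
#'   [Slow5Record-class].
#' @export
writeSlow5Record <- function(record, header) {
    viol <- validateRecord(record, header)
    if (length(viol))
        s5_stop("slow5_validation_error", "invalid record '%s': %s",
                record@readID, viol[1L])
    aux_cells <- vapply(seq_along(header@auxNames), function(j) {
        nm <- header@auxNames[[j]]
        val <- if (nm %in% names(record@aux)) record@aux[[nm]] else NA
        .write_aux_cell(val, header@auxTypes[[j]])
    }, character(1))
    paste(c(record@readID,
            sprintf("%d", record@readGroup),
            .fmt_double(c(record@digitisation, record@offset, record@range,
                          record@samplingRate)),
            sprintf("%.0f", record@lenRawSignal),
            paste(record@signal, collapse = ","),
            aux_cells),
          collapse = "\t")
}

#' @rdname writeSlow5Record
#' @export
parseSlow5Record <- function(line, header) {
    cells <- .split_tsv(sub("\r$", "", line))
    want <- 8L + length(header@auxNames)
    if (length(cells) != want)
        s5_stop("slow5_column_count",
                "data row has %d cell(s), expected %d", length(cells), want)
    signal <- if (cells[8L] == "") integer() else {
        s <- suppressWarnings(as.integer(strsplit(cells[8L], ",",
                                                  fixed = TRUE)[[1L]]))
        if (anyNA(s))
            s5_stop("slow5_type_error",
                    "raw_signal cell contains a non-integer value")
        s
    }
    len <- .parse_num(cells[7L], "len_raw_signal")
    if (len != length(signal))
        s5_stop("slow5_length_error",
                "len_raw_signal is %s but the signal cell has %d value(s)",
                cells[7L], length(signal))
    rg <- .parse_num(cells[2L], "read_group")
    aux <- list()
    if (length(header@auxNames)) {
        aux <- lapply(seq_along(header@auxNames), function(j)
            .parse_aux_cell(cells[8L + j], header@auxTypes[[j]]))
        names(aux) <- header@auxNames
    }
    rec <- Slow5Record(readID = cells[1L], readGroup = rg,
                       digitisation = .parse_num(cells[3L], "digitisation"),
                       offset = .parse_num(cells[4L], "offset"),
                       range = .parse_num(cells[5L], "range"),
                       samplingRate = .parse_num(cells[6L], "sampling_rate"),
                       signal = signal, lenRawSignal = len, aux = aux)
    viol <- validateRecord(rec, header)
    if (length(viol))
        s5_stop("slow5_validation_error", "record '%s' is invalid: %s",
                rec@readID, viol[1L])
    rec
}
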