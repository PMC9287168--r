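# File-level tooling: merge, split, stats, and FAST5 conversion through an
# HDF5 bridge script run by the system python (h5py).

.as_set <- function(x) {
    if (is(x, "Slow5Set")) x
    else if (is.character(x) && length(x) == 1L) readSlow5(x)
    else s5_stop("slow5_usage_error",
                 "expected a Slow5Set or a single file path")
}

.group_attr_map <- function(header, g) {
    vals <- vapply(header@attributes, function(v) v[[g + 1L]], character(1))
    vals[order(names(vals))]
}

.group_key <- function(map) {
    paste(names(map), map, sep = "=", collapse = "\x1f")
}

#' Merge SLOW5/BLOW5 files
#'
#' Combines several files (or in-memory sets) into one.  Read groups with
#' identical attribute maps are collapsed into a single group; distinct
#' groups are numbered by first occurrence in input order, and every
#' record's `read_group` is remapped accordingly.  Record content is
#' otherwise untouched.  A read identifier occurring in more than one
#' input is an error, as is mixing inputs whose format major versions
#' differ.
#'
#' @param inputs character vector of paths, or list of
#'   [Slow5Set-class] objects.
#' @param output optional path; when given, the merged set is written there.
#' @param format,config output encoding, as in [writeSlow5()].
#' @return the merged [Slow5Set-class] (invisibly when `output` is given).
#' @export
mergeSlow5 <- function(inputs, output = NULL, format = c("slow5", "blow5"),
                       config = CompressionConfig()) {
    format <- match.arg(format)
    if (is.character(inputs)) inputs <- as.list(inputs)
    if (!length(inputs))
        s5_stop("slow5_usage_error", "merge needs at least one input")
    sets <- lapply(inputs, .as_set)

    majors <- vapply(sets, function(s)
        .version_triple(s@header@slow5Version)[1L], integer(1))
    if (length(unique(majors)) > 1L)
        s5_stop("slow5_version_error",
                "inputs mix format major versions: %s",
                paste(unique(majors), collapse = ", "))

    # unify auxiliary schemas (same name must mean same type)
    aux_names <- character(); aux_types <- character()
    for (s in sets) {
        h <- s@header
        for (j in seq_along(h@auxNames)) {
            k <- match(h@auxNames[[j]], aux_names)
            if (is.na(k)) {
                aux_names <- c(aux_names, h@auxNames[[j]])
                aux_types <- c(aux_types, h@auxTypes[[j]])
            } else if (aux_types[[k]] != h@auxTypes[[j]]) {
                s5_stop("slow5_schema_error",
                        "auxiliary column '%s' has conflicting types (%s vs %s)",
                        h@auxNames[[j]], aux_types[[k]], h@auxTypes[[j]])
            }
        }
    }

    # collapse identical group attribute maps, first occurrence wins
    keys <- character(); maps <- list()
    remap <- vector("list", length(sets))
    for (i in seq_along(sets)) {
        h <- sets[[i]]@header
        remap[[i]] <- integer(max(h@numReadGroups, 1L))
        for (g in seq_len(h@numReadGroups) - 1L) {
            map <- .group_attr_map(h, g)
            key <- .group_key(map)
            k <- match(key, keys)
            if (is.na(k)) {
                keys <- c(keys, key)
                maps <- c(maps, list(map))
                k <- length(keys)
            }
            remap[[i]][[g + 1L]] <- k - 1L
        }
    }
    ngroups <- max(length(keys), 1L)
    all_attr_names <- unique(unlist(lapply(maps, names)))
    attributes <- stats::setNames(lapply(all_attr_names, function(nm)
        vapply(maps, function(m)
            if (nm %in% names(m)) m[[nm]] else "", character(1))),
        all_attr_names)

    header <- Slow5Header(slow5Version = sets[[1L]]@header@slow5Version,
                          numReadGroups = ngroups,
                          attributes = attributes,
                          auxNames = aux_names, auxTypes = aux_types)
    records <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
    for (i in seq_along(sets)) {
        for (rec in sets[[i]]@records) {
            if (!is.null(get0(rec@readID, envir = seen)))
                s5_stop("slow5_duplicate_id",
                        "read id '%s' occurs in more than one input",
                        rec@readID)
            assign(rec@readID, TRUE, envir = seen)
            rec@readGroup <- remap[[i]][[rec@readGroup + 1L]]
            records[[length(records) + 1L]] <- rec
        }
    }
    merged <- Slow5Set(header, records)
    if (!is.null(output)) {
        writeSlow5(merged, output, format = format, config = config)
        return(invisible(merged))
    }
    merged
}

#' Split a SLOW5/BLOW5 file
#'
#' `mode = "group"` writes one single-group file per read group (records'
#' `read_group` reset to 0; groups without records still yield a
#' header-only file).  `mode = "reads"` writes files of `n` records each in
#' file order (the last may be smaller), copying the header.  Splitting
#' then merging reproduces the original content (identical groups collapse
#' back).
#'
#' @param input path or [Slow5Set-class].
#' @param outDir output directory (created if needed).
#' @param mode `"group"` or `"reads"`.
#' @param n records per file for `mode = "reads"`.
#' @param format,config output encoding, as in [writeSlow5()].
#' @param prefix output file name prefix.
#' @return character vector of files written.
#' @export
splitSlow5 <- function(input, outDir, mode = c("group", "reads"), n = NULL,
                       format = c("slow5", "blow5"),
                       config = CompressionConfig(), prefix = "split") {
    mode <- match.arg(mode)
    format <- match.arg(format)
    set <- .as_set(input)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "blow5") ".blow5" else ".slow5"
    h <- set@header
    paths <- character()
    if (mode == "group") {
        groups <- vapply(set@records, readGroup, integer(1))
        for (g in seq_len(max(h@numReadGroups, 1L)) - 1L) {
            sub_header <- Slow5Header(
                slow5Version = h@slow5Version, numReadGroups = 1L,
                attributes = lapply(h@attributes, function(v) v[[g + 1L]]),
                auxNames = h@auxNames, auxTypes = h@auxTypes)
            recs <- lapply(set@records[which(groups == g)], function(r) {
                r@readGroup <- 0L
                r
            })
            p <- file.path(outDir, sprintf("%s_group%d%s", prefix, g, ext))
            writeSlow5(Slow5Set(sub_header, recs), p, format, config)
            paths <- c(paths, p)
        }
    } else {
        if (is.null(n) || n < 1L)
            s5_stop("slow5_usage_error",
                    "mode = \"reads\" needs n >= 1 records per file")
        nrec <- length(set@records)
        starts <- seq(1L, max(nrec, 1L), by = n)
        if (nrec == 0L) starts <- 1L
        for (k in seq_along(starts)) {
            idx <- seq(starts[[k]], min(starts[[k]] + n - 1L, nrec))
            if (nrec == 0L) idx <- integer()
            p <- file.path(outDir, sprintf("%s_part%d%s", prefix, k, ext))
            writeSlow5(Slow5Set(h, set@records[idx]), p, format, config)
            paths <- c(paths, p)
        }
    }
    paths
}

#' Summary statistics of a SLOW5/BLOW5 file
#'
#' Streams the file once and reports exact counts plus a bytes-per-sample
#' compression proxy.
#'
#' @param path file path.
#' @return list with `format`, `compression`, `records`, `readGroups`,
#'   `totalSamples`, `bytes`, `bytesPerSample`.
#' @export
slow5Stats <- function(path) {
    reader <- slow5Open(path)
    on.exit(slow5Close(reader), add = TRUE)
    nrec <- 0L; nsamp <- 0
    repeat {
        rec <- slow5ReadNext(reader)
        if (is.null(rec)) break
        nrec <- nrec + 1L
        nsamp <- nsamp + length(rec@signal)
    }
    bytes <- file.size(path)
    list(format = reader$format,
         compression = paste0(reader$config@recordMethod, "/",
                              reader$config@signalMethod),
         records = nrec,
         readGroups = reader$header@numReadGroups,
         totalSamples = nsamp,
         bytes = bytes,
         bytesPerSample = if (nsamp > 0) bytes / nsamp else NA_real_)
}

# ---- FAST5 conversion --------------------------------------------------------

.bridge_state <- new.env(parent = emptyenv())

.python_bin <- function() Sys.getenv("SLOWFIVE_PYTHON", Sys.which("python"))

#' Is the HDF5 bridge usable?
#'
#' FAST5 files are HDF5 containers; this package reads and writes them
#' through a small bridge script executed by the system `python` with
#' `h5py`.  Returns `TRUE` when such an interpreter is available.  Set the
#' `SLOWFIVE_PYTHON` environment variable to point at a specific
#' interpreter.
#'
#' @return logical.
#' @export
hdf5BridgeAvailable <- function() {
    if (!is.null(.bridge_state$available))
        return(.bridge_state$available)
    py <- .python_bin()
    ok <- nzchar(py) &&
        suppressWarnings(system2(py, c("-c", shQuote("import h5py")),
                                 stdout = FALSE, stderr = FALSE)) == 0L
    .bridge_state$available <- isTRUE(ok)
    .bridge_state$available
}

.run_bridge <- function(args) {
    if (!hdf5BridgeAvailable())
        s5_stop("slow5_env_error",
                "FAST5 conversion needs a python interpreter with h5py (set SLOWFIVE_PYTHON)")
    script <- system.file("python", "fast5_bridge.py", package = "slowfive")
    err <- tempfile("bridge_err_")
    status <- suppressWarnings(
        system2(.python_bin(), c(shQuote(script), args),
                stdout = FALSE, stderr = err))
    if (status != 0L) {
        msg <- paste(readLines(err, warn = FALSE), collapse = "; ")
        if (status == 4L)
            s5_stop("slow5_unsupported_format", "%s", msg)
        s5_stop("slow5_io_error", "HDF5 bridge failed (status %d): %s",
                status, msg)
    }
    invisible(TRUE)
}

#' Convert multi-read FAST5 files to SLOW5/BLOW5 (f2s) and back (s2f)
#'
#' `fast5ToSlow5` converts one or more multi-read FAST5 files into a single
#' output file, preserving every read's raw signal, the four calibration
#' attributes and the run metadata; run metadata becomes the read-group
#' attribute map, and identical maps collapse into one group.  Work is
#' partitioned at file granularity across `nWorkers` independent processes
#' and the result is independent of the worker count.  `slow5ToFast5`
#' writes the records back into a multi-read FAST5 container.
#' Single-read FAST5 files are rejected with an unsupported-format error.
#'
#' @param fast5 character vector of multi-read FAST5 paths.
#' @param output output file path.
#' @param format,config output encoding, as in [writeSlow5()].
#' @param nWorkers parallel conversion processes.
#' @param input a SLOW5/BLOW5 path for `slow5ToFast5`.
#' @return invisibly, the output path.
#' @export
fast5ToSlow5 <- function(fast5, output, format = c("blow5", "slow5"),
                         config = vbzConfig(), nWorkers = 1L) {
    format <- match.arg(format)
    if (!length(fast5))
        s5_stop("slow5_usage_error", "f2s needs at least one input")
    convert_one <- function(path) {
        tmp <- tempfile(fileext = ".slow5")
        on.exit(unlink(tmp), add = TRUE)
        .run_bridge(c("dump", shQuote(path), shQuote(tmp)))
        readSlow5(tmp)
    }
    sets <- if (nWorkers > 1L && .Platform$OS.type == "unix") {
        out <- parallel::mclapply(fast5, convert_one, mc.cores = nWorkers)
        bad <- vapply(out, inherits, logical(1), "try-error")
        if (any(bad)) stop(attr(out[[which(bad)[1L]]], "condition"))
        out
    } else {
        lapply(fast5, convert_one)
    }
    merged <- mergeSlow5(sets)
    writeSlow5(merged, output, format = format, config = config)
    invisible(output)
}

#' @rdname fast5ToSlow5
#' @export
slow5ToFast5 <- function(input, output) {
    set <- .as_set(input)
    tmp <- tempfile(fileext = ".slow5")
    on.exit(unlink(tmp), add = TRUE)
    writeSlow5(set, tmp, format = "slow5")
    .run_bridge(c("build", shQuote(tmp), shQuote(output)))
    invisible(output)
}
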