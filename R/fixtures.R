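# Deterministic synthetic data: random-walk reads that mimic the local
# smoothness of nanopore current (so the signal codec is exercised
# realistically), and the worked single-read-group example file.

#' Generate synthetic nanopore reads
#'
#' Signals are integer random walks `s[i] = s[i-1] + round(N(0, sigmaStep))`
#' clipped to the signed 16-bit range, started near `N(startMean,
#' startSD)`.  Random-walk signals are locally smooth like real nanopore
#' current, which is what makes delta-based signal compression effective;
#' they carry none of the pore chemistry (no event structure, no adapter
#' or polyA segments).  Read lengths are drawn from `N(meanLength,
#' sdLength)` truncated at 1.  Calibration constants are drawn once per
#' read group.  Everything is a pure function of `seed`.
#'
#' @param n number of reads.
#' @param nReadGroups number of read groups to spread reads across.
#' @param meanLength,sdLength read length distribution (samples).
#' @param sigmaStep standard deviation of the random-walk step (ADC units).
#' @param startMean,startSD distribution of the walk's starting level.
#' @param seed RNG seed; equal seeds give identical output.
#' @param idPrefix read identifier prefix (ids are `<prefix><number>`).
#' @param withAux when `TRUE` the header carries a small auxiliary schema
#'   (channel_number, median_before, start_time) and each record carries
#'   values; `median_before` is occasionally missing to exercise the
#'   missing-value sentinel.
#' @return a [Slow5Set-class].
#' @examples
#' s <- generateRecords(3, seed = 7)
#' length(s)
#' @export
generateRecords <- function(n, nReadGroups = 1L, meanLength = 2000,
                            sdLength = 200, sigmaStep = 5, startMean = 500,
                            startSD = 30, seed = NULL, idPrefix = "r",
                            withAux = TRUE) {
    if (n < 0 || nReadGroups < 1)
        s5_stop("slow5_domain_error",
                "n must be >= 0 and nReadGroups >= 1")
    if (sigmaStep < 0 || sdLength < 0 || meanLength < 1)
        s5_stop("slow5_domain_error", "invalid distribution parameters")
    if (!is.null(seed)) set.seed(seed)
    ng <- as.integer(nReadGroups)

    hex <- function(k) paste(sample(c(0:9, letters[1:6]), k, replace = TRUE),
                             collapse = "")
    attributes <- list(
        asic_id = vapply(seq_len(ng), function(g) hex(16L), character(1)),
        exp_start_time = rep("2020-01-01T00:00:00Z", ng),
        flow_cell_id = vapply(seq_len(ng), function(g)
            paste0("FC", hex(6L)), character(1)),
        run_id = vapply(seq_len(ng), function(g) hex(12L), character(1)))
    aux_names <- character(); aux_types <- character()
    if (withAux) {
        aux_names <- c("channel_number", "median_before", "start_time")
        aux_types <- c("int32_t", "double", "uint64_t")
    }
    header <- Slow5Header(numReadGroups = ng, attributes = attributes,
                          auxNames = aux_names, auxTypes = aux_types)

    digitisation <- rep(8192, ng)
    range <- round(runif(ng, 1300, 1600), 1)
    offset <- sample(-10:10, ng, replace = TRUE)
    rate <- rep(4000, ng)

    records <- vector("list", n)
    groups <- if (n > 0) sort(rep_len(seq_len(ng) - 1L, n)) else integer()
    lens <- pmax(1, round(rnorm(n, meanLength, sdLength)))
    for (i in seq_len(n)) {
        g <- groups[[i]]
        len <- lens[[i]]
        steps <- c(round(rnorm(1, startMean, startSD)),
                   round(rnorm(len - 1, 0, sigmaStep)))
        signal <- as.integer(pmin(pmax(cumsum(steps), INT16_MIN), INT16_MAX))
        aux <- list()
        if (withAux) {
            aux <- list(
                channel_number = sample.int(512L, 1L),
                median_before = if (runif(1) < 0.02) NA else
                    round(runif(1, 150, 250), 3),
                start_time = as.integer(floor(runif(1, 0, 1e8))))
        }
        records[[i]] <- Slow5Record(
            readID = sprintf("%s%06d", idPrefix, i), readGroup = g,
            digitisation = digitisation[[g + 1L]],
            offset = offset[[g + 1L]], range = range[[g + 1L]],
            samplingRate = rate[[g + 1L]], signal = signal, aux = aux)
    }
    Slow5Set(header, records)
}

#' The worked single-read-group example file
#'
#' Returns the canonical small example: a header with one read group
#' (attributes asic_id, exp_start_time, flow_cell_id, run_id) and three
#' reads — read0 (offset 6, 123456 samples), read1 (offset 5, 2000
#' samples) and readN (offset 3, 3000 samples), all with digitisation
#' 8192, range 1467.6 and sampling rate 4000.  The printed form of this
#' example truncates each signal after its first values; here each signal
#' is padded with its last printed value out to the declared length, and
#' [table1SignalPrefixes()] exposes the exact printed prefixes for tests
#' that compare values.
#'
#' @return a [Slow5Set-class] with three records.
#' @export
table1Example <- function() {
    header <- Slow5Header(
        slow5Version = "1.0.0", numReadGroups = 1L,
        attributes = list(asic_id = "0004A30B00232BEC",
                          exp_start_time = "2020-01-01T00:00:00Z",
                          flow_cell_id = "FAH00000",
                          run_id = "855cdb"))
    pad <- function(prefix, len) {
        as.integer(c(prefix, rep(prefix[length(prefix)],
                                 len - length(prefix))))
    }
    pre <- table1SignalPrefixes()
    records <- list(
        Slow5Record("read0", 0L, digitisation = 8192, offset = 6,
                    range = 1467.6, samplingRate = 4000,
                    signal = pad(pre$read0, 123456)),
        Slow5Record("read1", 0L, digitisation = 8192, offset = 5,
                    range = 1467.6, samplingRate = 4000,
                    signal = pad(pre$read1, 2000)),
        Slow5Record("readN", 0L, digitisation = 8192, offset = 3,
                    range = 1467.6, samplingRate = 4000,
                    signal = pad(pre$readN, 3000)))
    Slow5Set(header, records)
}

#' @rdname table1Example
#' @export
table1SignalPrefixes <- function() {
    list(read0 = c(498L, 492L), read1 = c(491L, 491L),
         readN = c(400L, 400L))
}

#' Build a synthetic multi-read FAST5 container
#'
#' Writes the given records into an HDF5 file laid out like a multi-read
#' FAST5: one `read_<id>` group per read carrying the run metadata as
#' group attributes, a `channel_id` subgroup with the four calibration
#' attributes, and a `Raw` subgroup holding the int16 `Signal` dataset.
#' Requires the HDF5 bridge (see [hdf5BridgeAvailable()]).
#'
#' @param set a [Slow5Set-class] (e.g. from [generateRecords()]).
#' @param path output `.fast5` path.
#' @return invisibly, the output path.
#' @export
generateFast5Fixture <- function(set, path) {
    tmp <- tempfile(fileext = ".slow5")
    on.exit(unlink(tmp), add = TRUE)
    writeSlow5(set, tmp, format = "slow5")
    .run_bridge(c("build", shQuote(tmp), shQuote(path)))
    invisible(path)
}
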