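# Measurement formulas and the parallel random-access throughput harness.

#' Normalized CPU utilization percentage
#'
#' `cpu_seconds / (wall_seconds * n_threads) * 100`: the fraction of the
#' available CPU capacity the job actually used, normalized by the number
#' of threads it was given, as a percentage.
#'
#' @param cpuSeconds CPU time (user + system), seconds.
#' @param wallSeconds wall-clock time, seconds (> 0).
#' @param nThreads number of CPU threads employed (>= 1).
#' @return percentage in `[0, 100]` up to timer jitter.
#' @examples
#' cpuUtilisation(20, 10, 4)   # 50
#' @export
cpuUtilisation <- function(cpuSeconds, wallSeconds, nThreads = 1L) {
    if (any(wallSeconds <= 0))
        s5_stop("slow5_domain_error", "wall time must be positive")
    if (any(nThreads < 1))
        s5_stop("slow5_domain_error", "thread count must be at least 1")
    cpuSeconds / (wallSeconds * nThreads) * 100
}

#' Core-hours of a job
#'
#' The product of the number of processing threads and the wall-clock
#' hours spent — the cloud-accounting analogue of man-hours.  For an
#' ideally parallel program it is constant in the thread count.
#'
#' @param nThreads number of processing threads (>= 0).
#' @param wallHours wall-clock duration in hours (>= 0).
#' @return core-hours.
#' @examples
#' coreHours(48, 10.5)   # 504
#' @export
coreHours <- function(nThreads, wallHours) {
    if (any(nThreads < 0) || any(wallHours < 0))
        s5_stop("slow5_domain_error",
                "thread count and wall hours must be non-negative")
    nThreads * wallHours
}

.proc_cpu_seconds <- function() {
    pt <- proc.time()
    sum(pt[c("user.self", "sys.self", "user.child", "sys.child")],
        na.rm = TRUE)
}

#' Timed parallel random-access benchmark
#'
#' Partitions a sample of read identifiers across `nWorkers` independent
#' worker processes, each holding its own connection to the shared data
#' file, and times the retrieval of every record through the index.
#' Content correctness is captured by an order-invariant checksum of the
#' retrieved record set, which by construction cannot depend on the worker
#' count or scheduling; the timing figures are reported but are
#' hardware-dependent.  Note the operating system page cache is warm in
#' repeated runs — supply `preRunHook` (e.g. a cache-dropping command) if
#' cold-cache numbers are wanted.
#'
#' @param index a [Slow5Index-class].
#' @param readIDs identifiers to fetch; defaults to all indexed reads.
#' @param nWorkers number of parallel workers.
#' @param sampleSize when given, a random sample of this many ids is drawn
#'   from `readIDs` using `seed`.
#' @param repetitions number of timed repetitions.
#' @param seed RNG seed used for sampling (recorded in the report).
#' @param preRunHook optional function called before each repetition.
#' @return a [BenchReport-class].
#' @export
accessBenchmark <- function(index, readIDs = NULL, nWorkers = 1L,
                            sampleSize = NULL, repetitions = 1L,
                            seed = NULL, preRunHook = NULL) {
    nWorkers <- as.integer(nWorkers)
    if (nWorkers < 1L)
        s5_stop("slow5_domain_error", "nWorkers must be at least 1")
    if (is.null(readIDs)) readIDs <- index@readIDs
    if (!length(readIDs))
        s5_stop("slow5_usage_error", "no read ids to fetch")
    if (!is.null(sampleSize)) {
        if (!is.null(seed)) set.seed(seed)
        readIDs <- sample(readIDs, min(sampleSize, length(readIDs)))
    }
    present <- vapply(readIDs, function(id)
        !is.null(get0(id, envir = index@entries)), logical(1))
    notFound <- readIDs[!present]
    readIDs <- readIDs[present]

    chunks <- split(readIDs, ceiling(seq_along(readIDs) /
                                     max(1, ceiling(length(readIDs) /
                                                    nWorkers))))
    fetch_all <- function() {
        res <- if (nWorkers > 1L && .Platform$OS.type == "unix")
            parallel::mclapply(chunks, function(ch) getReads(index, ch),
                               mc.cores = nWorkers)
        else lapply(chunks, function(ch) getReads(index, ch))
        unlist(res, recursive = FALSE, use.names = FALSE)
    }

    walls <- numeric(repetitions); cpus <- numeric(repetitions)
    records <- list()
    for (rep in seq_len(repetitions)) {
        if (is.function(preRunHook)) preRunHook()
        c0 <- .proc_cpu_seconds()
        t0 <- Sys.time()
        records <- fetch_all()
        walls[[rep]] <- max(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 1e-9)
        cpus[[rep]] <- .proc_cpu_seconds() - c0
    }
    mw <- mean(walls)
    new("BenchReport", nThreads = nWorkers, wallSeconds = walls,
        cpuSeconds = cpus, readsAccessed = length(readIDs),
        readsPerSecond = length(readIDs) / mw,
        cpuUtilisationPct = cpuUtilisation(mean(cpus), mw, nWorkers),
        coreHours = coreHours(nWorkers, mw / 3600),
        checksum = recordSetChecksum(records),
        notFound = notFound,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

setMethod("show", "BenchReport", function(object) {
    cat("BenchReport: ", object@readsAccessed, " reads, ",
        object@nThreads, " worker(s)\n",
        "  wall s     : ", paste(signif(object@wallSeconds, 4),
                                 collapse = ", "), "\n",
        "  reads/s    : ", signif(object@readsPerSecond, 4), "\n",
        "  cpu util % : ", signif(object@cpuUtilisationPct, 4), "\n",
        "  core-hours : ", signif(object@coreHours, 4), "\n",
        "  checksum   : ", object@checksum, "\n", sep = "")
    if (length(object@notFound))
        cat("  not found  :", length(object@notFound), "id(s)\n")
})
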