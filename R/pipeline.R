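stageFail <- function(stage, e) {
  stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
}

runMapper <- function(adapter, readsPath, referencePath, scratch) {
  out <- file.path(scratch, "mapping.out")
  cmd <- adapter@command
  cmd <- gsub("{reads}", readsPath, cmd, fixed = TRUE)
  cmd <- gsub("{reference}", referencePath, cmd, fixed = TRUE)
  cmd <- gsub("{output}", out, cmd, fixed = TRUE)
  logEvent("info", "mapping", paste("invoking mapper:", cmd))
  status <- system(cmd)
  if (status != 0L)
    stop("mapper '", adapter@name, "' exited with status ", status)
  out
}

#' Run one quantification job
#'
#' Executes the per-worker workflow on a single sample: stream and
#' decompress the reads, optionally quality-filter and convert them,
#' map them with the configured adapter (or take a precomputed mapping
#' file), filter the hits, accumulate coverage and/or counts per the
#' toggles, compute per-region statistics, and write the results table to
#' the job's output path. A per-job processing log is written next to the
#' output (\code{<output>.log}). Results are written atomically (a failed
#' job leaves no results file). Intermediate mapper output lives in a
#' scratch directory and is deleted unless \code{keepMapping}, in which
#' case it is retained at \code{<output>.mapping}; a precomputed mapping
#' file is never deleted. With both counts and coverage disabled the
#' quantification stage is skipped entirely (zero array writes) and only
#' the mapping output is kept - a pure parallel-mapping run.
#'
#' @param job a \code{\link{Job-class}}.
#' @param options a \code{\link{pipelineOptions}} object.
#' @return invisibly, a list with \code{output} (results path or NA),
#'   \code{log} (log path), \code{quantWrites} (instrumented array writes
#'   of the quantification stage), and \code{hits} (retained hit count).
#' @export
runJob <- function(job, options = pipelineOptions()) {
  stopifnot(is(job, "Job"), is(options, "PipelineOptions"))
  logPath <- paste0(job@outputPath, ".log")
  oldLog <- configureLogging(if (options@verbose) "verbose" else "info",
                             file = logPath)
  on.exit(do.call(configureLogging, oldLog), add = TRUE)
  logEvent("info", "job", paste("start job", job@jobId))

  scratch <- if (nzchar(options@scratchDir)) options@scratchDir
             else file.path(tempdir(), paste0("mq-", job@jobId, "-",
                                              Sys.getpid()))
  dir.create(scratch, showWarnings = FALSE, recursive = TRUE)
  cleanupScratch <- !nzchar(options@scratchDir)
  on.exit({
    if (cleanupScratch) unlink(scratch, recursive = TRUE)
  }, add = TRUE)

  for (p in c(job@readsPath, job@referencePath, job@annotationsPath))
    if (!file.exists(p))
      stop("stage inputs: missing input file '", p, "'", call. = FALSE)

  precomputed <- options@adapter@name == "precomputed"
  needReads <- options@qualityFilter || !precomputed
  mapInput <- job@readsPath

  if (needReads) {
    logEvent("info", "preprocess", "streaming reads")
    tryCatch({
      stream <- streamReads(job@readsPath)
      outFa <- file.path(scratch, "reads.fasta")
      con <- file(outFa, "wt")
      nIn <- nKept <- 0L
      repeat {
        ch <- stream$nextChunk()
        if (is.null(ch)) break
        nIn <- nIn + nrow(ch)
        if (options@qualityFilter) ch <- qualityFilter(ch, options@qfParams)
        nKept <- nKept + nrow(ch)
        if (nrow(ch))
          writeLines(paste0(">", ch$id, "\n", ch$sequence), con)
      }
      close(con)
      logEvent("verbose", "preprocess", "read pre-processing",
               stats = list(reads_in = nIn, reads_kept = nKept))
      mapInput <- outFa
    }, error = function(e) stageFail("preprocess", e))
    logEvent("info", "preprocess", "finished pre-processing")
  } else {
    logEvent("info", "preprocess",
             "skipped (precomputed mapping, no filtering)")
  }

  mappingFile <- tryCatch({
    if (precomputed) {
      if (!nzchar(job@mappingPath))
        stop("precomputed adapter but job has no mapping path")
      if (!file.exists(job@mappingPath))
        stop("missing mapping file '", job@mappingPath, "'")
      logEvent("info", "mapping", paste("using precomputed mapping",
                                        job@mappingPath))
      job@mappingPath
    } else {
      runMapper(options@adapter, mapInput, job@referencePath, scratch)
    }
  }, error = function(e) stageFail("mapping", e))

  if (options@keepMapping && !precomputed) {
    keep <- paste0(job@outputPath, ".mapping")
    file.copy(mappingFile, keep, overwrite = TRUE)
    logEvent("info", "mapping", paste("mapping output retained at", keep))
  }

  quantWrites <- 0
  nHits <- NA_integer_
  if (options@counts || options@coverage) {
    tryCatch({
      logEvent("info", "quantify", "start quantification")
      refLens <- referenceLengths(job@referencePath)
      anns <- readAnnotations(job@annotationsPath)
      hits <- if (options@adapter@parser == "sam")
        parseSam(mappingFile) else parseBlast8(mappingFile)
      hits <- filterHits(hits, options@hitCriteria)
      nHits <- nrow(hits)
      counts <- if (options@counts)
        countReads(hits, anns, options@overlapRule) else NULL
      cov <- if (options@coverage) {
        cm <- buildCoverage(hits, refLens)
        quantWrites <- coverageWrites(cm)
        cm
      } else NULL
      results <- regionStatistics(cov, anns, counts)
      tmp <- paste0(job@outputPath, ".tmp")
      writeResults(results, tmp)
      file.rename(tmp, job@outputPath)
      logEvent("info", "quantify", "results written",
               stats = list(regions = nrow(results), hits = nHits))
    }, error = function(e) {
      unlink(paste0(job@outputPath, ".tmp"))
      unlink(job@outputPath)
      stageFail("quantify", e)
    })
  } else {
    logEvent("info", "quantify",
             "skipped (counts and coverage disabled); mapping-only run")
  }

  logEvent("info", "job", paste("finished job", job@jobId))
  invisible(list(output = if (options@counts || options@coverage)
                   job@outputPath else NA_character_,
                 log = logPath, quantWrites = quantWrites, hits = nHits))
}

#' Run a set of jobs locally with forked workers
#'
#' Desk-scale front end to the master-worker scheme: forks
#' \code{workers} local worker processes whose executor is
#' \code{\link{runJob}} with the given options, serves the job queue to
#' them over a loopback TCP endpoint, and returns the master's run
#' summary. Results are identical to running every job serially because
#' jobs are independent and \code{runJob} is deterministic for a fixed
#' input and option set.
#'
#' @param jobs list of \code{\link{Job-class}} objects, or the path of a
#'   jobs table for \code{\link{readJobsFile}}.
#' @param workers number of forked local workers (>= 1).
#' @param options a \code{\link{pipelineOptions}} object.
#' @param retryLimit maximum re-dispatches per failing job.
#' @param endpoint optional \code{tcp://host:port}; default picks a free
#'   loopback port.
#' @param masterLog optional master log file.
#' @return the \code{\link{masterServe}} run summary.
#' @export
runLocal <- function(jobs, workers = 1L, options = pipelineOptions(),
                     retryLimit = 3L, endpoint = NULL, masterLog = NULL) {
  if (is.character(jobs)) jobs <- readJobsFile(jobs)
  stopifnot(workers >= 1L)
  if (is.null(endpoint))
    endpoint <- sprintf("tcp://127.0.0.1:%d", freePort())
  pids <- lapply(seq_len(workers), function(i)
    parallel::mcparallel(workerLoop(endpoint,
                                    executor = function(j)
                                      runJob(j, options),
                                    workerId = sprintf("local-%d", i)),
                         silent = TRUE))
  summary <- tryCatch(
    masterServe(jobs, endpoint, retryLimit = retryLimit,
                logFile = masterLog, expectedWorkers = workers),
    finally = suppressWarnings(parallel::mccollect(pids, wait = TRUE)))
  summary
}
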