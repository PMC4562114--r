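#' @importFrom stats setNames
NULL

## Dynamic master-worker distribution over TCP.
##
## Protocol: one request/reply per TCP connection, each a single
## line-delimited JSON object. Requests: register / poll / done / failed /
## status. Replies: job / wait / shutdown / status / error. Payloads are
## small control messages only; job data files are never transmitted -
## workers fetch inputs and write outputs themselves.

parseEndpoint <- function(endpoint) {
  m <- regmatches(endpoint,
                  regexec("^tcp://([^:]+):([0-9]+)$", endpoint))[[1]]
  if (length(m) != 3L)
    stop("endpoint must look like tcp://host:port, got '", endpoint, "'")
  list(host = m[2], port = as.integer(m[3]))
}

#' Find a free local TCP port
#'
#' Binds and releases candidate ports at random until one succeeds.
#'
#' @param tries attempts before giving up.
#' @return a port number.
#' @export
freePort <- function(tries = 50L) {
  for (i in seq_len(tries)) {
    p <- sample(20000:60000, 1L)
    s <- tryCatch(serverSocket(p), error = function(e) NULL)
    if (!is.null(s)) {
      close(s)
      return(p)
    }
  }
  stop("no free TCP port found after ", tries, " tries")
}

jobToList <- function(j) {
  list(job_id = j@jobId, reads = j@readsPath, reference = j@referencePath,
       annotations = j@annotationsPath, output = j@outputPath,
       mapping = j@mappingPath)
}

jobFromList <- function(l) {
  job(jobId = l$job_id, readsPath = l$reads, referencePath = l$reference,
      annotationsPath = l$annotations, outputPath = l$output,
      mappingPath = if (is.null(l$mapping)) "" else l$mapping)
}

writeMsg <- function(con, msg) {
  writeLines(jsonlite::toJSON(msg, auto_unbox = TRUE, null = "null"), con)
  flush(con)
}

readMsg <- function(con) {
  line <- readLines(con, n = 1L, warn = FALSE)
  if (!length(line) || !nzchar(line)) return(NULL)
  tryCatch(jsonlite::fromJSON(line, simplifyVector = FALSE),
           error = function(e) NULL)
}

## one request-reply round trip on a fresh connection
dmwRequest <- function(host, port, msg, timeout = 10) {
  ## a refused connection raises both a warning and an error; the error
  ## carries the information, so silence the duplicate warning
  con <- suppressWarnings(
    socketConnection(host = host, port = port, blocking = TRUE,
                     open = "r+", timeout = timeout))
  on.exit(close(con))
  writeMsg(con, msg)
  reply <- readMsg(con)
  if (is.null(reply)) stop("empty or unparsable reply from master")
  reply
}

statusFrame <- function(st) {
  if (!length(st$state))
    return(data.frame(job_id = character(0), state = character(0),
                      attempts = integer(0), worker_id = character(0),
                      error = character(0), stringsAsFactors = FALSE))
  data.frame(job_id = names(st$state), state = unname(st$state),
             attempts = unname(st$attempts[names(st$state)]),
             worker_id = unname(st$worker[names(st$state)]),
             error = unname(st$error[names(st$state)]),
             stringsAsFactors = FALSE)
}

#' Serve a job queue to dynamically registering workers
#'
#' The master holds a FIFO queue of jobs and a table of their statuses.
#' Workers register at any time over TCP, receive one job per request,
#' and report done or failed; a failure requeues the job until it has
#' been dispatched \code{retryLimit + 1} times, after which it is
#' abandoned. A job whose worker goes silent for longer than
#' \code{heartbeatTimeout} seconds is requeued. The master exits when
#' every job is done or abandoned, after replying shutdown to workers
#' that ask for more work. The master only ever transmits job file paths;
#' it never transfers data or results.
#'
#' A done report is accepted at most once per job, and only from the
#' worker the job is currently assigned to, so a job can never complete
#' twice.
#'
#' @param jobs list of \code{\link{Job-class}} objects with unique ids.
#' @param endpoint \code{tcp://host:port} to bind (host is informational;
#'   the socket listens on all interfaces).
#' @param retryLimit maximum number of re-dispatches after failures.
#' @param heartbeatTimeout seconds a running job may go unreported before
#'   being requeued.
#' @param drainTimeout seconds to keep answering shutdown after the queue
#'   empties, so idle workers exit cleanly.
#' @param expectedWorkers when the launcher knows how many workers it
#'   started (e.g. \code{\link{runLocal}}), the drain phase also waits for
#'   stragglers that had not yet registered, up to \code{drainTimeout}.
#' @param logFile optional master log; records run settings and every
#'   worker-job assignment.
#' @return run summary: data.frame with one row per job (\code{job_id},
#'   \code{state}, \code{attempts}, \code{worker_id}, \code{error}).
#' @export
masterServe <- function(jobs, endpoint, retryLimit = 3L,
                        heartbeatTimeout = 60, drainTimeout = 5,
                        logFile = NULL, expectedWorkers = NULL) {
  ids <- vapply(jobs, function(j) j@jobId, "")
  if (anyDuplicated(ids))
    stop("duplicate job ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ep <- parseEndpoint(endpoint)
  mlog <- function(...) {
    if (!is.null(logFile))
      cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...), "\n",
          sep = "", file = logFile, append = TRUE)
  }
  mlog("master start: %d job(s), endpoint %s, retry limit %d",
       length(jobs), endpoint, retryLimit)

  st <- new.env(parent = emptyenv())
  st$state <- setNames(rep("queued", length(ids)), ids)
  st$attempts <- setNames(rep(0L, length(ids)), ids)
  st$worker <- setNames(rep(NA_character_, length(ids)), ids)
  st$error <- setNames(rep(NA_character_, length(ids)), ids)
  st$dispatched <- setNames(rep(Inf, length(ids)), ids)
  queue <- ids                       # FIFO
  jobsById <- setNames(jobs, ids)
  workersSeen <- character(0)
  workersDown <- character(0)

  allTerminal <- function() all(st$state %in% c("done", "abandoned"))

  requeueOrAbandon <- function(id, why) {
    if (st$attempts[[id]] >= retryLimit + 1L) {
      st$state[[id]] <- "abandoned"
      st$error[[id]] <- why
      mlog("job %s abandoned after %d attempt(s): %s", id,
           st$attempts[[id]], why)
    } else {
      st$state[[id]] <- "failed"
      st$error[[id]] <- why
      queue <<- c(queue, id)
      mlog("job %s requeued (attempt %d failed): %s", id,
           st$attempts[[id]], why)
    }
    st$dispatched[[id]] <- Inf
  }

  nextDirective <- function(worker) {
    ## drop any stale running assignment this worker abandoned by asking
    ## for new work without reporting (protocol violation)
    stale <- names(st$state)[st$state == "running" &
                               !is.na(st$worker) & st$worker == worker]
    for (id in stale) requeueOrAbandon(id, "worker abandoned job")
    if (length(queue)) {
      id <- queue[1]
      queue <<- queue[-1]
      st$state[[id]] <- "running"
      st$attempts[[id]] <- st$attempts[[id]] + 1L
      st$worker[[id]] <- worker
      st$dispatched[[id]] <- as.numeric(Sys.time())
      mlog("job %s -> worker %s (attempt %d)", id, worker,
           st$attempts[[id]])
      list(type = "job", job = jobToList(jobsById[[id]]))
    } else if (allTerminal()) {
      workersDown <<- union(workersDown, worker)
      mlog("shutdown -> worker %s", worker)
      list(type = "shutdown")
    } else {
      list(type = "wait", retry_after = 0.2)
    }
  }

  handle <- function(msg) {
    worker <- if (is.null(msg$worker)) "unknown" else msg$worker
    if (identical(msg$type, "status"))
      return(list(type = "status",
                  jobs = unname(apply(statusFrame(st), 1L, as.list))))
    workersSeen <<- union(workersSeen, worker)
    if (identical(msg$type, "register") || identical(msg$type, "poll")) {
      if (identical(msg$type, "register"))
        mlog("worker %s registered", worker)
      return(nextDirective(worker))
    }
    if (identical(msg$type, "done") || identical(msg$type, "failed")) {
      id <- msg$job_id
      valid <- !is.null(id) && id %in% names(st$state) &&
        st$state[[id]] == "running" && identical(st$worker[[id]], worker)
      if (!valid) {
        mlog("rejected %s report for job %s from worker %s", msg$type,
             if (is.null(id)) "<none>" else id, worker)
      } else if (msg$type == "done") {
        st$state[[id]] <- "done"
        st$error[[id]] <- NA_character_
        st$dispatched[[id]] <- Inf
        mlog("job %s done (worker %s)", id, worker)
      } else {
        requeueOrAbandon(id, if (is.null(msg$error)) "worker-reported failure"
                             else msg$error)
      }
      return(nextDirective(worker))
    }
    list(type = "error", message = paste("unknown message type:",
                                         if (is.null(msg$type)) "<none>"
                                         else msg$type))
  }

  srv <- serverSocket(ep$port)
  on.exit(close(srv), add = TRUE)

  serveOne <- function(timeout) {
    if (!socketSelect(list(srv), timeout = timeout)) return(FALSE)
    con <- tryCatch(socketAccept(srv, blocking = TRUE, open = "r+",
                                 timeout = 10),
                    error = function(e) NULL)
    if (is.null(con)) return(FALSE)
    on.exit(close(con))
    msg <- readMsg(con)
    reply <- if (is.null(msg))
      list(type = "error", message = "unparsable request")
    else handle(msg)
    tryCatch(writeMsg(con, reply), error = function(e) NULL)
    TRUE
  }

  while (!allTerminal()) {
    serveOne(timeout = 0.2)
    now <- as.numeric(Sys.time())
    late <- names(st$state)[st$state == "running" &
                              now - st$dispatched > heartbeatTimeout]
    for (id in late) requeueOrAbandon(id, "heartbeat timeout")
  }

  deadline <- as.numeric(Sys.time()) + drainTimeout
  needDrain <- function() {
    length(setdiff(workersSeen, workersDown)) > 0L ||
      (!is.null(expectedWorkers) && length(workersDown) < expectedWorkers)
  }
  while (needDrain() && as.numeric(Sys.time()) < deadline)
    serveOne(timeout = 0.2)

  mlog("master exit: %d done, %d abandoned",
       sum(st$state == "done"), sum(st$state == "abandoned"))
  statusFrame(st)
}

#' Worker loop
#'
#' Registers with the master, then repeatedly receives a job, runs
#' \code{executor(job)}, reports done (or failed, with the error message)
#' and receives the next directive, until the master replies shutdown.
#' The worker fetches its own inputs and writes its own outputs; only
#' control messages cross the network. An executor error is reported as a
#' job failure and the loop continues with the next job.
#'
#' @param endpoint master \code{tcp://host:port}.
#' @param executor function taking a \code{\link{Job-class}} and producing
#'   the job's outputs; its return value is discarded.
#' @param workerId identifier reported to the master; default combines
#'   host name and PID.
#' @param connectRetries bounded connection attempts (the master may not
#'   be up yet, or busy); exhausted before any successful contact is an
#'   error.
#' @param retryInterval seconds between connection attempts.
#' @return invisibly, the number of jobs executed.
#' @export
workerLoop <- function(endpoint, executor, workerId = NULL,
                       connectRetries = 80L, retryInterval = 0.25) {
  ep <- parseEndpoint(endpoint)
  if (is.null(workerId))
    workerId <- sprintf("%s-%d", Sys.info()[["nodename"]], Sys.getpid())
  everConnected <- FALSE
  request <- function(msg) {
    for (i in seq_len(connectRetries)) {
      reply <- tryCatch(dmwRequest(ep$host, ep$port, msg),
                        error = function(e) e)
      if (!inherits(reply, "error")) {
        everConnected <<- TRUE
        return(reply)
      }
      Sys.sleep(retryInterval)
    }
    if (!everConnected)
      stop("worker ", workerId, ": master unreachable at ", endpoint)
    NULL                            # master gone after a completed run
  }
  nDone <- 0L
  msg <- list(type = "register", worker = workerId)
  repeat {
    reply <- request(msg)
    if (is.null(reply) || identical(reply$type, "shutdown")) break
    if (identical(reply$type, "wait")) {
      Sys.sleep(if (is.null(reply$retry_after)) 0.2
                else as.numeric(reply$retry_after))
      msg <- list(type = "poll", worker = workerId)
    } else if (identical(reply$type, "job")) {
      j <- jobFromList(reply$job)
      res <- tryCatch({
        executor(j)
        NULL
      }, error = function(e) conditionMessage(e))
      nDone <- nDone + 1L
      msg <- if (is.null(res))
        list(type = "done", worker = workerId, job_id = j@jobId)
      else list(type = "failed", worker = workerId, job_id = j@jobId,
                error = res)
    } else {
      stop("worker ", workerId, ": unexpected reply type '", reply$type,
           "'")
    }
  }
  invisible(nDone)
}

#' Query the status of a running master
#'
#' Read-only snapshot of every job's status, for interactive monitoring
#' from the command line.
#'
#' @param endpoint master \code{tcp://host:port}.
#' @return data.frame with columns \code{job_id}, \code{state},
#'   \code{attempts}, \code{worker_id}, \code{error}.
#' @export
queryStatus <- function(endpoint) {
  ep <- parseEndpoint(endpoint)
  reply <- tryCatch(dmwRequest(ep$host, ep$port, list(type = "status")),
                    error = function(e)
                      stop("master not reachable at ", endpoint, ": ",
                           conditionMessage(e), call. = FALSE))
  rows <- lapply(reply$jobs, function(j)
    data.frame(job_id = j$job_id, state = j$state,
               attempts = as.integer(j$attempts),
               worker_id = if (is.null(j$worker_id)) NA_character_
                           else j$worker_id,
               error = if (is.null(j$error)) NA_character_ else j$error,
               stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(job_id = character(0), state = character(0),
                      attempts = integer(0), worker_id = character(0),
                      error = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a jobs table
#'
#' Tab-separated, one job per line: reads, reference, annotations, output
#' and optionally a precomputed mapping file as a fifth column. Lines
#' starting with '#' are ignored. Job ids are j1, j2, ... in file order.
#'
#' @param path jobs file.
#' @return list of \code{\link{Job-class}} objects.
#' @export
readJobsFile <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (!length(f) %in% 4:5)
      stop("jobs file parse error at line ", keep[i], " of '", path,
           "': expected 4 or 5 tab-separated columns, found ", length(f))
    job(jobId = paste0("j", i), readsPath = f[1], referencePath = f[2],
        annotationsPath = f[3], outputPath = f[4],
        mappingPath = if (length(f) == 5L) f[5] else "")
  })
}
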