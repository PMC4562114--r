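.logState <- new.env(parent = emptyenv())
.logState$level <- "info"
.logState$file <- NULL
.logState$mirror <- FALSE

#' Configure logging
#'
#' The pipeline has two log levels: \code{"info"} emits one line when each
#' important step starts or finishes; \code{"verbose"} additionally emits
#' summary statistics (record tallies in and out) around many steps.
#' Messages go to \code{file} when set, and are mirrored to the console
#' when \code{mirror} is TRUE.
#'
#' @param level "info" or "verbose".
#' @param file log file path, or NULL to disable file output.
#' @param mirror also write log lines to the console.
#' @return previous settings, invisibly.
#' @export
configureLogging <- function(level = c("info", "verbose"), file = NULL,
                             mirror = FALSE) {
  level <- match.arg(level)
  old <- as.list(.logState)
  .logState$level <- level
  .logState$file <- file
  .logState$mirror <- mirror
  invisible(old)
}

#' Emit one log event
#'
#' Info-level events are always emitted; verbose-level events only when the
#' configured level is "verbose". Optional \code{stats} (a named list of
#' scalars) are appended as \code{key=value} pairs.
#'
#' @param level "info" or "verbose" (the level of this event).
#' @param stage pipeline stage name.
#' @param message free-text message.
#' @param stats optional named list of summary statistics.
#' @export
logEvent <- function(level = c("info", "verbose"), stage, message,
                     stats = NULL) {
  level <- match.arg(level)
  if (level == "verbose" && .logState$level != "verbose") return(invisible())
  extra <- ""
  if (length(stats))
    extra <- paste0(" [", paste(names(stats), unlist(stats), sep = "=",
                                collapse = " "), "]")
  line <- sprintf("%s %-7s %s: %s%s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), stage, message, extra)
  if (!is.null(.logState$file))
    cat(line, "\n", sep = "", file = .logState$file, append = TRUE)
  if (.logState$mirror) message(line)
  invisible()
}
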