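#' @importFrom utils head tail
NULL

## gzip magic bytes 1f 8b
isGzip <- function(path) {
  two <- readBin(path, "raw", n = 2L)
  length(two) == 2L && two[1] == as.raw(0x1f) && two[2] == as.raw(0x8b)
}

openTextMaybeGzip <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (isGzip(path)) gzfile(path, "rt") else file(path, "rt")
}

#' Stream sequence reads from FASTA/FASTQ
#'
#' Opens a FASTA or FASTQ file (optionally gzip-compressed, detected from
#' the magic bytes) and returns a stream object whose \code{$nextChunk()}
#' yields successive chunks of records as a data.frame with columns
#' \code{id} (first whitespace-delimited token of the header),
#' \code{sequence}, and \code{quality} (the raw quality string, or NA for
#' FASTA). Records are parsed lazily, so memory use is bounded by one
#' chunk. \code{$nextChunk()} returns NULL at end of file (the underlying
#' connection is then closed); \code{$close()} releases it early.
#'
#' @param path FASTA/FASTQ file, optionally gzipped.
#' @param format "auto" (detect from the first non-empty character:
#'   '>' FASTA, '@' FASTQ), "fasta" or "fastq".
#' @param chunkSize maximum records per chunk.
#' @return an object of class \code{SequenceStream} with elements
#'   \code{nextChunk}, \code{close} and \code{format}.
#' @seealso \code{\link{readSequences}} to materialize a whole file.
#' @export
streamReads <- function(path, format = c("auto", "fasta", "fastq"),
                        chunkSize = 5000L) {
  format <- match.arg(format)
  con <- openTextMaybeGzip(path)
  state <- new.env(parent = emptyenv())
  state$lineNo <- 0L
  state$open <- TRUE
  state$pendingHeader <- NULL   # FASTA: header line waiting for its sequence
  state$pendingSeq <- character(0)
  state$fmt <- if (format == "auto") NA_character_ else format

  getLines <- function(n) {
    x <- readLines(con, n = n, warn = FALSE)
    state$lineNo <- state$lineNo + length(x)
    x
  }

  detect <- function() {
    repeat {
      l <- getLines(1L)
      if (!length(l)) return(NULL)
      if (!nzchar(trimws(l))) next
      ch <- substr(trimws(l), 1L, 1L)
      state$fmt <- switch(ch, ">" = "fasta", "@" = "fastq",
        stop("cannot detect read format of '", path,
             "': first record starts with '", ch, "'"))
      return(l)
    }
  }

  closeStream <- function() {
    if (state$open) {
      close(con)
      state$open <- FALSE
    }
    invisible()
  }

  idOf <- function(header) sub("^\\s*", "", strsplit(sub("^[>@]", "", header),
                                                     "\\s+")[[1]][1])

  nextFasta <- function(firstLine = NULL) {
    ids <- character(0); seqs <- character(0)
    flushRec <- function() {
      if (!is.null(state$pendingHeader)) {
        id <- idOf(state$pendingHeader)
        if (!nzchar(id) || is.na(id))
          stop("malformed FASTA header at line ",
               state$pendingHeaderLine, " of '", path, "'")
        ids <<- c(ids, id)
        seqs <<- c(seqs, paste(state$pendingSeq, collapse = ""))
        state$pendingHeader <- NULL
        state$pendingSeq <- character(0)
      }
    }
    takeLine <- function(l, lineNo) {
      if (startsWith(l, ">")) {
        flushRec()
        state$pendingHeader <- l
        state$pendingHeaderLine <- lineNo
      } else if (nzchar(trimws(l))) {
        if (is.null(state$pendingHeader))
          stop("sequence data before any FASTA header at line ", lineNo,
               " of '", path, "'")
        state$pendingSeq <- c(state$pendingSeq, trimws(l))
      }
    }
    if (!is.null(firstLine)) takeLine(firstLine, state$lineNo)
    while (length(ids) < chunkSize) {
      l <- getLines(256L)
      if (!length(l)) { flushRec(); closeStream(); break }
      for (i in seq_along(l)) takeLine(l[i], state$lineNo - length(l) + i)
      if (length(ids) >= chunkSize) break
    }
    if (!length(ids)) return(NULL)
    data.frame(id = ids, sequence = seqs, quality = NA_character_,
               stringsAsFactors = FALSE)
  }

  nextFastq <- function(firstLine = NULL) {
    lines <- firstLine
    want <- chunkSize * 4L - length(lines)
    lines <- c(lines, getLines(want))
    if (!length(lines)) { closeStream(); return(NULL) }
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at end of '", path, "' (line ",
           state$lineNo, ")")
    k <- length(lines) %/% 4L
    hd <- lines[seq(1L, by = 4L, length.out = k)]
    sq <- lines[seq(2L, by = 4L, length.out = k)]
    pl <- lines[seq(3L, by = 4L, length.out = k)]
    qu <- lines[seq(4L, by = 4L, length.out = k)]
    firstLineNo <- state$lineNo - length(lines) + 1L
    bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
    if (length(bad))
      stop("malformed FASTQ record at line ",
           firstLineNo + (bad[1] - 1L) * 4L, " of '", path, "'")
    mism <- which(nchar(sq) != nchar(qu))
    if (length(mism))
      stop("FASTQ length mismatch for record '", idOf(hd[mism[1]]),
           "' at line ", firstLineNo + (mism[1] - 1L) * 4L, " of '", path,
           "': sequence ", nchar(sq[mism[1]]), " bases, qualities ",
           nchar(qu[mism[1]]))
    if (length(lines) < chunkSize * 4L) closeStream()
    data.frame(id = vapply(hd, idOf, "", USE.NAMES = FALSE), sequence = sq,
               quality = qu, stringsAsFactors = FALSE)
  }

  nextChunk <- function() {
    if (!state$open && is.null(state$pendingHeader)) return(NULL)
    tryCatch({
      first <- NULL
      if (is.na(state$fmt)) {
        first <- detect()
        if (is.null(first)) { closeStream(); return(NULL) }
      }
      if (state$fmt == "fasta") nextFasta(first) else nextFastq(first)
    }, error = function(e) {
      closeStream()
      stop(e)
    })
  }

  structure(list(nextChunk = nextChunk, close = closeStream,
                 format = function() state$fmt, path = path),
            class = "SequenceStream")
}

#' @export
print.SequenceStream <- function(x, ...) {
  cat("SequenceStream over", x$path, "\n")
  invisible(x)
}

#' Read a whole FASTA/FASTQ file into a data.frame
#'
#' Materializes \code{\link{streamReads}}: one row per record with columns
#' \code{id}, \code{sequence}, \code{quality} (NA for FASTA).
#'
#' @inheritParams streamReads
#' @return data.frame of sequence records.
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq"),
                          chunkSize = 50000L) {
  s <- streamReads(path, format, chunkSize = chunkSize)
  out <- list()
  repeat {
    ch <- s$nextChunk()
    if (is.null(ch)) break
    out[[length(out) + 1L]] <- ch
  }
  if (!length(out))
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write sequence records as FASTA
#'
#' @param reads data.frame with columns \code{id}, \code{sequence}.
#' @param path output path; a ".gz" suffix selects gzip compression.
#' @export
writeFasta <- function(reads, path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0(">", reads$id, "\n", reads$sequence), con)
  invisible(path)
}

#' Write sequence records as FASTQ
#'
#' @param reads data.frame with columns \code{id}, \code{sequence},
#'   \code{quality}; all quality strings must be present.
#' @param path output path; a ".gz" suffix selects gzip compression.
#' @export
writeFastq <- function(reads, path) {
  if (nrow(reads) && anyNA(reads$quality))
    stop("cannot write FASTQ: missing quality strings")
  con <- if (endsWith(path, ".gz")) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con)
  invisible(path)
}

#' Reference sequence lengths from a FASTA file
#'
#' Names are trimmed to the first whitespace-delimited token so they match
#' the reference ids used by mappers.
#'
#' @param path reference FASTA.
#' @return named integer vector of sequence lengths.
#' @export
referenceLengths <- function(path) {
  lens <- Biostrings::fasta.seqlengths(path)
  names(lens) <- vapply(strsplit(names(lens), "\\s+"), `[[`, "", 1L)
  lens
}
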