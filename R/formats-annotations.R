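#' Read an annotation table
#'
#' The annotation format is a minimal GFF-like tab-separated table with
#' five columns per line: reference id, start, end, strand, label. File
#' coordinates are 1-based inclusive (GFF convention); internally all
#' coordinates are 0-based half-open, so a file line \code{start=1 end=45}
#' becomes the interval [0, 45). Lines starting with '#' and blank lines
#' are ignored. File order is preserved.
#'
#' @param path tab-separated annotation file.
#' @return data.frame with columns \code{ref_id}, \code{start} (0-based),
#'   \code{end} (exclusive), \code{strand} (one of "+", "-", "."),
#'   \code{label}.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) return(emptyAnnotations())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    i <- which(nf != 5L)[1]
    stop("annotation parse error at line ", keep[i], " of '", path,
         "': expected 5 tab-separated columns, found ", nf[i])
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 2]))
  end1 <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad))
    stop("annotation parse error at line ", keep[bad[1]], " of '", path,
         "': non-integer coordinates")
  bad <- which(start1 < 1L | start1 > end1)
  if (length(bad))
    stop("annotation parse error at line ", keep[bad[1]], " of '", path,
         "': need 1 <= start <= end, got start=", start1[bad[1]],
         " end=", end1[bad[1]])
  bad <- which(!m[, 4] %in% c("+", "-", "."))
  if (length(bad))
    stop("annotation parse error at line ", keep[bad[1]], " of '", path,
         "': strand must be one of + - .")
  bad <- which(!nzchar(m[, 5]))
  if (length(bad))
    stop("annotation parse error at line ", keep[bad[1]], " of '", path,
         "': empty label")
  data.frame(ref_id = m[, 1], start = start1 - 1L, end = end1,
             strand = m[, 4], label = m[, 5], stringsAsFactors = FALSE)
}

emptyAnnotations <- function() {
  data.frame(ref_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' Write an annotation table
#'
#' Inverse of \code{\link{readAnnotations}}: internal 0-based half-open
#' coordinates are converted back to the file's 1-based inclusive
#' convention (an involution with the reader).
#'
#' @param annotations data.frame as returned by \code{readAnnotations}.
#' @param path output path.
#' @export
writeAnnotations <- function(annotations, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", annotations$ref_id,
                   annotations$start + 1L, annotations$end,
                   annotations$strand, annotations$label)
  writeLines(lines, path)
  invisible(path)
}
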