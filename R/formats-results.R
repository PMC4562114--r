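resultsHeader <- paste0("#ref_id\tstart\tend\tstrand\tlabel\tcount\t",
                        "median_cov\tmean_cov\tsd_cov")

fmtNum <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
fmtInt <- function(x) ifelse(is.na(x), "NA", as.character(x))

#' Write quantification results
#'
#' One header comment line, then one tab-separated row per annotated
#' region in annotation-file order: ref_id, start, end (1-based inclusive
#' file convention), strand, label, count, median_cov, mean_cov, sd_cov.
#' Coverage statistics are fixed 4-decimal; disabled fields are written as
#' "NA".
#'
#' @param results data.frame as returned by \code{\link{regionStatistics}}
#'   (internal 0-based half-open coordinates).
#' @param path output path.
#' @export
writeResults <- function(results, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(resultsHeader, con)
  if (nrow(results)) {
    lines <- paste(results$ref_id, results$start + 1L, results$end,
                   results$strand, results$label, fmtInt(results$count),
                   fmtNum(results$median_cov), fmtNum(results$mean_cov),
                   fmtNum(results$sd_cov), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a quantification results table
#'
#' Inverse of \code{\link{writeResults}}; coordinates are converted back
#' to the internal 0-based half-open convention.
#'
#' @param path results file.
#' @return data.frame with columns \code{ref_id}, \code{start}, \code{end},
#'   \code{strand}, \code{label}, \code{count}, \code{median_cov},
#'   \code{mean_cov}, \code{sd_cov}.
#' @export
readResults <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      label = character(0), count = integer(0),
                      median_cov = numeric(0), mean_cov = numeric(0),
                      sd_cov = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L))
    stop("results parse error in '", path, "': expected 9 columns")
  m <- matrix(unlist(parts), ncol = 9L, byrow = TRUE)
  num <- function(j) suppressWarnings(as.numeric(ifelse(m[, j] == "NA",
                                                        NA, m[, j])))
  data.frame(ref_id = m[, 1], start = as.integer(m[, 2]) - 1L,
             end = as.integer(m[, 3]), strand = m[, 4], label = m[, 5],
             count = as.integer(ifelse(m[, 6] == "NA", NA, m[, 6])),
             median_cov = num(7), mean_cov = num(8), sd_cov = num(9),
             stringsAsFactors = FALSE)
}
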