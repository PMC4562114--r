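#' @importFrom data.table fread fwrite setDF
NULL

emptyHits <- function() {
  data.frame(query_id = character(0), ref_id = character(0),
             ref_start = integer(0), ref_end = integer(0),
             identity_pct = numeric(0), aln_len = integer(0),
             file_order = integer(0), stringsAsFactors = FALSE)
}

makeHits <- function(query_id, ref_id, ref_start, ref_end, identity_pct,
                     aln_len, file_order = seq_along(query_id) - 1L) {
  data.frame(query_id = query_id, ref_id = ref_id,
             ref_start = as.integer(ref_start), ref_end = as.integer(ref_end),
             identity_pct = as.numeric(identity_pct),
             aln_len = as.integer(aln_len),
             file_order = as.integer(file_order), stringsAsFactors = FALSE)
}

badLine <- function(policy, lineNo, path, what) {
  msg <- sprintf("mapping parse error at line %d of '%s': %s", lineNo,
                 path, what)
  if (policy == "strict") stop(msg)
  logEvent("verbose", "parse", msg)
  invisible()
}

#' Parse BLAST tabular (blast8/blast6out) mapper output
#'
#' Reads the 12-column tab-separated BLAST tabular format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart,
#' qend, sstart, send, e-value, bitscore). Subject coordinates are 1-based
#' inclusive and may have sstart > send for reverse-strand hits; the
#' reference interval is normalized to the 0-based half-open
#' [min(sstart,send)-1, max(sstart,send)), so strand never needs to be
#' carried further (quantification is strand-agnostic). \code{file_order}
#' numbers the emitted records sequentially from 0; it is what the
#' best-hit policy means by "first listed".
#'
#' @param path blast8 file.
#' @param policy malformed-line policy: \code{"skip"} drops the line and
#'   logs it (a summary count is logged at the end), \code{"strict"}
#'   aborts with the line number.
#' @return hits data.frame with columns \code{query_id}, \code{ref_id},
#'   \code{ref_start}, \code{ref_end}, \code{identity_pct}, \code{aln_len},
#'   \code{file_order}.
#' @export
parseBlast8 <- function(path, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1:2), data.table = TRUE,
              showProgress = FALSE)
  if (!nrow(dt)) return(emptyHits())
  if (ncol(dt) < 12L) {
    # whole file short on columns: report the first offending line
    badLine("strict", 1L, path,
            sprintf("expected 12 columns, found %d", ncol(dt)))
  }
  id <- suppressWarnings(as.numeric(dt[[3]]))
  al <- suppressWarnings(as.integer(dt[[4]]))
  s <- suppressWarnings(as.integer(dt[[9]]))
  e <- suppressWarnings(as.integer(dt[[10]]))
  ok <- !(is.na(id) | is.na(al) | is.na(s) | is.na(e)) &
    nzchar(dt[[1]]) & nzchar(dt[[2]]) & id >= 0 & id <= 100 & s >= 1L &
    e >= 1L
  if (ncol(dt) > 12L)  # ragged rows padded by fill=TRUE
    ok <- ok & is.na(dt[[13]])
  if (!all(ok)) {
    for (i in head(which(!ok), 20L))
      badLine(policy, i, path, "malformed blast8 record")
    logEvent("verbose", "parse",
             sprintf("skipped %d malformed line(s) in '%s'",
                     sum(!ok), path))
  }
  makeHits(dt[[1]][ok], dt[[2]][ok], pmin(s, e)[ok] - 1L, pmax(s, e)[ok],
           id[ok], al[ok])
}

#' Write hits in blast8 dialect
#'
#' Used by the synthetic module for ground-truth mappings. The inverse of
#' \code{\link{parseBlast8}} for the fields quantification consumes;
#' query coordinates are written as 1..aln_len, mismatches/gaps as 0.
#'
#' @param hits hits data.frame (internal 0-based half-open intervals).
#' @param path output path.
#' @export
writeBlast8 <- function(hits, path) {
  n <- nrow(hits)
  dt <- data.table::data.table(
    q = hits$query_id, s = hits$ref_id,
    id = sprintf("%.2f", hits$identity_pct), al = hits$aln_len,
    mm = 0L, go = 0L, qs = 1L, qe = hits$aln_len,
    ss = hits$ref_start + 1L, se = hits$ref_end,
    ev = rep("1e-30", n), bs = rep("90.0", n))
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

cigarRefSpan <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops)) return(NA_integer_)
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- substr(ops, nchar(ops), nchar(ops))
  list(ref = sum(n[op %in% c("M", "D", "N", "=", "X")]),
       cols = sum(n[op %in% c("M", "I", "D", "=", "X")]))
}

#' Parse SAM mapper output
#'
#' Reads SAM text (header lines tolerated but not required). Unmapped
#' records (FLAG bit 0x4) are skipped; mapped records with CIGAR '*' are
#' skipped and logged. The reference interval is [POS-1, POS-1 + span)
#' where span is the total length of the reference-consuming CIGAR
#' operations (M/D/N/=/X). Percent identity is derived from the NM tag as
#' 100*(1 - NM/columns) over the M/I/D/=/X alignment columns, or 100 when
#' the tag is absent. \code{file_order} numbers emitted records from 0.
#'
#' @inheritParams parseBlast8
#' @return hits data.frame (see \code{\link{parseBlast8}}).
#' @export
parseSam <- function(path, policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, warn = FALSE)
  aln <- which(nzchar(lines) & !startsWith(lines, "@"))
  qid <- rid <- character(0)
  rs <- re <- al <- integer(0)
  idp <- numeric(0)
  for (i in aln) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) {
      badLine(policy, i, path, "fewer than 11 SAM fields")
      next
    }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos)) {
      badLine(policy, i, path, "non-numeric FLAG or POS")
      next
    }
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    if (f[6] == "*") {
      badLine(policy, i, path, "mapped record with CIGAR '*'")
      next
    }
    span <- cigarRefSpan(f[6])
    if (!is.list(span) || is.na(span$ref) || span$ref < 1L) {
      badLine(policy, i, path, paste0("unparsable CIGAR '", f[6], "'"))
      next
    }
    nm <- regmatches(lines[i], regexpr("\tNM:i:\\d+", lines[i]))
    pid <- if (length(nm)) {
      nmv <- as.integer(sub("\tNM:i:", "", nm))
      100 * (1 - nmv / span$cols)
    } else 100.0
    qid <- c(qid, f[1]); rid <- c(rid, f[3])
    rs <- c(rs, pos - 1L); re <- c(re, pos - 1L + span$ref)
    al <- c(al, span$cols); idp <- c(idp, pid)
  }
  makeHits(qid, rid, rs, re, idp, al)
}
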