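#' @importFrom stats runif
NULL

checkHitRefs <- function(hits, refLengths, policy) {
  known <- hits$ref_id %in% names(refLengths)
  if (!all(known)) {
    msg <- sprintf("%d hit(s) reference unknown sequence(s): %s",
                   sum(!known),
                   paste(head(unique(hits$ref_id[!known]), 5L),
                         collapse = ", "))
    if (policy == "abort") stop(msg)
    logEvent("verbose", "coverage", paste("skipped:", msg))
    hits <- hits[known, , drop = FALSE]
  }
  hits
}

clipHits <- function(hits, refLengths) {
  lens <- unname(refLengths[hits$ref_id])
  over <- hits$ref_end > lens | hits$ref_start < 0L
  if (any(over)) {
    hits$ref_end <- pmin(hits$ref_end, as.integer(lens))
    hits$ref_start <- pmax(hits$ref_start, 0L)
    logEvent("verbose", "coverage",
             sprintf("clipped %d hit(s) at reference bounds", sum(over)))
  }
  list(hits = hits, clipped = sum(over))
}

#' Per-base coverage by difference-array accumulation
#'
#' Each reference sequence is represented by an integer array with one
#' slot per base. For every hit, the slot at the interval start is
#' incremented and the slot just past the interval end is decremented
#' (half-open convention, so the last aligned base stays covered); the
#' per-base depth is then the cumulative sum over each array. This costs
#' 2 writes per hit plus one write per reference base for the cumulative
#' sum - O(n + N) for n total reference bases and N hits, independent of
#' read length. The instrumented count of these elementary writes is
#' available via \code{\link{coverageWrites}}.
#'
#' Hits extending past a reference end are clipped to the reference and
#' logged rather than dropped, preserving coverage mass.
#'
#' @param hits hits data.frame (already filtered).
#' @param refLengths named integer vector of reference lengths (see
#'   \code{\link{referenceLengths}}).
#' @param policy what to do with hits on unknown references: "skip" (log
#'   and drop) or "abort".
#' @return a \code{\link{CoverageMap-class}} object.
#' @seealso \code{\link{naiveCoverage}} for the per-base reference
#'   implementation used as a test oracle.
#' @export
buildCoverage <- function(hits, refLengths, policy = c("skip", "abort")) {
  policy <- match.arg(policy)
  hits <- checkHitRefs(hits, refLengths, policy)
  cl <- clipHits(hits, refLengths)
  hits <- cl$hits
  keep <- hits$ref_end > hits$ref_start
  hits <- hits[keep, , drop = FALSE]
  depth <- vector("list", length(refLengths))
  names(depth) <- names(refLengths)
  writes <- 0
  byRef <- split(seq_len(nrow(hits)), hits$ref_id)
  for (r in names(refLengths)) {
    L <- as.integer(refLengths[[r]])
    idx <- byRef[[r]]
    if (is.null(idx)) {
      depth[[r]] <- integer(L)
      writes <- writes + L       # cumulative sum still writes every slot
      next
    }
    s <- hits$ref_start[idx]
    e <- hits$ref_end[idx]
    d <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
    writes <- writes + 2 * length(idx)   # one +1 and one -1 per hit
    depth[[r]] <- cumsum(d)[seq_len(L)]
    writes <- writes + L                 # one store per slot in the cumsum
  }
  new("CoverageMap", depth = depth, writes = writes,
      nHits = nrow(hits), clipped = as.integer(cl$clipped))
}

#' Per-base coverage by naive per-base increments
#'
#' Reference implementation used as a test oracle for
#' \code{\link{buildCoverage}}: every base covered by every hit is
#' incremented individually, costing O(n + N*M) writes where M is the
#' interval length. Output is identical to the difference-array route;
#' only the instrumented write count differs.
#'
#' @inheritParams buildCoverage
#' @return a \code{\link{CoverageMap-class}} object.
#' @export
naiveCoverage <- function(hits, refLengths, policy = c("skip", "abort")) {
  policy <- match.arg(policy)
  hits <- checkHitRefs(hits, refLengths, policy)
  cl <- clipHits(hits, refLengths)
  hits <- cl$hits
  depth <- lapply(refLengths, function(L) integer(L))
  names(depth) <- names(refLengths)
  writes <- 0
  for (i in seq_len(nrow(hits))) {
    s <- hits$ref_start[i]
    e <- hits$ref_end[i]
    if (e <= s) next
    r <- hits$ref_id[i]
    depth[[r]][(s + 1L):e] <- depth[[r]][(s + 1L):e] + 1L
    writes <- writes + (e - s)           # one increment per covered base
  }
  new("CoverageMap", depth = depth, writes = writes,
      nHits = nrow(hits), clipped = as.integer(cl$clipped))
}

#' Count reads per annotated region
#'
#' A retained hit contributes +1 to every annotation on the same
#' reference whose intersection with the hit's interval satisfies the
#' overlap rule; a hit spanning several overlapping regions counts in
#' each of them (no fractional assignment). Counts are per retained hit.
#' Overlap detection uses interval trees (\code{IRanges::findOverlaps}).
#'
#' @param hits hits data.frame, already passed through
#'   \code{\link{filterHits}}.
#' @param annotations annotation data.frame (see
#'   \code{\link{readAnnotations}}).
#' @param rule an \code{\link{overlapRule}} object.
#' @return integer vector of counts, parallel to the rows of
#'   \code{annotations}.
#' @export
countReads <- function(hits, annotations, rule = overlapRule()) {
  stopifnot(is(rule, "OverlapRule"))
  counts <- integer(nrow(annotations))
  if (!nrow(hits) || !nrow(annotations)) return(counts)
  for (r in unique(annotations$ref_id)) {
    ai <- which(annotations$ref_id == r)
    hi <- which(hits$ref_id == r)
    if (!length(hi)) next
    hr <- IRanges::IRanges(start = hits$ref_start[hi] + 1L,
                           end = hits$ref_end[hi])
    ar <- IRanges::IRanges(start = annotations$start[ai] + 1L,
                           end = annotations$end[ai])
    ov <- IRanges::findOverlaps(hr, ar, minoverlap = rule@minOverlapBases)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (!is.na(rule@minOverlapFrac) && length(qh)) {
      w <- IRanges::width(IRanges::pintersect(hr[qh], ar[sh]))
      ok <- w / IRanges::width(hr[qh]) >= rule@minOverlapFrac
      sh <- sh[ok]
    }
    counts[ai] <- counts[ai] + tabulate(sh, nbins = length(ai))
  }
  counts
}

## midpoint median / population sd computed from first principles; the
## test suite checks them against stats:: routines as an independent route
midMedian <- function(x) {
  n <- length(x)
  s <- sort(x)
  if (n %% 2L == 1L) as.numeric(s[(n + 1L) %/% 2L])
  else (as.numeric(s[n %/% 2L]) + as.numeric(s[n %/% 2L + 1L])) / 2
}

popSd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

#' Per-region coverage statistics
#'
#' For every annotation, computes the median (midpoint-averaged for
#' even-length regions), arithmetic mean, and population standard
#' deviation (divisor = region length, since the region's slots are the
#' whole population, not a sample) of the depth values over exactly the
#' slots [start, end). Counts or coverage can each be disabled by passing
#' NULL, in which case the corresponding output fields are NA.
#'
#' @param cov a \code{\link{CoverageMap-class}}, or NULL to disable
#'   coverage statistics.
#' @param annotations annotation data.frame.
#' @param counts integer vector from \code{\link{countReads}}, or NULL to
#'   disable counts.
#' @return results data.frame: the annotation columns plus \code{count},
#'   \code{median_cov}, \code{mean_cov}, \code{sd_cov}, in annotation
#'   order.
#' @export
regionStatistics <- function(cov, annotations, counts = NULL) {
  n <- nrow(annotations)
  med <- mea <- sdv <- rep(NA_real_, n)
  if (!is.null(cov)) {
    stopifnot(is(cov, "CoverageMap"))
    for (i in seq_len(n)) {
      r <- annotations$ref_id[i]
      if (!r %in% names(cov@depth))
        stop("annotation '", annotations$label[i],
             "' references unknown sequence '", r, "'")
      d <- cov@depth[[r]]
      if (annotations$end[i] > length(d))
        stop("annotation '", annotations$label[i], "' [",
             annotations$start[i], ",", annotations$end[i],
             ") extends past the end of reference '", r, "' (length ",
             length(d), ")")
      x <- d[(annotations$start[i] + 1L):annotations$end[i]]
      med[i] <- midMedian(x)
      mea[i] <- sum(x) / length(x)
      sdv[i] <- popSd(x)
    }
  }
  cnt <- if (is.null(counts)) rep(NA_integer_, n) else as.integer(counts)
  data.frame(ref_id = annotations$ref_id, start = annotations$start,
             end = annotations$end, strand = annotations$strand,
             label = annotations$label, count = cnt, median_cov = med,
             mean_cov = mea, sd_cov = sdv, stringsAsFactors = FALSE)
}
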