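#' FASTQ quality filtering
#'
#' Keeps a read iff at least \code{params@minPercent} percent of its bases
#' have Phred quality >= \code{params@minQuality}. Order is preserved;
#' kept/discarded tallies are logged at the verbose level. Requesting
#' quality filtering on records without qualities (FASTA input) is a
#' configuration error.
#'
#' @param reads data.frame of sequence records (\code{id}, \code{sequence},
#'   \code{quality}).
#' @param params a \code{\link{qualityFilterParams}} object.
#' @return the kept records, same columns, original order.
#' @export
qualityFilter <- function(reads, params = qualityFilterParams()) {
  stopifnot(is(params, "QualityFilterParams"))
  if (!nrow(reads)) return(reads)
  if (anyNA(reads$quality))
    stop("quality filtering requested but records carry no qualities ",
         "(FASTA input?)")
  thr <- params@minQuality + params@offset
  nGood <- vapply(reads$quality,
                  function(s) sum(as.integer(charToRaw(s)) >= thr), 0L,
                  USE.NAMES = FALSE)
  len <- nchar(reads$sequence)
  keep <- nGood / len * 100 >= params@minPercent
  logEvent("verbose", "quality_filter", "filtered reads",
           stats = list(reads_in = nrow(reads), reads_kept = sum(keep),
                        reads_discarded = sum(!keep)))
  reads[keep, , drop = FALSE]
}

#' Drop qualities (FASTQ to FASTA conversion)
#'
#' Ids and sequences are unchanged; the quality column is set to NA so
#' that downstream writers emit FASTA.
#'
#' @param reads data.frame of sequence records.
#' @return the same records without qualities.
#' @export
convertToFasta <- function(reads) {
  reads$quality <- rep(NA_character_, nrow(reads))
  reads
}

#' Exclude reads by id (host-read removal hook)
#'
#' Pre-mapping hook for host-read removal: an upstream screen (e.g. an
#' alignment against a host genome) supplies the ids of reads to drop.
#' No aligner is bundled; only the exclusion step is provided.
#'
#' @param reads data.frame of sequence records.
#' @param ids character vector of read ids to exclude.
#' @return the records whose id is not in \code{ids}.
#' @export
excludeReads <- function(reads, ids) {
  keep <- !(reads$id %in% ids)
  logEvent("verbose", "exclude_reads", "host-read exclusion",
           stats = list(reads_in = nrow(reads), reads_kept = sum(keep)))
  reads[keep, , drop = FALSE]
}

#' Filter mapper hits and resolve ambiguous reads
#'
#' First removes hits failing the matching criteria (minimum percent
#' identity, minimum alignment length); then, if \code{bestHitOnly}, keeps
#' for each query only the surviving hit with the smallest
#' \code{file_order}, i.e. the first hit listed in the mapper output among
#' those that pass. Applying the criteria before best-hit selection means
#' a failing first hit does not shadow a passing later one. Output is
#' sorted by \code{file_order}.
#'
#' @param hits hits data.frame (see \code{\link{parseBlast8}}).
#' @param criteria a \code{\link{hitCriteria}} object.
#' @return the retained hits, sorted by \code{file_order}.
#' @export
filterHits <- function(hits, criteria = hitCriteria()) {
  stopifnot(is(criteria, "HitCriteria"))
  ok <- hits$identity_pct >= criteria@minIdentityPct &
    hits$aln_len >= criteria@minAlnLen
  h <- hits[ok, , drop = FALSE]
  h <- h[order(h$file_order), , drop = FALSE]
  if (criteria@bestHitOnly) h <- h[!duplicated(h$query_id), , drop = FALSE]
  logEvent("verbose", "filter_hits", "hit filtering",
           stats = list(hits_in = nrow(hits), hits_kept = nrow(h)))
  rownames(h) <- NULL
  h
}
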