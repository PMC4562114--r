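#' @import methods
NULL

#' Quality-filter parameters
#'
#' Parameters of the FASTQ quality filter: a read is kept iff at least
#' \code{minPercent} percent of its bases have Phred quality >=
#' \code{minQuality}.
#'
#' @slot minQuality Phred threshold q (0-60).
#' @slot minPercent minimum percentage p of bases at quality >= q (0 < p <= 100).
#' @slot offset ASCII offset of the quality encoding (33 = Phred+33).
#' @exportClass QualityFilterParams
setClass("QualityFilterParams",
  representation(minQuality = "integer", minPercent = "numeric",
                 offset = "integer"),
  prototype(minQuality = 20L, minPercent = 90, offset = 33L))

setValidity("QualityFilterParams", function(object) {
  if (object@minQuality < 0L || object@minQuality > 60L)
    return("minQuality must be in [0, 60]")
  if (object@minPercent <= 0 || object@minPercent > 100)
    return("minPercent must be in (0, 100]")
  if (object@offset < 0L) return("offset must be >= 0")
  TRUE
})

#' @param minQuality,minPercent,offset see slots.
#' @rdname QualityFilterParams-class
#' @export
qualityFilterParams <- function(minQuality = 20L, minPercent = 90,
                                offset = 33L) {
  new("QualityFilterParams", minQuality = as.integer(minQuality),
      minPercent = as.numeric(minPercent), offset = as.integer(offset))
}

#' Hit matching criteria
#'
#' Criteria applied to mapper hits before quantification, plus the policy
#' for ambiguously mapped reads: either keep all hits passing the criteria,
#' or only the best hit per read, defined as the first hit listed in the
#' mapper output among those that pass.
#'
#' @slot minIdentityPct minimum percent identity (0-100).
#' @slot minAlnLen minimum alignment length in columns.
#' @slot bestHitOnly keep only the first-listed surviving hit per read.
#' @exportClass HitCriteria
setClass("HitCriteria",
  representation(minIdentityPct = "numeric", minAlnLen = "integer",
                 bestHitOnly = "logical"),
  prototype(minIdentityPct = 0, minAlnLen = 0L, bestHitOnly = FALSE))

setValidity("HitCriteria", function(object) {
  if (object@minIdentityPct < 0 || object@minIdentityPct > 100)
    return("minIdentityPct must be in [0, 100]")
  if (object@minAlnLen < 0L) return("minAlnLen must be >= 0")
  if (length(object@bestHitOnly) != 1L) return("bestHitOnly must be scalar")
  TRUE
})

#' @param minIdentityPct,minAlnLen,bestHitOnly see slots.
#' @rdname HitCriteria-class
#' @export
hitCriteria <- function(minIdentityPct = 0, minAlnLen = 0L,
                        bestHitOnly = FALSE) {
  new("HitCriteria", minIdentityPct = as.numeric(minIdentityPct),
      minAlnLen = as.integer(minAlnLen), bestHitOnly = bestHitOnly)
}

#' Read-to-region overlap rule
#'
#' A hit is counted toward an annotated region when its reference interval
#' overlaps the region by at least \code{minOverlapBases} bases and, when
#' \code{minOverlapFrac} is set (non-NA), by at least that fraction of the
#' hit's own interval. Both conditions must hold when both are set.
#'
#' @slot minOverlapBases minimum overlap in bases (>= 1).
#' @slot minOverlapFrac optional minimum overlap fraction of the hit
#'   interval, in (0, 1]; NA disables the fractional condition.
#' @exportClass OverlapRule
setClass("OverlapRule",
  representation(minOverlapBases = "integer", minOverlapFrac = "numeric"),
  prototype(minOverlapBases = 1L, minOverlapFrac = NA_real_))

setValidity("OverlapRule", function(object) {
  if (object@minOverlapBases < 1L) return("minOverlapBases must be >= 1")
  f <- object@minOverlapFrac
  if (!is.na(f) && (f <= 0 || f > 1))
    return("minOverlapFrac must be in (0, 1] or NA")
  TRUE
})

#' @param minOverlapBases,minOverlapFrac see slots.
#' @rdname OverlapRule-class
#' @export
overlapRule <- function(minOverlapBases = 1L, minOverlapFrac = NA_real_) {
  new("OverlapRule", minOverlapBases = as.integer(minOverlapBases),
      minOverlapFrac = as.numeric(minOverlapFrac))
}

#' Per-base coverage over a reference database
#'
#' Per-reference integer arrays holding the number of retained hits that
#' span each base. Built by \code{\link{buildCoverage}} (difference-array
#' accumulation) or \code{\link{naiveCoverage}} (per-base increments, the
#' test oracle). The \code{writes} slot is an instrumented count of
#' elementary array-write operations, used to witness the O(n + N) claim.
#'
#' @slot depth named list of integer vectors, one per reference sequence.
#' @slot writes instrumented elementary array-write count.
#' @slot nHits number of hits accumulated.
#' @slot clipped number of hits clipped at a reference end.
#' @exportClass CoverageMap
setClass("CoverageMap",
  representation(depth = "list", writes = "numeric", nHits = "integer",
                 clipped = "integer"),
  prototype(depth = list(), writes = 0, nHits = 0L, clipped = 0L))

setValidity("CoverageMap", function(object) {
  if (length(object@depth) && is.null(names(object@depth)))
    return("depth must be a named list of integer vectors")
  for (d in object@depth) {
    if (!is.integer(d)) return("depth vectors must be integer")
    if (length(d) && min(d) < 0L) return("depth must be non-negative")
  }
  TRUE
})

#' @describeIn CoverageMap-class depth vector of one reference, or the full
#'   named list when \code{ref} is NULL.
#' @param x a CoverageMap.
#' @param ref reference id, or NULL for all.
#' @export
coverageDepth <- function(x, ref = NULL) {
  stopifnot(is(x, "CoverageMap"))
  if (is.null(ref)) return(x@depth)
  if (!ref %in% names(x@depth)) stop("unknown reference: ", ref)
  x@depth[[ref]]
}

#' @describeIn CoverageMap-class instrumented elementary-write count.
#' @export
coverageWrites <- function(x) {
  stopifnot(is(x, "CoverageMap"))
  x@writes
}

#' @describeIn CoverageMap-class total coverage mass, i.e. the sum of all
#'   depth values across all references (equals the summed interval length
#'   of the accumulated hits).
#' @export
totalCoverage <- function(x) {
  stopifnot(is(x, "CoverageMap"))
  sum(vapply(x@depth, function(d) sum(as.double(d)), 0))
}

setMethod("show", "CoverageMap", function(object) {
  n <- sum(vapply(object@depth, length, 0L))
  cat("CoverageMap:", length(object@depth), "reference(s),",
      n, "slots,", object@nHits, "hits, mass", totalCoverage(object), "\n")
})

#' Spiking design for the synthetic validation study
#'
#' Describes how a contig set is spiked with artificial reads: contigs
#' longer than \code{contigMinLen} are eligible, a fraction
#' \code{selectFraction} of them is selected at random, and each selected
#' contig of length L receives round(C * L / readLength) error-free reads
#' of length \code{readLength} at uniform start positions fully inside the
#' contig, where C is \code{coverageLevel}.
#'
#' @slot coverageLevel target fold-coverage C (> 0).
#' @slot readLength read length in bases.
#' @slot contigMinLen minimum contig length eligible for spiking.
#' @slot selectFraction fraction of eligible contigs to spike.
#' @slot seed random seed for selection and fragmentation.
#' @exportClass SpikeDesign
setClass("SpikeDesign",
  representation(coverageLevel = "numeric", readLength = "integer",
                 contigMinLen = "integer", selectFraction = "numeric",
                 seed = "integer"),
  prototype(coverageLevel = 1, readLength = 45L, contigMinLen = 2500L,
            selectFraction = 0.10, seed = 1L))

setValidity("SpikeDesign", function(object) {
  if (object@coverageLevel <= 0) return("coverageLevel must be > 0")
  if (object@readLength < 1L) return("readLength must be >= 1")
  if (object@selectFraction <= 0 || object@selectFraction > 1)
    return("selectFraction must be in (0, 1]")
  TRUE
})

#' @param coverageLevel,readLength,contigMinLen,selectFraction,seed see slots.
#' @rdname SpikeDesign-class
#' @export
spikeDesign <- function(coverageLevel = 1, readLength = 45L,
                        contigMinLen = 2500L, selectFraction = 0.10,
                        seed = 1L) {
  new("SpikeDesign", coverageLevel = as.numeric(coverageLevel),
      readLength = as.integer(readLength),
      contigMinLen = as.integer(contigMinLen),
      selectFraction = as.numeric(selectFraction), seed = as.integer(seed))
}

#' Mapper adapter
#'
#' Describes how an external read mapper is invoked and how its output is
#' parsed. The command template may contain the placeholders
#' \code{{reads}}, \code{{reference}} and \code{{output}}. The special
#' adapter name \code{"precomputed"} bypasses execution and reads an
#' existing mapping file (the job's \code{mappingPath}); it is the adapter
#' used throughout the test suite and the validation study.
#'
#' @slot name adapter name; \code{"precomputed"} is special.
#' @slot command shell command template, empty for precomputed.
#' @slot parser one of \code{"blast8"}, \code{"sam"}.
#' @exportClass MapperAdapter
setClass("MapperAdapter",
  representation(name = "character", command = "character",
                 parser = "character"),
  prototype(name = "precomputed", command = "", parser = "blast8"))

setValidity("MapperAdapter", function(object) {
  if (!object@parser %in% c("blast8", "sam"))
    return("parser must be 'blast8' or 'sam'")
  if (object@name != "precomputed" && !nzchar(object@command))
    return("non-precomputed adapters need a command template")
  TRUE
})

#' @param name,command,parser see slots.
#' @rdname MapperAdapter-class
#' @export
mapperAdapter <- function(name = "precomputed", command = "",
                          parser = "blast8") {
  new("MapperAdapter", name = name, command = command, parser = parser)
}

#' Pipeline options
#'
#' The full per-job parameter set of the worker pipeline: pre-processing,
#' hit filtering, overlap rule, quantification toggles, mapper adapter and
#' log level. At least one of counts, coverage or keepMapping must be
#' enabled, otherwise the job would produce nothing. Disabling both counts
#' and coverage (with keepMapping on) turns the pipeline into a pure
#' parallel mapping framework: the quantification stage performs zero
#' array writes and no results file is produced.
#'
#' @slot qualityFilter apply the FASTQ quality filter.
#' @slot qfParams a \code{QualityFilterParams}.
#' @slot hitCriteria a \code{HitCriteria}.
#' @slot overlapRule an \code{OverlapRule}.
#' @slot counts compute per-region read counts.
#' @slot coverage compute per-region coverage statistics.
#' @slot keepMapping retain the mapper output next to the results.
#' @slot adapter a \code{MapperAdapter}.
#' @slot verbose verbose logging (per-stage record tallies).
#' @slot scratchDir scratch directory for intermediates; "" = per-job tempdir.
#' @exportClass PipelineOptions
setClass("PipelineOptions",
  representation(qualityFilter = "logical", qfParams = "QualityFilterParams",
                 hitCriteria = "HitCriteria", overlapRule = "OverlapRule",
                 counts = "logical", coverage = "logical",
                 keepMapping = "logical", adapter = "MapperAdapter",
                 verbose = "logical", scratchDir = "character"),
  prototype(qualityFilter = FALSE, counts = TRUE, coverage = TRUE,
            keepMapping = FALSE, verbose = FALSE, scratchDir = ""))

setValidity("PipelineOptions", function(object) {
  if (!object@counts && !object@coverage && !object@keepMapping)
    return(paste("at least one of counts, coverage or keepMapping must be",
                 "enabled; the job would produce nothing"))
  TRUE
})

#' @param qualityFilter,qfParams,hitCriteria,overlapRule,counts,coverage,keepMapping,adapter,verbose,scratchDir see slots.
#' @rdname PipelineOptions-class
#' @export
pipelineOptions <- function(qualityFilter = FALSE,
                            qfParams = qualityFilterParams(),
                            hitCriteria = metaquant::hitCriteria(),
                            overlapRule = metaquant::overlapRule(),
                            counts = TRUE, coverage = TRUE,
                            keepMapping = FALSE,
                            adapter = mapperAdapter(),
                            verbose = FALSE, scratchDir = "") {
  new("PipelineOptions", qualityFilter = qualityFilter, qfParams = qfParams,
      hitCriteria = hitCriteria, overlapRule = overlapRule,
      counts = counts, coverage = coverage, keepMapping = keepMapping,
      adapter = adapter, verbose = verbose, scratchDir = scratchDir)
}

setMethod("show", "PipelineOptions", function(object) {
  cat("PipelineOptions: adapter", object@adapter@name,
      sprintf("(%s)", object@adapter@parser),
      "| counts", object@counts, "| coverage", object@coverage,
      "| qualityFilter", object@qualityFilter,
      "| bestHitOnly", object@hitCriteria@bestHitOnly, "\n")
})

#' A unit of distributable work
#'
#' A job names the input files of one sample (reads, reference FASTA,
#' annotation table), the destination of its results table, and optionally
#' a precomputed mapping file for the \code{"precomputed"} adapter. The
#' master only ever transmits these paths; it never touches the data
#' files themselves.
#'
#' @slot jobId unique job identifier within a run.
#' @slot readsPath path to FASTA/FASTQ reads (optionally gzipped).
#' @slot referencePath path to the reference FASTA.
#' @slot annotationsPath path to the 5-column annotation table.
#' @slot outputPath destination for the results table.
#' @slot mappingPath optional precomputed mapping file ("" if unused).
#' @exportClass Job
setClass("Job",
  representation(jobId = "character", readsPath = "character",
                 referencePath = "character", annotationsPath = "character",
                 outputPath = "character", mappingPath = "character"),
  prototype(mappingPath = ""))

setValidity("Job", function(object) {
  need <- c(jobId = object@jobId, reads = object@readsPath,
            reference = object@referencePath,
            annotations = object@annotationsPath,
            output = object@outputPath)
  bad <- names(need)[!nzchar(need)]
  if (length(bad)) return(paste("empty job field(s):",
                                paste(bad, collapse = ", ")))
  TRUE
})

#' @param jobId,readsPath,referencePath,annotationsPath,outputPath,mappingPath see slots.
#' @rdname Job-class
#' @export
job <- function(jobId, readsPath, referencePath, annotationsPath,
                outputPath, mappingPath = "") {
  new("Job", jobId = jobId, readsPath = readsPath,
      referencePath = referencePath, annotationsPath = annotationsPath,
      outputPath = outputPath, mappingPath = mappingPath)
}

setMethod("show", "Job", function(object) {
  cat("Job", object@jobId, "\n  reads:      ", object@readsPath,
      "\n  reference:  ", object@referencePath,
      "\n  annotations:", object@annotationsPath,
      "\n  output:     ", object@outputPath, "\n")
  if (nzchar(object@mappingPath))
    cat("  mapping:    ", object@mappingPath, "\n")
})
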