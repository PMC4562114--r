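#' Generate random contigs with whole-contig annotations
#'
#' Emits \code{n} uniform-random A/C/G/T sequences with lengths drawn
#' uniformly from \code{lengthRange}, as a FASTA file, plus one
#' whole-contig annotation per contig (strand "+", label
#' \code{<id>_region}) in the 5-column annotation format. A stand-in for
#' assembled metagenome contigs; reproducible from \code{seed}.
#'
#' @param n number of contigs.
#' @param lengthRange length-2 vector, min and max contig length.
#' @param seed random seed.
#' @param fastaPath,annotationsPath output paths.
#' @return invisibly, data.frame with \code{id} and \code{length}.
#' @export
generateContigs <- function(n, lengthRange = c(2500L, 10000L), seed = 1L,
                            fastaPath, annotationsPath) {
  stopifnot(n >= 1L, lengthRange[1] >= 1L,
            lengthRange[1] <= lengthRange[2])
  set.seed(seed)
  lens <- as.integer(round(runif(n, lengthRange[1], lengthRange[2])))
  ids <- sprintf("contig%04d", seq_len(n))
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), "")
  writeFasta(data.frame(id = ids, sequence = seqs,
                        stringsAsFactors = FALSE), fastaPath)
  writeAnnotations(data.frame(ref_id = ids, start = 0L, end = lens,
                              strand = "+",
                              label = paste0(ids, "_region"),
                              stringsAsFactors = FALSE), annotationsPath)
  invisible(data.frame(id = ids, length = lens, stringsAsFactors = FALSE))
}

#' Spike a contig set with artificial reads of known coverage
#'
#' Reproduces the spiking procedure of the validation study: among the
#' contigs at least \code{design@contigMinLen} long, a fraction
#' \code{design@selectFraction} is selected at random (or the caller
#' supplies \code{selectedIds}); each selected contig of length L is
#' fragmented into \code{round(C * L / readLength)} error-free reads of
#' fixed length at start positions drawn uniformly (with replacement)
#' from [0, L - readLength], i.e. fully inside the contig. Reads are
#' written as FASTQ with constant Q40 qualities; the ground-truth mapping
#' is written in the blast8 dialect with 100 percent identity and the
#' true coordinates; a truth table records the per-contig theoretical
#' coverage C.
#'
#' @param contigsFasta FASTA of contigs (e.g. from
#'   \code{\link{generateContigs}}).
#' @param design a \code{\link{spikeDesign}} object.
#' @param readsPath output FASTQ path.
#' @param mappingPath output ground-truth blast8 path.
#' @param truthPath output truth-table TSV path (contig_id, length,
#'   coverage_level, n_reads).
#' @param selectedIds optional explicit contig selection, overriding the
#'   random draw (used to spike one selection at several levels).
#' @return invisibly, the truth table data.frame.
#' @export
spikeReads <- function(contigsFasta, design, readsPath, mappingPath,
                       truthPath, selectedIds = NULL) {
  stopifnot(is(design, "SpikeDesign"))
  rl <- design@readLength
  contigs <- Biostrings::readDNAStringSet(contigsFasta)
  names(contigs) <- vapply(strsplit(names(contigs), "\\s+"), `[[`, "", 1L)
  lens <- Biostrings::width(contigs)
  set.seed(design@seed)
  if (is.null(selectedIds)) {
    eligible <- which(lens >= max(design@contigMinLen, rl))
    short <- sum(lens < rl)
    if (short)
      logEvent("verbose", "spike",
               sprintf("excluded %d contig(s) shorter than one read",
                       short))
    if (!length(eligible))
      stop("no contig is eligible for spiking (min length ",
           design@contigMinLen, ")")
    nSel <- max(1L, as.integer(round(design@selectFraction *
                                       length(eligible))))
    selectedIds <- names(contigs)[sort(sample(eligible, nSel))]
  } else {
    bad <- setdiff(selectedIds, names(contigs))
    if (length(bad)) stop("unknown contig id(s): ",
                          paste(bad, collapse = ", "))
    if (any(lens[match(selectedIds, names(contigs))] < rl))
      stop("selected contig shorter than one read")
  }

  C <- design@coverageLevel
  allIds <- allSeqs <- allRefs <- character(0)
  allStarts <- integer(0)
  truth <- data.frame(contig_id = character(0), length = integer(0),
                      coverage_level = numeric(0), n_reads = integer(0),
                      stringsAsFactors = FALSE)
  perContig <- vector("list", length(selectedIds))
  for (k in seq_along(selectedIds)) {
    id <- selectedIds[k]
    L <- lens[match(id, names(contigs))]
    nReads <- as.integer(round(C * L / rl))
    starts <- if (nReads)
      sample.int(L - rl + 1L, nReads, replace = TRUE) - 1L else integer(0)
    seqStr <- as.character(contigs[[id]])
    perContig[[k]] <- list(
      ids = sprintf("%s_read%07d", id, seq_len(nReads)),
      seqs = substring(seqStr, starts + 1L, starts + rl),
      starts = starts, ref = id)
    truth <- rbind(truth, data.frame(contig_id = id, length = L,
                                     coverage_level = C, n_reads = nReads,
                                     stringsAsFactors = FALSE))
  }
  allIds <- unlist(lapply(perContig, `[[`, "ids"))
  allSeqs <- unlist(lapply(perContig, `[[`, "seqs"))
  allStarts <- unlist(lapply(perContig, `[[`, "starts"))
  allRefs <- rep(vapply(perContig, `[[`, "", "ref"),
                 vapply(perContig, function(x) length(x$ids), 0L))

  qual <- strrep(rawToChar(as.raw(40L + 33L)), rl)  # constant Q40
  writeFastq(data.frame(id = allIds, sequence = allSeqs,
                        quality = qual, stringsAsFactors = FALSE),
             readsPath)
  writeBlast8(makeHits(allIds, allRefs, allStarts, allStarts + rl,
                       identity_pct = 100, aln_len = rl), mappingPath)
  data.table::fwrite(truth, truthPath, sep = "\t")
  invisible(truth)
}

#' Coverage-accuracy validation study
#'
#' Reproduces the spiking validation: per replicate, generate a fresh
#' random contig set, select the spiking fraction once, spike the
#' selected contigs at every requested coverage level, run the full
#' quantification pipeline with the precomputed-mapping adapter, and
#' measure per selected contig the relative deviation of the estimated
#' median coverage from the theoretical level C,
#' |median - C| / C * 100 (percent). Reported per level: the mean
#' deviation over all spiked contigs (across replicates) and its
#' standard error over contigs.
#'
#' @param levels coverage levels C to spike at.
#' @param nContigs contigs per replicate.
#' @param lengthRange contig length range in bases.
#' @param readLength spiked read length in bases.
#' @param contigMinLen minimum contig length eligible for spiking.
#' @param selectFraction fraction of eligible contigs spiked.
#' @param replicates number of independently generated contig sets.
#' @param seed master seed; all sub-seeds derive from it.
#' @param workDir working directory for the generated files (created;
#'   caller-owned).
#' @param options pipeline options; the adapter must be "precomputed".
#' @return data.frame with one row per level: \code{level},
#'   \code{mean_deviation_pct}, \code{se_pct}, \code{n_contigs}.
#' @export
validationStudy <- function(levels = c(1, 10, 100, 1000), nContigs = 100L,
                            lengthRange = c(2500L, 10000L),
                            readLength = 45L, contigMinLen = 2500L,
                            selectFraction = 0.10, replicates = 3L,
                            seed = 1L, workDir = tempfile("mq-validate-"),
                            options = pipelineOptions()) {
  stopifnot(options@adapter@name == "precomputed")
  dir.create(workDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  subSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                replicates * (length(levels) + 2L)),
                     nrow = replicates)
  devs <- setNames(vector("list", length(levels)), as.character(levels))
  for (rep in seq_len(replicates)) {
    fasta <- file.path(workDir, sprintf("contigs-r%d.fasta", rep))
    anns <- file.path(workDir, sprintf("annotations-r%d.tsv", rep))
    contigs <- generateContigs(nContigs, lengthRange,
                               seed = subSeeds[rep, 1L], fasta, anns)
    ## one selection per replicate, shared across levels
    set.seed(subSeeds[rep, 2L])
    eligible <- contigs$id[contigs$length >= max(contigMinLen, readLength)]
    nSel <- max(1L, as.integer(round(selectFraction * length(eligible))))
    selected <- sort(sample(eligible, nSel))
    for (li in seq_along(levels)) {
      C <- levels[li]
      tag <- sprintf("r%d-c%g", rep, C)
      reads <- file.path(workDir, sprintf("reads-%s.fastq", tag))
      mapping <- file.path(workDir, sprintf("mapping-%s.blast8", tag))
      truthF <- file.path(workDir, sprintf("truth-%s.tsv", tag))
      out <- file.path(workDir, sprintf("results-%s.tsv", tag))
      design <- spikeDesign(coverageLevel = C, readLength = readLength,
                            contigMinLen = contigMinLen,
                            selectFraction = selectFraction,
                            seed = subSeeds[rep, li + 2L])
      spikeReads(fasta, design, reads, mapping, truthF,
                 selectedIds = selected)
      j <- job(jobId = tag, readsPath = reads, referencePath = fasta,
               annotationsPath = anns, outputPath = out,
               mappingPath = mapping)
      runJob(j, options)
      res <- readResults(out)
      med <- res$median_cov[match(selected, res$ref_id)]
      devs[[as.character(C)]] <-
        c(devs[[as.character(C)]], abs(med - C) / C * 100)
    }
  }
  data.frame(
    level = levels,
    mean_deviation_pct = vapply(as.character(levels),
                                function(k) mean(devs[[k]]), 0),
    se_pct = vapply(as.character(levels), function(k)
      stats::sd(devs[[k]]) / sqrt(length(devs[[k]])), 0),
    n_contigs = vapply(as.character(levels),
                       function(k) length(devs[[k]]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
}
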