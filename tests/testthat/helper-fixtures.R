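## shared fixture builders; everything is generated in code at test time

hitsDF <- metaquant:::makeHits

randomHits <- function(n, refLengths, maxLen = 60L, nQueries = n) {
  refs <- sample(names(refLengths), n, replace = TRUE)
  lens <- unname(refLengths[refs])
  w <- pmin(sample.int(maxLen, n, replace = TRUE), lens)
  s <- vapply(seq_len(n), function(i)
    sample.int(lens[i] - w[i] + 1L, 1L) - 1L, 0L)
  hitsDF(query_id = sprintf("q%03d", sample.int(nQueries, n, replace = TRUE)),
         ref_id = refs, ref_start = s, ref_end = s + w,
         identity_pct = round(runif(n, 60, 100), 2),
         aln_len = w)
}

randomRefs <- function(nRefs, maxLen = 500L, minLen = 50L) {
  lens <- sample(minLen:maxLen, nRefs, replace = TRUE)
  names(lens) <- sprintf("ref%02d", seq_len(nRefs))
  lens
}

randomAnnotations <- function(nAnn, refLengths) {
  refs <- sample(names(refLengths), nAnn, replace = TRUE)
  lens <- unname(refLengths[refs])
  s <- vapply(lens, function(L) sample.int(L, 1L) - 1L, 0L)
  e <- vapply(seq_len(nAnn), function(i)
    s[i] + sample.int(lens[i] - s[i], 1L), 0L)
  data.frame(ref_id = refs, start = as.integer(s), end = as.integer(e),
             strand = sample(c("+", "-", "."), nAnn, replace = TRUE),
             label = sprintf("region%03d", seq_len(nAnn)),
             stringsAsFactors = FALSE)
}

## brute-force per-base coverage oracle, independent of both package routes
bruteCoverage <- function(hits, refLengths) {
  depth <- lapply(refLengths, function(L) integer(L))
  for (i in seq_len(nrow(hits))) {
    r <- hits$ref_id[i]
    if (!r %in% names(depth)) next
    s <- max(hits$ref_start[i], 0L)
    e <- min(hits$ref_end[i], length(depth[[r]]))
    if (e > s) for (p in (s + 1L):e) depth[[r]][p] <- depth[[r]][p] + 1L
  }
  depth
}

## a tiny complete job fixture: contigs, annotations, one spiked read set
makeSyntheticJob <- function(dir, seed = 1L, coverage = 2, nContigs = 6L,
                             lengthRange = c(300L, 800L), readLength = 45L,
                             tag = "fix") {
  fasta <- file.path(dir, paste0(tag, "-contigs.fasta"))
  anns <- file.path(dir, paste0(tag, "-annotations.tsv"))
  generateContigs(nContigs, lengthRange, seed = seed, fasta, anns)
  d <- spikeDesign(coverageLevel = coverage, readLength = readLength,
                   contigMinLen = lengthRange[1], selectFraction = 0.5,
                   seed = seed + 1L)
  reads <- file.path(dir, paste0(tag, "-reads.fastq"))
  mapping <- file.path(dir, paste0(tag, "-mapping.blast8"))
  truth <- file.path(dir, paste0(tag, "-truth.tsv"))
  tt <- spikeReads(fasta, d, reads, mapping, truth)
  list(job = job(paste0("job-", tag), reads, fasta, anns,
                 file.path(dir, paste0(tag, "-results.tsv")), mapping),
       truth = tt, fasta = fasta, annotations = anns, mapping = mapping,
       reads = reads)
}

## fork local workers, serve the queue, collect; returns the run summary
runDMW <- function(jobs, workers, executor, retryLimit = 3L,
                   heartbeatTimeout = 60) {
  endpoint <- sprintf("tcp://127.0.0.1:%d", freePort())
  pids <- lapply(seq_len(workers), function(i)
    parallel::mcparallel(workerLoop(endpoint, executor,
                                    workerId = sprintf("w%d", i)),
                         silent = TRUE))
  on.exit(suppressWarnings(parallel::mccollect(pids, wait = TRUE)))
  masterServe(jobs, endpoint, retryLimit = retryLimit,
              heartbeatTimeout = heartbeatTimeout,
              expectedWorkers = workers)
}

## jobs whose executor just appends a line to the output file
touchJobs <- function(dir, n) {
  lapply(seq_len(n), function(i)
    job(sprintf("t%02d", i), readsPath = file.path(dir, "in"),
        referencePath = file.path(dir, "in"),
        annotationsPath = file.path(dir, "in"),
        outputPath = file.path(dir, sprintf("out-%02d", i))))
}

touchExecutor <- function(j) {
  cat(j@jobId, "\n", sep = "", file = j@outputPath, append = TRUE)
}
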