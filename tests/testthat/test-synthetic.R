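test_that("contig generation is exact, annotated and seed-deterministic", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta"); an <- file.path(dir, "a.tsv")
  info <- generateContigs(5L, c(2500L, 2500L), seed = 3L, fa, an)
  expect_equal(info$length, rep(2500L, 5))
  seqs <- readSequences(fa)
  expect_equal(nchar(seqs$sequence), rep(2500L, 5))
  anns <- readAnnotations(an)
  expect_equal(nrow(anns), 5L)
  expect_equal(anns$start, rep(0L, 5))
  expect_equal(anns$end, rep(2500L, 5))

  fa2 <- file.path(dir, "c2.fasta"); an2 <- file.path(dir, "a2.tsv")
  generateContigs(5L, c(2500L, 2500L), seed = 3L, fa2, an2)
  expect_identical(readLines(fa), readLines(fa2))
  expect_identical(readLines(an), readLines(an2))
})

test_that("generated base composition is unbiased (binomial check)", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta"); an <- file.path(dir, "a.tsv")
  generateContigs(100L, c(10000L, 10000L), seed = 12L, fa, an)
  seqs <- paste(readSequences(fa)$sequence, collapse = "")
  nBases <- nchar(seqs)
  expect_equal(nBases, 1e6)
  gc <- sum(strsplit(seqs, "")[[1]] %in% c("G", "C")) / nBases
  se <- sqrt(0.5 * 0.5 / nBases)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("spiking emits round(C*L/readLength) reads of conserved mass", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta"); an <- file.path(dir, "a.tsv")
  generateContigs(1L, c(2500L, 2500L), seed = 4L, fa, an)
  d <- spikeDesign(coverageLevel = 10, readLength = 45L, seed = 5L,
                   selectFraction = 1)
  rd <- file.path(dir, "r.fastq"); mp <- file.path(dir, "m.blast8")
  tr <- file.path(dir, "t.tsv")
  truth <- spikeReads(fa, d, rd, mp, tr)
  expect_equal(truth$n_reads, 556L)        # round(10 * 2500 / 45)

  hits <- parseBlast8(mp)
  expect_equal(nrow(hits), 556L)
  expect_equal(sum(hits$ref_end - hits$ref_start), 556L * 45L)

  reads <- readSequences(rd)
  expect_equal(nrow(reads), 556L)
  expect_equal(unique(nchar(reads$sequence)), 45L)
  expect_equal(unique(reads$quality), strrep("I", 45))  # constant Q40

  # every read is the exact substring its ground-truth coordinates claim
  contig <- readSequences(fa)$sequence[1]
  expect_identical(reads$sequence,
                   substring(contig, hits$ref_start + 1L, hits$ref_end))

  # reads fall fully inside the contig
  expect_true(all(hits$ref_start >= 0L & hits$ref_end <= 2500L))

  # seed determinism of the whole spike
  rd2 <- file.path(dir, "r2.fastq"); mp2 <- file.path(dir, "m2.blast8")
  tr2 <- file.path(dir, "t2.tsv")
  spikeReads(fa, d, rd2, mp2, tr2)
  expect_identical(readLines(rd), readLines(rd2))
  expect_identical(readLines(mp), readLines(mp2))
})

test_that("ground-truth coverage has interior mean depth near C", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta"); an <- file.path(dir, "a.tsv")
  generateContigs(3L, c(3000L, 6000L), seed = 14L, fa, an)
  rl <- 45L
  d <- spikeDesign(coverageLevel = 10, readLength = rl, seed = 15L,
                   contigMinLen = 2500L, selectFraction = 1)
  rd <- file.path(dir, "r.fastq"); mp <- file.path(dir, "m.blast8")
  tr <- file.path(dir, "t.tsv")
  truth <- spikeReads(fa, d, rd, mp, tr)
  cov <- buildCoverage(parseBlast8(mp), referenceLengths(fa))
  for (i in seq_len(nrow(truth))) {
    L <- truth$length[i]
    depth <- coverageDepth(cov, truth$contig_id[i])
    interior <- depth[rl:(L - rl)]
    p <- rl / (L - rl + 1)
    sdSlot <- sqrt(truth$n_reads[i] * p * (1 - p))
    nEff <- length(interior) / rl    # ~independent blocks of one read length
    expect_lt(abs(mean(interior) - 10), 3 * sdSlot / sqrt(nEff) + 0.2)
  }
})

test_that("the median estimate converges to the interior expectation", {
  # law-of-large-numbers check: with reads placed fully inside the contig
  # the interior expectation is mu = nReads*rl/(L-rl+1); the median's
  # relative deviation from mu shrinks as the spiking level grows
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "c.fasta"); an <- file.path(dir, "a.tsv")
  generateContigs(1L, c(2500L, 2500L), seed = 16L, fa, an)
  rl <- 45L
  relDev <- vapply(c(10, 1e4), function(C) {
    d <- spikeDesign(coverageLevel = C, readLength = rl, seed = 17L,
                     selectFraction = 1)
    mp <- file.path(dir, sprintf("m-%g.blast8", C))
    spikeReads(fa, d, file.path(dir, sprintf("r-%g.fastq", C)), mp,
               file.path(dir, sprintf("t-%g.tsv", C)))
    cov <- buildCoverage(parseBlast8(mp), referenceLengths(fa))
    ann <- readAnnotations(an)
    med <- regionStatistics(cov, ann)$median_cov[1]
    nReads <- round(C * 2500 / rl)
    mu <- nReads * rl / (2500 - rl + 1)
    abs(med - mu) / mu
  }, 0)
  expect_lt(relDev[2], relDev[1])
})

test_that("the validation study reports per-level deviations with errors", {
  # miniature version of the full study to exercise the driver itself
  study <- validationStudy(levels = c(1, 10), nContigs = 20L,
                           lengthRange = c(2500L, 4000L), replicates = 2L,
                           seed = 99L, workDir = withr::local_tempdir())
  expect_equal(study$level, c(1, 10))
  expect_equal(study$n_contigs, rep(4L, 2))  # 2 selected x 2 replicates
  expect_true(all(study$mean_deviation_pct >= 0))
  expect_true(all(is.finite(study$se_pct)))
  # byte-level reproducibility of the whole study from the master seed
  study2 <- validationStudy(levels = c(1, 10), nContigs = 20L,
                            lengthRange = c(2500L, 4000L), replicates = 2L,
                            seed = 99L, workDir = withr::local_tempdir())
  expect_identical(study, study2)
})
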