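test_that("FASTA parsing yields records without qualities, gzip transparent", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">readA some description", "ACGTACGT", "ACGT",
               ">readB", "TTTT"), fa)
  recs <- readSequences(fa, format = "fasta")
  expect_equal(recs$id, c("readA", "readB"))
  expect_equal(recs$sequence, c("ACGTACGTACGT", "TTTT"))
  expect_true(all(is.na(recs$quality)))

  gz <- withr::local_tempfile(fileext = ".fasta.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(fa), con)
  close(con)
  expect_equal(readSequences(gz), recs)  # auto-detected format + gzip
})

test_that("FASTQ round-trips through write and stream", {
  set.seed(42)
  n <- 120L
  reads <- data.frame(
    id = sprintf("r%03d", 1:n),
    sequence = vapply(sample(20:70, n, TRUE), function(L)
      paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""), ""),
    stringsAsFactors = FALSE)
  reads$quality <- vapply(nchar(reads$sequence), function(L)
    rawToChar(as.raw(sample(33:73, L, TRUE))), "")
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(reads, fq)
  expect_equal(readSequences(fq), reads, ignore_attr = TRUE)

  # chunked streaming preserves order and content
  s <- streamReads(fq, chunkSize = 7L)
  got <- list()
  repeat {
    ch <- s$nextChunk()
    if (is.null(ch)) break
    expect_lte(nrow(ch), 7L)
    got[[length(got) + 1L]] <- ch
  }
  expect_equal(do.call(rbind, got), reads, ignore_attr = TRUE)
})

test_that("malformed FASTQ is reported with record and line number", {
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@ok", "ACGT", "+", "IIII",
               "@bad", "ACGTACGT", "+", "III"), fq)
  expect_error(readSequences(fq), "bad.*line 5|line 5.*bad")
  writeLines(c("@only", "ACGT", "+"), fq)
  expect_error(readSequences(fq), "truncated")
})

test_that("annotation coordinates are normalized and round-trip", {
  an <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "contig1\t1\t45\t+\tgeneA",
               "contig1\t10\t10\t-\tgeneB"), an)
  a <- readAnnotations(an)
  expect_equal(a$start, c(0L, 9L))
  expect_equal(a$end, c(45L, 10L))
  expect_equal(a$strand, c("+", "-"))
  expect_equal(a$label, c("geneA", "geneB"))

  set.seed(7)
  refs <- randomRefs(5L)
  big <- randomAnnotations(100L, refs)
  writeAnnotations(big, an)
  expect_equal(readAnnotations(an), big, ignore_attr = TRUE)
})

test_that("annotation parse errors name the offending line", {
  an <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t1\t10\t+\tg1", "c1\t5\t3\t+\tg2"), an)
  expect_error(readAnnotations(an), "line 2.*start")
  writeLines(c("c1\t1\t10\t+"), an)
  expect_error(readAnnotations(an), "line 1.*5 tab-separated")
  writeLines(c("c1\tone\t10\t+\tg1"), an)
  expect_error(readAnnotations(an), "line 1.*non-integer")
  writeLines(c("c1\t1\t10\t?\tg1"), an)
  expect_error(readAnnotations(an), "strand")
})

test_that("blast8 parsing normalizes intervals and assigns file order", {
  b8 <- withr::local_tempfile(fileext = ".blast8")
  writeLines(c(
    "q1\tr1\t100.00\t45\t0\t0\t1\t45\t10\t54\t1e-20\t90.0",
    "q2\tr1\t95.50\t45\t2\t0\t1\t45\t54\t10\t1e-18\t85.0"), b8)
  h <- parseBlast8(b8)
  expect_equal(h$ref_start, c(9L, 9L))       # reverse hit normalized
  expect_equal(h$ref_end, c(54L, 54L))
  expect_equal(h$identity_pct, c(100, 95.5))
  expect_equal(h$aln_len, c(45L, 45L))
  expect_equal(h$file_order, c(0L, 1L))
})

test_that("blast8 malformed-line policy skips by default, aborts when strict", {
  b8 <- withr::local_tempfile(fileext = ".blast8")
  writeLines(c(
    "q1\tr1\t100.00\t45\t0\t0\t1\t45\t10\t54\t1e-20\t90.0",
    "q2\tr1\tnot_a_number\t45\t0\t0\t1\t45\t1\t45\t1e-20\t90.0"), b8)
  h <- parseBlast8(b8)
  expect_equal(nrow(h), 1L)
  expect_equal(h$file_order, 0L)
  expect_error(parseBlast8(b8, policy = "strict"), "line 2")
})

test_that("blast8 write/parse round-trips the quantified fields", {
  set.seed(11)
  refs <- randomRefs(3L, maxLen = 400L)
  h <- randomHits(200L, refs)
  b8 <- withr::local_tempfile(fileext = ".blast8")
  writeBlast8(h, b8)
  back <- parseBlast8(b8)
  expect_equal(back$query_id, h$query_id)
  expect_equal(back$ref_start, h$ref_start)
  expect_equal(back$ref_end, h$ref_end)
  expect_equal(back$aln_len, h$aln_len)
  expect_equal(back$identity_pct, h$identity_pct, tolerance = 1e-8)
  expect_equal(back$file_order, h$file_order)
})

test_that("SAM parsing handles CIGAR arithmetic, flags and NM identity", {
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:r1\tLN:1000",
    "q1\t0\tr1\t10\t60\t45M\t*\t0\t0\tA\tI\tNM:i:0",
    "q2\t4\t*\t0\t0\t*\t*\t0\t0\tA\tI",               # unmapped: skipped
    "q3\t0\tr1\t10\t60\t20M5I20M2D5M\t*\t0\t0\tA\tI\tNM:i:5",
    "q4\t0\tr1\t5\t60\t*\t*\t0\t0\tA\tI",             # mapped, CIGAR *: skipped
    "q5\t16\tr1\t100\t60\t45M\t*\t0\t0\tA\tI\tNM:i:9"), sam)
  h <- parseSam(sam)
  expect_equal(h$query_id, c("q1", "q3", "q5"))
  expect_equal(h$ref_start, c(9L, 9L, 99L))
  # 20M5I20M2D5M consumes 20+20+2+5 = 47 reference bases
  expect_equal(h$ref_end, c(54L, 56L, 144L))
  expect_equal(h$file_order, 0:2)
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$identity_pct[2], 100 * (1 - 5 / 52))  # 52 aln columns
  expect_equal(h$identity_pct[3], 80)
})

test_that("equivalent alignments in blast8 and SAM give identical intervals", {
  set.seed(5)
  n <- 50L
  starts <- sample.int(900L, n) - 1L
  w <- sample(30:60, n, TRUE)
  h <- hitsDF(sprintf("q%02d", 1:n), "r1", starts, starts + w,
              identity_pct = 100, aln_len = w)
  b8 <- withr::local_tempfile(); sam <- withr::local_tempfile()
  writeBlast8(h, b8)
  writeLines(c("@SQ\tSN:r1\tLN:1000",
               sprintf("q%02d\t0\tr1\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       1:n, starts + 1L, w)), sam)
  hb <- parseBlast8(b8)
  hs <- parseSam(sam)
  expect_equal(hb[, c("query_id", "ref_id", "ref_start", "ref_end")],
               hs[, c("query_id", "ref_id", "ref_start", "ref_end")])
})

test_that("results tables round-trip at 4-decimal precision", {
  out <- withr::local_tempfile(fileext = ".tsv")
  writeResults(regionStatistics(NULL, metaquant:::emptyAnnotations(),
                                NULL), out)
  expect_equal(length(readLines(out)), 1L)      # header-only
  expect_true(startsWith(readLines(out)[1], "#"))

  ann <- data.frame(ref_id = "c1", start = 0L, end = 100L, strand = "+",
                    label = "g1", stringsAsFactors = FALSE)
  cov <- buildCoverage(hitsDF(c("a", "b"), "c1", c(0, 0), c(100, 100),
                              100, 100), c(c1 = 100L))
  res <- regionStatistics(cov, ann, counts = 3L)
  writeResults(res, out)
  row <- readLines(out)[2]
  expect_equal(row, "c1\t1\t100\t+\tg1\t3\t2.0000\t2.0000\t0.0000")

  set.seed(9)
  refs <- randomRefs(4L)
  anns <- randomAnnotations(50L, refs)
  cov <- buildCoverage(randomHits(300L, refs), refs)
  res <- regionStatistics(cov, anns, counts = sample.int(50L, 50L, TRUE))
  writeResults(res, out)
  back <- readResults(out)
  for (col in c("median_cov", "mean_cov", "sd_cov"))
    expect_equal(back[[col]], round(res[[col]], 4))
  expect_equal(back$count, res$count)
  expect_equal(back[, 1:5], res[, 1:5], ignore_attr = TRUE)
})
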