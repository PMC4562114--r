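test_that("difference-array coverage handles empty and single-hit cases", {
  refs <- c(r1 = 100L)
  cov0 <- buildCoverage(hitsDF(character(0), character(0), integer(0),
                               integer(0), numeric(0), integer(0)), refs)
  expect_equal(coverageDepth(cov0, "r1"), integer(100))

  cov1 <- buildCoverage(hitsDF("q1", "r1", 0L, 45L, 100, 45L), refs)
  d <- coverageDepth(cov1, "r1")
  expect_equal(d[1:45], rep(1L, 45))
  expect_equal(d[46:100], rep(0L, 55))
  expect_equal(totalCoverage(cov1), 45)

  # overlapping hits add up
  cov2 <- buildCoverage(hitsDF(c("a", "b"), "r1", c(0L, 5L), c(10L, 15L),
                               100, c(10L, 10L)), refs)
  d2 <- coverageDepth(cov2, "r1")
  expect_equal(d2[1:5], rep(1L, 5))
  expect_equal(d2[6:10], rep(2L, 5))
  expect_equal(d2[11:15], rep(1L, 5))
})

test_that("difference-array and naive coverage agree on random instances", {
  for (seed in 1:30) {
    set.seed(seed)
    refs <- randomRefs(sample(1:3, 1))
    h <- randomHits(sample(50:300, 1), refs)
    fast <- buildCoverage(h, refs)
    slow <- naiveCoverage(h, refs)
    expect_identical(coverageDepth(fast), coverageDepth(slow))
    expect_identical(coverageDepth(fast), bruteCoverage(h, refs))
    # conservation: coverage mass equals summed interval lengths, exactly
    expect_identical(totalCoverage(fast),
                     sum(as.double(h$ref_end - h$ref_start)))
  }
})

test_that("hits past a reference end are clipped, unknown references obey policy", {
  refs <- c(r1 = 50L)
  h <- hitsDF(c("a", "b"), c("r1", "rX"), c(30L, 0L), c(70L, 10L), 100,
              c(40L, 10L))
  cov <- buildCoverage(h, refs)            # default: skip unknown, clip
  expect_equal(totalCoverage(cov), 20)     # [30,50) after clipping
  expect_equal(cov@clipped, 1L)
  expect_error(buildCoverage(h, refs, policy = "abort"), "rX")
})

test_that("instrumented write counts witness O(n+N) vs O(n+N*M)", {
  n <- 2000L
  refs <- c(r1 = n)
  N <- 200L
  writesFast <- writesSlow <- numeric(0)
  for (M in c(10L, 100L, 1000L)) {
    set.seed(M)
    s <- sample.int(n - M, N, replace = TRUE) - 1L
    h <- hitsDF(sprintf("q%d", 1:N), "r1", s, s + M, 100, M)
    writesFast <- c(writesFast, coverageWrites(buildCoverage(h, refs)))
    writesSlow <- c(writesSlow, coverageWrites(naiveCoverage(h, refs)))
  }
  # difference array: exactly 2N + n writes, independent of M
  expect_equal(writesFast, rep(2 * N + n, 3))
  # naive: exactly N*M increments, growing 100x from M=10 to M=1000
  expect_equal(writesSlow, as.numeric(N * c(10L, 100L, 1000L)))
  expect_gte(writesSlow[3] / writesSlow[1], 50)
})

test_that("read counting honours the overlap rule", {
  ann <- data.frame(ref_id = c("r1", "r1"), start = c(0L, 60L),
                    end = c(45L, 90L), strand = "+",
                    label = c("gA", "gB"), stringsAsFactors = FALSE)
  h <- hitsDF("q1", "r1", 9L, 54L, 100, 45L)
  expect_equal(countReads(h, ann, overlapRule(1L)), c(1L, 0L))
  # overlap with gA is 36 bases: a 40-base minimum rejects it
  expect_equal(countReads(h, ann, overlapRule(40L)), c(0L, 0L))
  # fractional rule: 36/45 = 0.8 of the hit lies inside gA
  expect_equal(countReads(h, ann, overlapRule(1L, 0.8)), c(1L, 0L))
  expect_equal(countReads(h, ann, overlapRule(1L, 0.81)), c(0L, 0L))
})

test_that("read counting matches a brute-force all-pairs oracle", {
  set.seed(31)
  refs <- randomRefs(3L)
  h <- randomHits(300L, refs)
  ann <- randomAnnotations(30L, refs)
  rule <- overlapRule(minOverlapBases = 5L, minOverlapFrac = 0.5)
  counts <- countReads(h, ann, rule)
  oracle <- integer(nrow(ann))
  for (a in seq_len(nrow(ann))) for (i in seq_len(nrow(h))) {
    if (h$ref_id[i] != ann$ref_id[a]) next
    ov <- min(h$ref_end[i], ann$end[a]) - max(h$ref_start[i], ann$start[a])
    if (ov >= 5L && ov / (h$ref_end[i] - h$ref_start[i]) >= 0.5)
      oracle[a] <- oracle[a] + 1L
  }
  expect_identical(counts, oracle)
})

test_that("region statistics are median/mean/population-sd over the slots", {
  refs <- c(r1 = 100L)
  ann <- data.frame(ref_id = "r1", start = 0L, end = 100L, strand = "+",
                    label = "g", stringsAsFactors = FALSE)
  unif <- buildCoverage(hitsDF(c("a", "b"), "r1", 0L, 100L, 100, 100L),
                        refs)
  r <- regionStatistics(unif, ann, counts = 2L)
  expect_equal(c(r$median_cov, r$mean_cov, r$sd_cov), c(2, 2, 0))

  half <- buildCoverage(hitsDF("a", "r1", 0L, 50L, 100, 50L), refs)
  r2 <- regionStatistics(half, ann)
  expect_equal(c(r2$median_cov, r2$mean_cov, r2$sd_cov), c(0.5, 0.5, 0.5))
  expect_true(is.na(r2$count))

  bad <- data.frame(ref_id = "r1", start = 50L, end = 101L, strand = "+",
                    label = "overhang", stringsAsFactors = FALSE)
  expect_error(regionStatistics(unif, bad), "overhang")
})

test_that("region statistics agree with stats:: routines on random regions", {
  set.seed(41)
  refs <- randomRefs(3L)
  cov <- buildCoverage(randomHits(400L, refs), refs)
  ann <- randomAnnotations(50L, refs)
  res <- regionStatistics(cov, ann, counts = NULL)
  for (i in seq_len(nrow(ann))) {
    x <- coverageDepth(cov, ann$ref_id[i])[(ann$start[i] + 1):ann$end[i]]
    expect_equal(res$median_cov[i], stats::median(x))
    expect_equal(res$mean_cov[i], mean(x))
    n <- length(x)
    popSd <- if (n == 1L) 0 else stats::sd(x) * sqrt((n - 1) / n)
    expect_equal(res$sd_cov[i], popSd)
  }
})

test_that("adding a hit never decreases depth, counts or region means", {
  for (seed in 1:5) {
    set.seed(seed)
    refs <- randomRefs(2L)
    h <- randomHits(80L, refs)
    ann <- randomAnnotations(10L, refs)
    extra <- randomHits(1L, refs)
    extra$file_order <- max(h$file_order) + 1L
    h2 <- rbind(h, extra)
    d1 <- coverageDepth(buildCoverage(h, refs))
    d2 <- coverageDepth(buildCoverage(h2, refs))
    for (r in names(refs)) expect_true(all(d2[[r]] >= d1[[r]]))
    expect_true(all(countReads(h2, ann) >= countReads(h, ann)))
    m1 <- regionStatistics(buildCoverage(h, refs), ann)$mean_cov
    m2 <- regionStatistics(buildCoverage(h2, refs), ann)$mean_cov
    expect_true(all(m2 >= m1))
  }
})
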