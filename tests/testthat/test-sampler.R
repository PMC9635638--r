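mkReads <- function(lens, prefix = "r") {
  setNames(vapply(lens, function(l) strrep("A", l), character(1)),
           paste0(prefix, seq_along(lens)))
}

test_that("the length window is inclusive at both ends", {
  reads <- mkReads(c(9999, 10000, 40000, 40001))
  flt <- filterByLength(reads, 10000, 40000)
  expect_identical(names(flt$eligible), c("r2", "r3"))
  expect_equal(flt$nExcludedShort, 1L)
  expect_equal(flt$nExcludedLong, 1L)
  expect_equal(flt$nEligible + flt$nExcludedShort + flt$nExcludedLong,
               length(reads))

  all <- filterByLength(reads, 1, Inf)
  expect_equal(all$nEligible, 4L)

  none <- filterByLength(Biostrings::DNAStringSet(), 1, Inf)
  expect_equal(none$nEligible, 0L)
})

test_that("the stated worked case selects exactly 500 reads", {
  reads <- mkReads(rep(10000, 1000))
  res <- sampleToCoverage(reads, SamplingSpec(1e6, 5, seed = 17))
  expect_length(selectedIds(res), 500L)
  expect_equal(res@totalBases, 5e6)
  expect_equal(achievedCoverage(res), 5)
  expect_false(res@exhausted)
})

test_that("sampling is a pure function of the seed", {
  reads <- mkReads(sample(500:1500, 300, replace = TRUE))
  a <- sampleToCoverage(reads, SamplingSpec(20000, 3, seed = 11))
  b <- sampleToCoverage(reads, SamplingSpec(20000, 3, seed = 11))
  expect_identical(selectedIds(a), selectedIds(b))
  c <- sampleToCoverage(reads, SamplingSpec(20000, 3, seed = 12))
  expect_false(identical(selectedIds(a), selectedIds(c)))
})

test_that("coverage overshoot is bounded by one read and windows hold", {
  set.seed(61)
  for (i in 1:20) {
    lens <- sample(100:900, 150, replace = TRUE)
    reads <- mkReads(lens)
    spec <- SamplingSpec(1000, runif(1, 2, 20), minLen = 200,
                         maxLen = 800, seed = i)
    res <- suppressWarnings(sampleToCoverage(reads, spec))
    target <- spec@genomeSize * spec@targetCoverage
    w <- nchar(reads[selectedIds(res)])
    expect_true(all(w >= 200 & w <= 800))
    if (!res@exhausted) {
      expect_gte(res@totalBases, target)
      expect_lt(res@totalBases, target + 800)
    }
  }
})

test_that("pool exhaustion is flagged, an empty pool is an error", {
  reads <- mkReads(rep(1000, 3))
  expect_warning(
    res <- sampleToCoverage(reads, SamplingSpec(1000, 10, seed = 1)),
    "exhausted")
  expect_true(res@exhausted)
  expect_length(selectedIds(res), 3L)

  expect_error(
    sampleToCoverage(reads, SamplingSpec(1000, 2, minLen = 5000, seed = 1)),
    "no reads are eligible")
})

test_that("written subsamples keep order, format and the spec report", {
  tq <- withr::local_tempfile(fileext = ".fq")
  writeLines(unlist(lapply(1:6, function(i)
    c(paste0("@r", i), strrep("ACGT", 25), "+",
      strrep(LETTERS[i + 5], 100)))), tq)
  reads <- readSequences(tq)
  res <- sampleToCoverage(reads, SamplingSpec(100, 3, seed = 5))
  out <- withr::local_tempfile(fileext = ".fq")
  rep <- withr::local_tempfile(fileext = ".tsv")
  writeSample(reads, res, out, reportPath = rep)
  back <- readSequences(out)
  expect_identical(names(back), selectedIds(res))
  # qualities preserved for the selected reads
  expect_identical(S4Vectors::mcols(back)$quality,
                   S4Vectors::mcols(reads[selectedIds(res)])$quality)
  repDf <- read.delim(rep)
  expect_equal(repDf$seed, 5L)
  expect_equal(repDf$achieved_coverage, achievedCoverage(res))

  bogus <- methods::new("SampleResult", selectedIds = "nope",
                        totalBases = 1, achievedCoverage = 0.01,
                        nEligible = 1L, nExcludedShort = 0L,
                        nExcludedLong = 0L, exhausted = FALSE,
                        spec = SamplingSpec(100, 1, seed = 1))
  expect_error(writeSample(reads, bogus, out), "absent from the read set")
})
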