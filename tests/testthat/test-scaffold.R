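test_that("segmentation separates contigs at long N runs only", {
  sc <- segmentScaffold(paste0("ACGT", strrep("N", 10), "TTGA"),
                        minGapLen = 10)
  expect_equal(as.data.frame(contigSpans(sc))[, 1:2],
               data.frame(start = c(1L, 15L), end = c(4L, 18L)))
  expect_equal(as.data.frame(gapSpans(sc))[, 1:2],
               data.frame(start = 5L, end = 14L))

  noN <- segmentScaffold("ACGT")
  expect_length(gapSpans(noN), 0L)
  expect_equal(IRanges::width(contigSpans(noN)), 4L)

  # a 5-N run stays inside the contig at minGapLen 10
  short <- segmentScaffold("ACGTNNNNNTTGA", minGapLen = 10)
  expect_length(gapSpans(short), 0L)
  expect_equal(IRanges::width(contigSpans(short)), 13L)

  allN <- segmentScaffold(strrep("N", 25), minGapLen = 10)
  expect_length(contigSpans(allN), 0L)
  expect_length(gapSpans(allN), 1L)
})

test_that("contig and gap spans tile arbitrary N-salted sequences", {
  set.seed(42)
  for (i in 1:30) {
    s <- randomSeq(sample(50:400, 1), c("A", "C", "G", "T", "N", "N"))
    sc <- segmentScaffold(s, minGapLen = sample(2:12, 1))
    spans <- c(contigSpans(sc), gapSpans(sc))
    spans <- spans[order(IRanges::start(spans))]
    expect_equal(sum(IRanges::width(spans)), nchar(s))
    if (length(spans) > 1) {
      expect_true(all(IRanges::start(spans)[-1] ==
                      IRanges::end(spans)[-length(spans)] + 1))
    }
    # concatenating the span substrings reproduces the sequence
    parts <- substring(s, IRanges::start(spans), IRanges::end(spans))
    expect_identical(paste(parts, collapse = ""), s)
  }
})

test_that("N50 matches the brute-force candidate oracle", {
  expect_equal(n50(c(5, 4, 3)), 4)
  set.seed(7)
  for (i in 1:50) {
    lens <- sample(1:500, sample(1:40, 1), replace = TRUE)
    expect_equal(n50(lens), bruteN50(lens))
  }
})

test_that("assembly statistics follow their definitions", {
  asm <- c(a = randomSeq(5), b = randomSeq(4), c = randomSeq(3))
  st <- assemblyStats(asm)
  expect_equal(st$scaffold_n50, 4)
  expect_equal(st$n_scaffolds, 3L)

  withN <- c(s = paste0(randomSeq(470), strrep("N", 50), randomSeq(480)))
  st2 <- assemblyStats(withN)
  expect_equal(st2$ns_per_100kb, 1e5 * 50 / 1000)
  expect_equal(st2$n_contigs, 2L)
  expect_equal(st2$total_contig_len, 950)

  expect_equal(assemblyStats(c(x = "ACGT"))$ns_per_100kb, 0)
  expect_error(assemblyStats(Biostrings::DNAStringSet()), "empty")
})

test_that("reverse complement is a length- and N-preserving involution", {
  rc <- reverseComplementAssembly(c(s = "ACGTN"))
  expect_identical(as.character(rc[["s"]]), "NACGT")
  expect_identical(names(rc), "s")
  set.seed(11)
  for (i in 1:20) {
    s <- randomSeq(sample(10:200, 1), c("A", "C", "G", "T", "N"))
    twice <- reverseComplementAssembly(reverseComplementAssembly(c(x = s)))
    expect_identical(as.character(twice[["x"]]), s)
  }
  expect_identical(
    as.character(reverseComplementAssembly(c(p = "ACGT"))[["p"]]), "ACGT")
})

test_that("splitting at a gap drops the gap and conserves length", {
  s <- paste0("ACGT", strrep("N", 10), "TTGA")
  halves <- splitScaffoldAtGap(segmentScaffold(s, id = "sc"), 1)
  expect_identical(names(halves), c("sc.1", "sc.2"))
  expect_identical(as.character(halves[[1]]), "ACGT")
  expect_identical(as.character(halves[[2]]), "TTGA")
  expect_equal(sum(BiocGenerics::width(halves)) + 10, nchar(s))
  # re-inserting the gap reproduces the original
  expect_identical(
    paste0(as.character(halves[[1]]), strrep("N", 10),
           as.character(halves[[2]])), s)

  expect_error(splitScaffoldAtGap(segmentScaffold("ACGT"), 1), "no gaps")
  expect_error(splitScaffoldAtGap(segmentScaffold(s), 2), "out of range")
})
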