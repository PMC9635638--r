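test_that("PAF lines are parsed with identity from matches/alnlen", {
  tf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(
    pafLine("q1", 50000, 0, 30000, "+", "r1", 120000, 70000, 100000,
            29700, 30000),
    pafLine("q2", 8000, 100, 4100, "-", "r1", 120000, 500, 4500,
            3800, 4000)), tf)
  b <- parseAlignments(tf)
  expect_equal(nrow(b), 2L)
  expect_equal(b$identity_pct[1], 99.0)
  expect_equal(b$query_start[1], 0L)
  expect_equal(b$query_end[1], 30000L)
  expect_identical(b$strand[2], "-")
  # PAF query coordinates are already forward-strand
  expect_equal(b$query_start[2], 100L)

  expect_equal(nrow(parseAlignments(writeTempFasta(character(0)))), 0L)

  writeLines("q1\t100\t0", tf)
  expect_error(parseAlignments(tf, format = "paf"), "line 1")
})

test_that("show-coords tables normalize minus-strand query coordinates", {
  tf <- withr::local_tempfile(fileext = ".coords")
  writeLines(c("/path/ref.fa /path/query.fa", "NUCMER", "",
               paste("S1", "E1", "S2", "E2", sep = "\t"),
               paste(1001, 2000, 501, 1500, 1000, 1000, 97.5, "R1", "Q1",
                     sep = "\t"),
               paste(5001, 6000, 2500, 1501, 1000, 1000, 95.0, "R1", "Q1",
                     sep = "\t")), tf)
  b <- parseAlignments(tf)
  expect_equal(nrow(b), 2L)
  expect_equal(b$ref_start[1], 1000L)  # 1-based inclusive -> 0-based half-open
  expect_equal(b$ref_end[1], 2000L)
  expect_identical(b$strand, c("+", "-"))
  expect_equal(b$query_start[2], 1500L)
  expect_equal(b$query_end[2], 2500L)
  expect_equal(b$identity_pct[2], 95.0)
})

test_that("identity/length filters are inclusive and preset sweep is monotone", {
  blocks <- data.frame(
    ref_id = "r", query_id = "q", ref_start = 0L, ref_end = 10L,
    query_start = 0L, query_end = 10L, strand = "+",
    identity_pct = c(94.9, 95.0, 99.0, 98.0),
    block_len = c(2000L, 1000L, 800L, 12000L))
  expect_equal(nrow(filterAlignments(blocks, 95, 1000)), 2L)
  expect_true(all(filterAlignments(blocks, 95, 1000)$identity_pct >= 95))
  # the 95.0/1000 block survives exactly at its thresholds
  expect_true(any(filterAlignments(blocks, 95, 1000)$block_len == 1000L))

  kept <- vapply(c(0, 1000, 5000, 10000), function(l)
    nrow(filterAlignments(blocks, 95, l)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("worked overlap geometries and the 1.5 boundary behave as stated", {
  blk <- function(qs, qe) data.frame(
    ref_id = "r", query_id = "q", ref_start = 0L, ref_end = qe - qs,
    query_start = qs, query_end = qe, strand = "+",
    identity_pct = 99, block_len = qe - qs, stringsAsFactors = FALSE)

  single <- assessOverlap(blk(0, 30000))
  expect_equal(single$ovl_bp, 30000)
  expect_equal(single$novl_bp, 0)
  expect_identical(single$ratio, Inf)
  expect_true(single$merge_decision)

  two <- assessOverlap(rbind(blk(0, 10000), blk(40000, 45000)))
  expect_equal(two$ovl_bp, 15000)
  expect_equal(two$novl_bp, 30000)
  expect_equal(two$ratio, 0.5)
  expect_false(two$merge_decision)

  # OVL 30000, extent 50000 -> n-OVL 20000, ratio exactly 1.5: merged
  boundary <- assessOverlap(rbind(blk(0, 25000), blk(45000, 50000)))
  expect_equal(boundary$ratio, 1.5)
  expect_true(boundary$merge_decision)

  expect_error(assessOverlap(blk(0, 10)[0, ]), "at least one")
})

test_that("overlap assessment equals the base-set-union oracle", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:6, 1)
    qs <- sample(0:20000, n)
    qe <- qs + sample(50:5000, n, replace = TRUE)
    blocks <- data.frame(
      ref_id = "r", query_id = "q", ref_start = qs, ref_end = qe,
      query_start = qs, query_end = qe, strand = "+",
      identity_pct = 99, block_len = qe - qs, stringsAsFactors = FALSE)
    got <- assessOverlap(blocks)
    want <- bruteOvl(qs, qe)
    expect_equal(got$ovl_bp, want$ovl)
    expect_equal(got$novl_bp, want$novl)
  }
})

test_that("per-pair assessment covers every ref-query pair once", {
  blocks <- data.frame(
    ref_id = c("r1", "r1", "r2"), query_id = c("q1", "q1", "q2"),
    ref_start = 0L, ref_end = 100L,
    query_start = c(0L, 200L, 0L), query_end = c(100L, 300L, 100L),
    strand = "+", identity_pct = 99, block_len = 100L,
    stringsAsFactors = FALSE)
  res <- assessAllOverlaps(blocks)
  expect_equal(nrow(res), 2L)
  expect_setequal(paste(res$ref_id, res$query_id),
                  c("r1 q1", "r2 q2"))
})
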