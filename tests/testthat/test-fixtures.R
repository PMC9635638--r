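test_that("toy genomes are seed-deterministic with exact repeat copies", {
  a <- makeToyGenome(50000, repeatFamilies = list(c(500, 4)), seed = 5)
  b <- makeToyGenome(50000, repeatFamilies = list(c(500, 4)), seed = 5)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_equal(nrow(a$repeats), 4L)
  s <- as.character(a$genome[[1]])
  units <- substring(s, a$repeats$start, a$repeats$end)
  expect_true(all(units == units[1]))   # exact duplicates
  expect_equal(unique(nchar(units)), 500L)

  c2 <- makeToyGenome(50000, repeatFamilies = list(c(500, 4)), seed = 6)
  expect_false(identical(as.character(a$genome), as.character(c2$genome)))
})

test_that("GC content tracks the requested fraction", {
  g <- makeToyGenome(3e5, gcFrac = 0.42, seed = 7)
  gc <- sum(Biostrings::letterFrequency(g$genome, c("G", "C"))) / 3e5
  expect_lt(abs(gc - 0.42), 0.01)    # binomial: sd ~ 0.0009 at n = 3e5
})

test_that("planted assembly pairs honor the case-kind composition", {
  g <- makeToyGenome(120000, seed = 8)
  fx <- makePlantedAssemblyPair(g$genome, nGenes = 6, nFragmented = 3,
                                nRepeatFlanked = 2, nOrientAmbiguous = 1,
                                seed = 9)
  expect_equal(sum(fx$truth$kind == "clean"), 3L)
  expect_equal(sum(fx$truth$kind == "repeat_flank"), 2L)
  expect_equal(sum(fx$truth$kind == "orient_ambiguous"), 1L)
  fs <- buscoSummary(fx$focalBusco)
  expect_equal(fs[["F"]], 6L)
  ds <- buscoSummary(fx$donorBusco)
  expect_equal(ds[["CS"]], 6L)
  # determinism
  fx2 <- makePlantedAssemblyPair(g$genome, nGenes = 6, nFragmented = 3,
                                 nRepeatFlanked = 2, nOrientAmbiguous = 1,
                                 seed = 9)
  expect_identical(as.character(fx$focal), as.character(fx2$focal))
  expect_identical(as.character(fx$donor), as.character(fx2$donor))

  expect_error(
    makePlantedAssemblyPair(g$genome, nGenes = 60, seed = 1),
    "too short")
})

test_that("simulated reads meet coverage, chimera and fidelity contracts", {
  g <- makeToyGenome(2e5, seed = 10)
  rd <- simulateLongReads(g$genome, coverage = 5, meanLog = log(1000),
                          sdLog = 0.3, minLen = 300, maxLen = 4000,
                          chimeraRate = 0.05, substRate = 0, seed = 11)
  expect_gte(sum(nchar(as.character(rd$reads))), 5 * 2e5)
  n <- nrow(rd$truth)
  nChim <- sum(rd$truth$chimeric)
  # binomial 3-sigma band around n * 0.05
  expect_lt(abs(nChim - n * 0.05), 3 * sqrt(n * 0.05 * 0.95) + 1)
  # error-free non-chimeric reads are exact genome substrings
  gseq <- as.character(g$genome[[1]])
  plain <- which(!rd$truth$chimeric)[1:10]
  for (i in plain) {
    tr <- rd$truth[i, ]
    expect_identical(as.character(rd$reads[[i]]),
                     substr(gseq, tr$start, tr$start + tr$length - 1L))
  }
  # chimeric halves come from loci >= 100 kb apart (single scaffold)
  ch <- rd$truth[rd$truth$chimeric, ]
  expect_true(all(abs(ch$start2 - ch$start) >= 1e5))
  # determinism
  rd2 <- simulateLongReads(g$genome, coverage = 5, meanLog = log(1000),
                           sdLog = 0.3, minLen = 300, maxLen = 4000,
                           chimeraRate = 0.05, substRate = 0, seed = 11)
  expect_identical(as.character(rd$reads), as.character(rd2$reads))
})

test_that("substitution errors land at the requested rate", {
  g <- makeToyGenome(1e5, seed = 12)
  rd <- simulateLongReads(g$genome, coverage = 3, meanLog = log(1000),
                          sdLog = 0.2, minLen = 300, maxLen = 3000,
                          chimeraRate = 0, substRate = 0.01, seed = 13)
  gseq <- as.character(g$genome[[1]])
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(rd$truth))) {
    tr <- rd$truth[i, ]
    ref <- substr(gseq, tr$start, tr$start + tr$length - 1L)
    obs <- as.character(rd$reads[[i]])
    mism <- mism + sum(utf8ToInt(ref) != utf8ToInt(obs))
    tot <- tot + nchar(ref)
  }
  expect_lt(abs(mism / tot - 0.01), 0.003)
})

test_that("merge scenarios and gap fixtures are seed-deterministic", {
  a <- makeMergeScenario(seed = 14)
  b <- makeMergeScenario(seed = 14)
  expect_identical(as.character(a$merged), as.character(b$merged))
  expect_identical(buscoRecords(a$mergedBusco), buscoRecords(b$mergedBusco))

  g <- makeToyGenome(60000, seed = 15)
  mix <- c(closed = 2, partially_filled = 2, overfilled = 2, unresolved = 2)
  f1 <- makeGapFateFixture(g$genome, 8, mix, seed = 16)
  f2 <- makeGapFateFixture(g$genome, 8, mix, seed = 16)
  expect_identical(as.character(f1$post), as.character(f2$post))
  expect_identical(f1$truth, f2$truth)
  expect_error(makeGapFateFixture(g$genome, 8, c(closed = 3), seed = 1),
               "sum to nGaps")
})
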