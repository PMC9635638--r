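test_that("flank extraction clips at scaffold ends and flags short flanks", {
  s <- randomSeq(5000)
  fl <- extractFlanks(s, 1001, 2000, flankLen = 500)
  expect_equal(c(fl$left$start, fl$left$end), c(501, 1000))
  expect_equal(c(fl$right$start, fl$right$end), c(2001, 2500))
  expect_true(fl$left$usable && fl$right$usable)
  expect_false(fl$left$truncated || fl$right$truncated)

  tr <- extractFlanks(s, 101, 600, flankLen = 500)
  expect_equal(c(tr$left$start, tr$left$end), c(1, 100))
  expect_true(tr$left$truncated)

  edge <- extractFlanks(s, 4001, 4990, flankLen = 500, k = 31)
  expect_false(edge$right$usable)   # 10 bp flank cannot hold a 31-mer
})

test_that("plans are demoted for neighbor conflicts and disordered anchors", {
  set.seed(31)
  focalSeq <- paste0(randomSeq(3000), strrep("N", 50), randomSeq(3000))
  sc <- segmentScaffold(focalSeq, id = "s1")
  case <- data.frame(busco_id = "g1", focal_seq_id = "s1",
                     focal_start = 1500L, focal_end = 2500L,
                     donor_assembly_name = "alt", donor_seq_id = "d1",
                     donor_start = 100L, donor_end = 1100L,
                     donor_strand = "+", donor_score = 200,
                     stringsAsFactors = FALSE)
  mkAnchor <- function(s, e) list(start = s, end = e, matchedFrac = 1,
                                  reason = NA_character_)
  noNeighbors <- BuscoTable(data.frame(
    busco_id = "g1", status = "Fragmented", seq_id = "s1",
    start = 1500L, end = 2500L), "focal")
  p <- planReplacement(case, sc, mkAnchor(1000, 1400), mkAnchor(2600, 2900),
                       "forward", noNeighbors, "ACGT")
  expect_identical(p$status, "applied")
  expect_equal(c(p$replaced_start, p$replaced_end), c(1, 3000))

  neighbor <- BuscoTable(data.frame(
    busco_id = c("g1", "g9"), status = c("Fragmented", "Complete"),
    seq_id = "s1", start = c(1500L, 200L), end = c(2500L, 800L)), "focal")
  p2 <- planReplacement(case, sc, mkAnchor(1000, 1400), mkAnchor(2600, 2900),
                        "forward", neighbor, "ACGT")
  expect_identical(p2$status, "skipped_neighbor_conflict")
  expect_match(p2$reason, "g9")

  p3 <- planReplacement(case, sc, mkAnchor(2600, 2900), mkAnchor(1000, 1400),
                        "forward", noNeighbors, "ACGT")
  expect_identical(p3$status, "skipped_inconsistent")

  p4 <- planReplacement(case, sc, NULL, mkAnchor(2600, 2900),
                        "forward", noNeighbors, "ACGT")
  expect_identical(p4$status, "skipped_no_anchor")

  p5 <- planReplacement(case, sc, NULL, NULL, "ambiguous", noNeighbors, NA)
  expect_identical(p5$status, "skipped_orientation")
})

test_that("applying an empty plan set is the identity", {
  asm <- Biostrings::DNAStringSet(c(s1 = "ACGTACGT"))
  res <- applyReplacements(asm, asmrescue:::.emptyPlans())
  expect_identical(as.character(res$assembly), as.character(asm))
  expect_equal(casesIdentified(res$report), 0L)
})

test_that("the full rescue run matches the planted truth table", {
  g <- makeToyGenome(120000, seed = 301)
  fx <- makePlantedAssemblyPair(g$genome, nGenes = 6, geneLen = 2000,
                                nFragmented = 3, nRepeatFlanked = 1,
                                nOrientAmbiguous = 1, seed = 302)
  res <- correctAssembly(fx$focal, fx$focalBusco, list(fx$donor),
                         list(fx$donorBusco))
  plans <- replacementPlans(res$report)
  truth <- fx$truth[!is.na(fx$truth$expected_status), ]
  got <- setNames(plans$status, plans$busco_id)
  expect_equal(got[truth$busco_id], setNames(truth$expected_status,
                                             truth$busco_id))
  # every applied donor gene is an exact substring of the corrected scaffold
  corrected <- as.character(res$assembly[["focal_1"]])
  for (gene in truth$busco_id[truth$expected_status == "applied"])
    expect_true(grepl(fx$truth$gene_seq[fx$truth$busco_id == gene],
                      corrected, fixed = TRUE))
  # accounting conserves
  expect_equal(casesIdentified(res$report),
               sum(statusCounts(res$report)))
})

test_that("corrected assemblies differ only inside replaced intervals", {
  g <- makeToyGenome(90000, seed = 311)
  fx <- makePlantedAssemblyPair(g$genome, nGenes = 4, geneLen = 1500,
                                nFragmented = 2, seed = 312)
  res <- correctAssembly(fx$focal, fx$focalBusco, list(fx$donor),
                         list(fx$donorBusco))
  plans <- replacementPlans(res$report)
  app <- plans[plans$status == "applied", ]
  app <- app[order(app$replaced_start), ]
  orig <- as.character(fx$focal[["focal_1"]])
  # rebuild the expected corrected sequence from the original plus plans
  pieces <- character(0); prev <- 0L
  for (i in seq_len(nrow(app))) {
    pieces <- c(pieces, substr(orig, prev + 1L, app$replaced_start[i] - 1L),
                app$donor_segment_seq[i])
    prev <- app$replaced_end[i]
  }
  pieces <- c(pieces, substr(orig, prev + 1L, nchar(orig)))
  expect_identical(as.character(res$assembly[["focal_1"]]),
                   paste(pieces, collapse = ""))
})

test_that("an empty donor set identifies nothing and changes nothing", {
  g <- makeToyGenome(90000, seed = 321)
  fx <- makePlantedAssemblyPair(g$genome, nGenes = 4, geneLen = 1500,
                                nFragmented = 2, seed = 322)
  res <- correctAssembly(fx$focal, fx$focalBusco, list(), list())
  expect_equal(casesIdentified(res$report), 0L)
  expect_identical(as.character(res$assembly), as.character(fx$focal))
})

test_that("a second pass finds nothing left to rescue", {
  g <- makeToyGenome(90000, seed = 331)
  fx <- makePlantedAssemblyPair(g$genome, nGenes = 4, geneLen = 1500,
                                nFragmented = 3, seed = 332)
  res <- correctAssembly(fx$focal, fx$focalBusco, list(fx$donor),
                         list(fx$donorBusco))
  corrected <- as.character(res$assembly[["focal_1"]])
  # regenerate the focal table from ground truth: rescued genes are now
  # complete at their new coordinates
  applied <- replacementPlans(res$report)
  applied <- applied$busco_id[applied$status == "applied"]
  rows <- lapply(applied, function(id) {
    seq <- fx$truth$gene_seq[fx$truth$busco_id == id]
    at <- regexpr(seq, corrected, fixed = TRUE)
    data.frame(busco_id = id, status = "Complete", seq_id = "focal_1",
               start = as.integer(at), score = 100,
               end = as.integer(at) + nchar(seq) - 1L,
               length = nchar(seq), stringsAsFactors = FALSE)
  })
  newFocal <- BuscoTable(do.call(rbind, rows), "corrected")
  donorRecs <- buscoRecords(fx$donorBusco)
  newDonor <- BuscoTable(donorRecs[donorRecs$busco_id %in% applied, ],
                         "donorA")
  res2 <- correctAssembly(res$assembly, newFocal, list(fx$donor),
                          list(newDonor))
  expect_equal(casesIdentified(res2$report), 0L)
  expect_identical(as.character(res2$assembly[["focal_1"]]), corrected)
})
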