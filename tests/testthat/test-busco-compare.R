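mkTable <- function(name, ...) {
  rows <- list(...)
  BuscoTable(do.call(rbind, lapply(rows, function(r)
    data.frame(busco_id = r[[1]], status = r[[2]],
               seq_id = if (length(r) > 2) r[[3]] else NA,
               start = if (length(r) > 3) as.integer(r[[4]]) else NA,
               end = if (length(r) > 4) as.integer(r[[5]]) else NA,
               score = if (length(r) > 5) as.numeric(r[[6]]) else NA,
               length = if (length(r) > 6) as.integer(r[[7]]) else NA,
               stringsAsFactors = FALSE))), name)
}

test_that("a fragmented gene with one complete donor yields one case", {
  focal <- mkTable("focal", list("g1", "Fragmented", "s1", 100, 900, 80, 300))
  alt1 <- mkTable("alt1", list("g1", "Complete", "a9", 50, 700, 200, 650))
  res <- findRescuableGenes(focal, list(alt1))
  expect_equal(nrow(res$cases), 1L)
  expect_identical(res$cases$donor_assembly_name, "alt1")
  expect_identical(res$cases$donor_seq_id, "a9")
  expect_equal(nrow(res$unrescuable), 0L)
})

test_that("no fragmented genes means no cases", {
  focal <- mkTable("focal", list("g1", "Complete", "s1", 1, 9, 10, 9))
  alt <- mkTable("alt", list("g1", "Complete", "a1", 1, 9, 10, 9))
  res <- findRescuableGenes(focal, list(alt))
  expect_equal(nrow(res$cases), 0L)
})

test_that("donor choice is by score with supplied-order tie-break", {
  focal <- mkTable("focal", list("g1", "Fragmented", "s1", 1, 9, 10, 9))
  a1 <- mkTable("alt1", list("g1", "Complete", "x", 1, 9, 100, 9))
  a2 <- mkTable("alt2", list("g1", "Complete", "y", 1, 9, 120, 9))
  expect_identical(
    findRescuableGenes(focal, list(a1, a2))$cases$donor_assembly_name,
    "alt2")
  # equal scores: first-listed alternative wins
  a2tie <- mkTable("alt2", list("g1", "Complete", "y", 1, 9, 100, 9))
  expect_identical(
    findRescuableGenes(focal, list(a1, a2tie))$cases$donor_assembly_name,
    "alt1")
  expect_identical(
    findRescuableGenes(focal, list(a2tie, a1))$cases$donor_assembly_name,
    "alt2")
})

test_that("duplicated donors are ineligible and absent genes warn", {
  focal <- mkTable("focal", list("g1", "Fragmented", "s1", 1, 9, 10, 9))
  dup <- mkTable("alt1",
                 list("g1", "Duplicated", "x", 1, 9, 100, 9),
                 list("g1", "Duplicated", "y", 1, 9, 100, 9))
  res <- findRescuableGenes(focal, list(dup))
  expect_equal(nrow(res$cases), 0L)
  expect_identical(res$unrescuable$reason, "no_complete_donor")

  empty <- BuscoTable(data.frame(), "alt2")
  expect_warning(findRescuableGenes(focal, list(empty)),
                 "absent from alternative")
})

test_that("case sets are stable under focal record permutation", {
  set.seed(5)
  rows <- lapply(1:12, function(i) {
    st <- sample(c("Fragmented", "Complete", "Missing"), 1)
    if (st == "Missing") list(sprintf("g%02d", i), st)
    else list(sprintf("g%02d", i), st,
              "s1", i * 100, i * 100 + 50, runif(1, 10, 99), 50)
  })
  alt <- mkTable("alt", list("g01", "Complete", "a", 1, 60, 150, 60),
                 list("g05", "Complete", "a", 100, 160, 150, 60))
  for (perm in 1:3) {
    shuffled <- sample(rows)
    res <- suppressWarnings(
      findRescuableGenes(do.call(mkTable, c("focal", shuffled)), list(alt)))
    if (perm == 1) first <- res$cases
    expect_equal(res$cases, first)
  }
})

test_that("reclassification events capture status, length and location changes", {
  a <- mkTable("a", list("g1", "Fragmented", "s1", 1, 300, 10, 300))
  b <- mkTable("b", list("g1", "Complete", "s1", 1, 210, 50, 210))
  ev <- compareReclassification(a, b)
  expect_equal(nrow(ev), 1L)
  expect_identical(ev$transition, "F->C")
  expect_equal(ev$length_delta, -90L)

  expect_equal(nrow(compareReclassification(a, a)), 0L)

  c1 <- mkTable("a", list("g1", "Complete", "s1", 1, 200, 10, 200))
  c2 <- mkTable("b", list("g1", "Complete", "s2", 1, 200, 10, 200))
  ev2 <- compareReclassification(c1, c2)
  expect_equal(nrow(ev2), 1L)
  expect_identical(ev2$transition, "C->C")
  expect_identical(ev2$seq_id_after, "s2")
})

test_that("comparing any table with itself yields no events", {
  set.seed(9)
  rows <- lapply(1:8, function(i) {
    st <- sample(c("Fragmented", "Complete", "Missing"), 1)
    if (st == "Missing") list(sprintf("g%02d", i), st)
    else list(sprintf("g%02d", i), st, "s1", i * 10, i * 10 + 5, 10, 6)
  })
  x <- do.call(mkTable, c("x", rows))
  expect_equal(nrow(compareReclassification(x, x)), 0L)
})
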