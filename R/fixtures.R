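#' @name fixtures
#' @title Seeded synthetic-data generators
#' @description Every generator in this file is a pure function of its
#'   arguments and seed: identical calls give byte-identical output, and
#'   each emits ground-truth labels so downstream classifiers can be
#'   scored exactly. The generators emulate the failure modes the
#'   diagnostics target — repeat-mediated anchoring failures, ambiguous
#'   scaffold orientation, merge-failure duplication, and gap filling
#'   that expands gaps instead of closing them — on toy genomes small
#'   enough to analyze in seconds.
NULL

# Random sequence with a given GC fraction (call inside .withSeed).
.randSeq <- function(n, gcFrac = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gcFrac) / 2, gcFrac / 2, gcFrac / 2,
                        (1 - gcFrac) / 2)), collapse = "")
}

# Overwrite s[pos .. pos+nchar(repl)-1] with repl (1-based).
.overwrite <- function(s, pos, repl) {
  paste0(substr(s, 1L, pos - 1L), repl,
         substr(s, pos + nchar(repl), nchar(s)))
}

#' Generate a toy genome with exact repeat families
#'
#' A random genome at a chosen GC fraction, optionally salted with repeat
#' families: each family is one random unit copied verbatim to several
#' non-overlapping, annotated positions (exact duplicates — the k-mer
#' ambiguity source the anchoring machinery must refuse).
#'
#' @param lengthBp genome length in bp.
#' @param gcFrac GC fraction (default 0.42, a typical teleost value).
#' @param repeatFamilies list of \code{c(unitLen, copies)} pairs.
#' @param seed integer seed; output is a pure function of the arguments.
#' @param id sequence id (default \code{"toygenome"}).
#' @return list with \code{genome} (named \code{DNAStringSet} of 1) and
#'   \code{repeats} (data.frame \code{family}, \code{copy}, \code{start},
#'   \code{end}, 1-based inclusive).
#' @export
makeToyGenome <- function(lengthBp, gcFrac = 0.42, repeatFamilies = list(),
                          seed = 1L, id = "toygenome") {
  lengthBp <- as.integer(lengthBp)
  stopifnot(lengthBp > 0L)
  res <- .withSeed(seed, {
    s <- .randSeq(lengthBp, gcFrac)
    ann <- list()
    nFam <- length(repeatFamilies)
    if (nFam) {
      totRep <- sum(vapply(repeatFamilies,
                           function(f) f[1L] * f[2L], numeric(1)))
      if (totRep >= lengthBp)
        stop("repeat families exceed the genome length", call. = FALSE)
      # one stratum per copy keeps copies non-overlapping and reproducible
      copies <- sum(vapply(repeatFamilies, `[`, numeric(1), 2L))
      stratum <- lengthBp %/% copies
      ci <- 0L
      for (fi in seq_len(nFam)) {
        unitLen <- as.integer(repeatFamilies[[fi]][1L])
        nCopy <- as.integer(repeatFamilies[[fi]][2L])
        if (stratum <= unitLen + 2L)
          stop("repeat copies do not fit the genome", call. = FALSE)
        unit <- .randSeq(unitLen, gcFrac)
        for (cp in seq_len(nCopy)) {
          lo <- ci * stratum + 1L
          pos <- lo + sample.int(stratum - unitLen, 1L) - 1L
          s <- .overwrite(s, pos, unit)
          ann[[length(ann) + 1L]] <- data.frame(
            family = paste0("rep", fi), copy = cp,
            start = pos, end = pos + unitLen - 1L,
            stringsAsFactors = FALSE)
          ci <- ci + 1L
        }
      }
    }
    list(seq = s, ann = ann)
  })
  genome <- Biostrings::DNAStringSet(res$seq)
  names(genome) <- id
  repeats <- if (length(res$ann))
    do.call(rbind, c(res$ann, make.row.names = FALSE))
  else data.frame(family = character(0), copy = integer(0),
                  start = integer(0), end = integer(0),
                  stringsAsFactors = FALSE)
  list(genome = genome, repeats = repeats)
}

#' Write a repeat annotation as BED
#'
#' @param repeats data.frame from \code{\link{makeToyGenome}}.
#' @param seqId the genome sequence id.
#' @param path output BED path (0-based half-open, as BED requires).
#' @return \code{path}, invisibly.
#' @export
writeRepeatBed <- function(repeats, seqId, path) {
  bed <- data.frame(chrom = seqId, start = repeats$start - 1L,
                    end = repeats$end,
                    name = paste0(repeats$family, ".", repeats$copy))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a focal/donor assembly pair with planted rescuable genes
#'
#' Emulates the cross-assembly rescue setting: a single-scaffold focal
#' assembly in which planted genes are split by an inserted N gap
#' (classified Fragmented), and a donor assembly carrying each gene
#' contiguously (Complete, single-copy) on its own scaffold. Three planted
#' case kinds exercise the safety rails:
#' \itemize{
#'   \item \code{clean}: unique flanks; expected \code{applied}. The
#'     donor scaffold is reverse complemented with probability
#'     \code{revcomProb}, exercising orientation syncing.
#'   \item \code{repeat_flank}: the gene's left-flank sequence is copied
#'     to two other focal positions, so no flank k-mer is unique;
#'     expected \code{skipped_no_anchor}.
#'   \item \code{orient_ambiguous}: the donor scaffold carries equal
#'     forward and reverse-complement halves, so its orientation cannot
#'     be called; expected \code{skipped_orientation}.
#' }
#' Genes beyond the planted cases are complete in both assemblies and act
#' as neighbors. The focal scaffold also carries background N gaps between
#' gene slots so each gene's enclosing contigs are local.
#'
#' @param genome a toy genome (\code{DNAStringSet} of 1, or character).
#' @param nGenes total planted genes.
#' @param geneLen gene length in bp (default 2000).
#' @param nFragmented clean fragmented-and-rescuable genes.
#' @param nRepeatFlanked fragmented genes with a repeat-borne flank.
#' @param nOrientAmbiguous fragmented genes with an orientation-ambiguous
#'   donor scaffold.
#' @param flankLen donor flank length the rescue run will use.
#' @param gapLen length of inserted N gaps (default 100).
#' @param revcomProb probability a clean donor scaffold is reverse
#'   complemented (default 0.5).
#' @param seed integer seed.
#' @return list with \code{focal}, \code{donor} (named
#'   \code{DNAStringSet}s), \code{focalBusco}, \code{donorBusco}
#'   (\linkS4class{BuscoTable}s), and \code{truth} (data.frame with
#'   \code{busco_id}, \code{kind}, \code{expected_status},
#'   \code{expected_orientation}, \code{gene_seq}).
#' @export
makePlantedAssemblyPair <- function(genome, nGenes, geneLen = 2000L,
                                    nFragmented = nGenes,
                                    nRepeatFlanked = 0L,
                                    nOrientAmbiguous = 0L,
                                    flankLen = 1000L, gapLen = 100L,
                                    revcomProb = 0.5, seed = 1L) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome[[1L]])
  if (methods::is(genome, "DNAString")) genome <- as.character(genome)
  L <- nchar(genome)
  nGenes <- as.integer(nGenes); geneLen <- as.integer(geneLen)
  flankLen <- as.integer(flankLen); gapLen <- as.integer(gapLen)
  stopifnot(nFragmented + nRepeatFlanked + nOrientAmbiguous <= nGenes)
  stride <- L %/% nGenes
  pad <- 500L
  # slot must hold the donor window around the centered gene plus, left of
  # the window, two planted flank copies for repeat_flank cases
  need <- max(2L * (geneLen + flankLen + pad),
              4100L + 6L * flankLen)
  if (stride < need)
    stop("genome too short: need at least ", need * nGenes,
         " bp for ", nGenes, " genes at these lengths", call. = FALSE)

  .withSeed(seed, {
    kinds <- sample(c(rep("clean", nFragmented),
                      rep("repeat_flank", nRepeatFlanked),
                      rep("orient_ambiguous", nOrientAmbiguous),
                      rep("control",
                          nGenes - nFragmented - nRepeatFlanked -
                            nOrientAmbiguous)))
    slotStart <- (seq_len(nGenes) - 1L) * stride + 1L
    gs <- slotStart + stride %/% 2L
    ge <- gs + geneLen - 1L

    # plant flank duplications for repeat_flank genes
    trueG <- genome
    for (i in which(kinds == "repeat_flank")) {
      flank <- substr(trueG, gs[i] - flankLen, gs[i] - 1L)
      trueG <- .overwrite(trueG, slotStart[i] + 1000L, flank)
      trueG <- .overwrite(trueG, slotStart[i] + 1000L + flankLen + 500L,
                          flank)
    }

    # donor scaffolds: one window per gene
    winS <- pmax(slotStart, gs - flankLen - pad)
    winE <- pmin(slotStart + stride - 1L, ge + flankLen + pad)
    donorSeqs <- character(nGenes)
    donorGeneS <- integer(nGenes); donorGeneE <- integer(nGenes)
    orientation <- character(nGenes)
    for (i in seq_len(nGenes)) {
      win <- substr(trueG, winS[i], winE[i])
      s0 <- gs[i] - winS[i] + 1L
      e0 <- ge[i] - winS[i] + 1L
      if (kinds[i] == "orient_ambiguous") {
        decoy <- substr(trueG, slotStart[i] + pad,
                        slotStart[i] + pad + nchar(win) - 1L)
        donorSeqs[i] <- paste0(.revcomChar(decoy), win)
        donorGeneS[i] <- nchar(decoy) + s0
        donorGeneE[i] <- nchar(decoy) + e0
        orientation[i] <- "ambiguous"
      } else if (kinds[i] == "clean" && runif(1) < revcomProb) {
        wl <- nchar(win)
        donorSeqs[i] <- .revcomChar(win)
        donorGeneS[i] <- wl - e0 + 1L
        donorGeneE[i] <- wl - s0 + 1L
        orientation[i] <- "reverse"
      } else {
        donorSeqs[i] <- win
        donorGeneS[i] <- s0
        donorGeneE[i] <- e0
        orientation[i] <- "forward"
      }
    }

    # focal scaffold: true genome + N-gap insertions (slot boundaries and
    # the midpoint of every fragmented-kind gene)
    fragKinds <- c("clean", "repeat_flank", "orient_ambiguous")
    isFrag <- kinds %in% fragKinds
    mids <- gs + geneLen %/% 2L
    ins <- sort(c(slotStart[-1L] - 1L, mids[isFrag]))
    pieces <- character(0)
    prev <- 0L
    for (p in ins) {
      pieces <- c(pieces, substr(trueG, prev + 1L, p), strrep("N", gapLen))
      prev <- p
    }
    pieces <- c(pieces, substr(trueG, prev + 1L, L))
    focalSeq <- paste(pieces, collapse = "")
    focalPos <- function(x) x + gapLen * vapply(
      x, function(xx) sum(ins < xx), numeric(1))

    geneIds <- sprintf("g%03d", seq_len(nGenes))
    donorScore <- round(runif(nGenes, 200, 300), 1)
    fragScore <- round(runif(nGenes, 50, 150), 1)

    focalRecs <- lapply(seq_len(nGenes), function(i) {
      if (isFrag[i])
        data.frame(busco_id = geneIds[i], status = "Fragmented",
                   seq_id = "focal_1",
                   start = as.integer(focalPos(gs[i])),
                   end = as.integer(focalPos(mids[i])),
                   score = fragScore[i],
                   length = as.integer(geneLen %/% 2L),
                   stringsAsFactors = FALSE)
      else
        data.frame(busco_id = geneIds[i], status = "Complete",
                   seq_id = "focal_1",
                   start = as.integer(focalPos(gs[i])),
                   end = as.integer(focalPos(ge[i])),
                   score = donorScore[i], length = geneLen,
                   stringsAsFactors = FALSE)
    })
    donorRecs <- lapply(seq_len(nGenes), function(i) {
      data.frame(busco_id = geneIds[i], status = "Complete",
                 seq_id = paste0("donor_", geneIds[i]),
                 start = donorGeneS[i], end = donorGeneE[i],
                 score = donorScore[i], length = geneLen,
                 stringsAsFactors = FALSE)
    })

    focal <- Biostrings::DNAStringSet(focalSeq)
    names(focal) <- "focal_1"
    donor <- Biostrings::DNAStringSet(donorSeqs)
    names(donor) <- paste0("donor_", geneIds)

    truth <- data.frame(
      busco_id = geneIds, kind = kinds,
      expected_status = ifelse(
        kinds == "clean", "applied",
        ifelse(kinds == "repeat_flank", "skipped_no_anchor",
               ifelse(kinds == "orient_ambiguous", "skipped_orientation",
                      NA_character_))),
      expected_orientation = orientation,
      gene_seq = substring(trueG, gs, ge),
      true_start = gs, true_end = ge,
      stringsAsFactors = FALSE)

    list(
      focal = focal, donor = donor,
      focalBusco = BuscoTable(
        do.call(rbind, c(focalRecs, make.row.names = FALSE)), "focal"),
      donorBusco = BuscoTable(
        do.call(rbind, c(donorRecs, make.row.names = FALSE)), "donorA"),
      truth = truth)
  })
}

#' Build a pre/post assembly pair with planted gap fates
#'
#' The pre-assembly is the genome with \code{nGaps} equally spaced N gaps
#' of \code{gapLen} bp; the post-assembly rewrites each gap locus
#' according to its assigned fate: \code{closed} restores the true bases,
#' \code{partially_filled} fills part of the gap leaving residual N within
#' the original span, \code{overfilled} extends sequence inward from both
#' flanks while N remains — growing the locus beyond the original gap —
#' and \code{unresolved} scrambles the left flank so it cannot be
#' anchored.
#'
#' @param genome toy genome (\code{DNAStringSet} of 1, or character).
#' @param nGaps number of planted gaps.
#' @param fateMix named integer vector over \code{closed},
#'   \code{partially_filled}, \code{overfilled}, \code{unresolved};
#'   must sum to \code{nGaps}.
#' @param gapLen gap length in bp (default 100).
#' @param flankLen flank length the classifier will use (default 500).
#' @param seed integer seed.
#' @return list with \code{pre}, \code{post} (named \code{DNAStringSet}s)
#'   and \code{truth} (data.frame \code{gap_id}, \code{fate}).
#' @export
makeGapFateFixture <- function(genome, nGaps, fateMix, gapLen = 100L,
                               flankLen = 500L, seed = 1L) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome[[1L]])
  L <- nchar(genome)
  nGaps <- as.integer(nGaps); gapLen <- as.integer(gapLen)
  fateMix <- fateMix[c("closed", "partially_filled", "overfilled",
                       "unresolved")]
  fateMix[is.na(fateMix)] <- 0L
  names(fateMix) <- c("closed", "partially_filled", "overfilled",
                      "unresolved")
  if (sum(fateMix) != nGaps)
    stop("fateMix must sum to nGaps", call. = FALSE)
  stride <- L %/% (nGaps + 1L)
  if (stride < gapLen + 2L * flankLen + 200L)
    stop("genome too short for ", nGaps, " gaps at flankLen ", flankLen,
         call. = FALSE)
  .withSeed(seed, {
    fates <- sample(rep(names(fateMix), fateMix))
    gapStart <- seq_len(nGaps) * stride       # gap covers [gapStart, +gapLen)
    preSeq <- genome
    for (i in seq_len(nGaps))
      preSeq <- .overwrite(preSeq, gapStart[i], strrep("N", gapLen))
    # post: splice segment-by-segment
    pieces <- character(0)
    prev <- 0L
    for (i in seq_len(nGaps)) {
      seg <- substr(genome, prev + 1L, gapStart[i] - 1L)
      if (fates[i] == "unresolved") {
        # scramble the left flank so it cannot anchor
        scr <- .randSeq(flankLen)
        seg <- paste0(substr(seg, 1L, nchar(seg) - flankLen), scr)
      }
      fill <- switch(fates[i],
        closed = substr(genome, gapStart[i], gapStart[i] + gapLen - 1L),
        partially_filled = {
          resid <- max(10L, gapLen %/% 3L)
          nonN <- gapLen - 20L - resid
          paste0(.randSeq(nonN %/% 2L), strrep("N", resid),
                 .randSeq(nonN - nonN %/% 2L))
        },
        overfilled = paste0(.randSeq(80L), strrep("N", 40L),
                            .randSeq(gapLen - 30L)),
        unresolved = substr(genome, gapStart[i], gapStart[i] + gapLen - 1L))
      pieces <- c(pieces, seg, fill)
      prev <- gapStart[i] + gapLen - 1L
    }
    pieces <- c(pieces, substr(genome, prev + 1L, L))
    postSeq <- paste(pieces, collapse = "")
    pre <- Biostrings::DNAStringSet(preSeq); names(pre) <- "pre_1"
    post <- Biostrings::DNAStringSet(postSeq); names(post) <- "post_1"
    list(pre = pre, post = post,
         truth = data.frame(gap_id = paste0("pre_1:gap", seq_len(nGaps)),
                            fate = fates, stringsAsFactors = FALSE))
  })
}

#' Simulate long reads with known provenance
#'
#' Draws read lengths from a log-normal clamped to \code{[minLen,
#' maxLen]} (a pragmatic stand-in for a CLR length distribution), read
#' start positions uniformly along the genome, and — at
#' \code{chimeraRate} — joins two segments from loci at least 100 kb
#' apart (or from different scaffolds) into one chimeric read. Reads
#' accumulate until total bases cross \code{coverage} times the genome
#' length. Substitution errors are applied at \code{substRate} per base.
#'
#' @param genome named \code{DNAStringSet} (one or more scaffolds).
#' @param coverage target fold coverage of the simulated set.
#' @param meanLog,sdLog log-normal length parameters (defaults give a
#'   mode near 15-25 kb).
#' @param minLen,maxLen clamp bounds for read lengths.
#' @param chimeraRate probability a read is chimeric (default 0).
#' @param substRate per-base substitution error rate (default 0).
#' @param seed integer seed.
#' @return list with \code{reads} (named \code{DNAStringSet} with
#'   placeholder qualities in \code{mcols}) and \code{truth} (data.frame
#'   \code{read_id}, \code{chimeric}, \code{seq_id}, \code{start},
#'   \code{seq_id2}, \code{start2}, \code{length}).
#' @export
simulateLongReads <- function(genome, coverage, meanLog = log(20000),
                              sdLog = 0.35, minLen = 1000L,
                              maxLen = 60000L, chimeraRate = 0,
                              substRate = 0, seed = 1L) {
  genome <- .asSeqSet(genome)
  gchar <- as.character(genome)
  glen <- nchar(gchar)
  total <- sum(as.numeric(glen))
  target <- coverage * total
  stopifnot(chimeraRate >= 0, chimeraRate <= 1,
            substRate >= 0, substRate <= 1)
  .withSeed(seed, {
    seqs <- character(0); truth <- list(); acc <- 0
    ri <- 0L
    pickScaffold <- function() sample.int(length(glen), 1L,
                                          prob = glen / total)
    segment <- function(sid, len) {
      len <- min(len, glen[sid])
      start <- sample.int(glen[sid] - len + 1L, 1L)
      list(sid = sid, start = start, seq = substr(gchar[sid], start,
                                                  start + len - 1L))
    }
    while (acc < target) {
      ri <- ri + 1L
      len <- as.integer(pmin(pmax(round(rlnorm(1, meanLog, sdLog)),
                                  minLen), maxLen))
      chim <- runif(1) < chimeraRate
      if (chim) {
        half <- len %/% 2L
        s1 <- segment(pickScaffold(), half)
        repeat {
          s2 <- segment(pickScaffold(), len - half)
          if (s2$sid != s1$sid || abs(s2$start - s1$start) >= 100000L) break
        }
        rseq <- paste0(s1$seq, s2$seq)
        tr <- data.frame(read_id = sprintf("read%06d", ri),
                         chimeric = TRUE, seq_id = names(genome)[s1$sid],
                         start = s1$start,
                         seq_id2 = names(genome)[s2$sid],
                         start2 = s2$start, length = nchar(rseq),
                         stringsAsFactors = FALSE)
      } else {
        s1 <- segment(pickScaffold(), len)
        rseq <- s1$seq
        tr <- data.frame(read_id = sprintf("read%06d", ri),
                         chimeric = FALSE, seq_id = names(genome)[s1$sid],
                         start = s1$start, seq_id2 = NA_character_,
                         start2 = NA_integer_, length = nchar(rseq),
                         stringsAsFactors = FALSE)
      }
      if (substRate > 0) {
        nSub <- rbinom(1L, nchar(rseq), substRate)
        if (nSub > 0L) {
          pos <- sample.int(nchar(rseq), nSub)
          for (p in pos) {
            old <- substr(rseq, p, p)
            new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
            substr(rseq, p, p) <- new
          }
        }
      }
      seqs[ri] <- rseq
      truth[[ri]] <- tr
      acc <- acc + nchar(rseq)
    }
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- sprintf("read%06d", seq_len(ri))
    mcols(reads) <- DataFrame(
      description = rep("", ri),
      quality = vapply(nchar(seqs), function(w) strrep("I", w),
                       character(1)))
    list(reads = reads,
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Build a merge scenario with a planted merge-failure duplication
#'
#' Constructs a reference assembly (contig \code{R1} carrying genes
#' g001-g005, plus background \code{R0}), a query assembly (\code{Q1},
#' which merges with \code{R1}, and \code{Q2}, which carries the same
#' gene set but fails to merge), and the resulting merged assembly whose
#' hybrid \code{H} concatenates \code{R1} and \code{Q1}. In the merged
#' BUSCO table the shared genes are Duplicated on \code{H} and \code{Q2}
#' — the merge-failure signature. An optional control plants a gene
#' duplicated within the query alone (\code{Q3}/\code{Q4}), which must be
#' labeled \code{preexisting}.
#'
#' @param seed integer seed.
#' @param includeUnmerged keep the unmerged \code{Q2} (default TRUE);
#'   without it no duplication arises.
#' @param includeControl add the preexisting-duplication control
#'   (default TRUE).
#' @param segLen length of each planted contig (default 30000).
#' @return list with \code{ref}, \code{query}, \code{merged}
#'   (\code{DNAStringSet}s), \code{refBusco}, \code{queryBusco},
#'   \code{mergedBusco}, \code{provenance} (data.frame), and \code{truth}
#'   (data.frame of expected duplicate cases).
#' @export
makeMergeScenario <- function(seed = 1L, includeUnmerged = TRUE,
                              includeControl = TRUE, segLen = 30000L) {
  segLen <- as.integer(segLen)
  nShared <- 5L
  .withSeed(seed, {
    mkSeg <- function() .randSeq(segLen)
    r1 <- mkSeg(); r0 <- mkSeg(); q1 <- mkSeg()
    geneLen <- 1500L
    gStart <- as.integer(seq(2000L, segLen - geneLen - 2000L,
                             length.out = nShared))
    genes <- sprintf("g%03d", seq_len(nShared))
    rec <- function(id, status, sid, s, e, score)
      data.frame(busco_id = id, status = status, seq_id = sid,
                 start = as.integer(s), end = as.integer(e + 0L),
                 score = score, length = geneLen, stringsAsFactors = FALSE)
    scores <- round(runif(nShared, 200, 300), 1)

    refRecs <- lapply(seq_len(nShared), function(i)
      rec(genes[i], "Complete", "R1", gStart[i],
          gStart[i] + geneLen - 1L, scores[i]))
    q2 <- mkSeg()
    qryRecs <- if (includeUnmerged)
      lapply(seq_len(nShared), function(i)
        rec(genes[i], "Complete", "Q2", gStart[i],
            gStart[i] + geneLen - 1L, scores[i]))
    else list()

    # merged assembly: hybrid H = R1 + Q1, plus survivors
    h <- paste0(r1, q1)
    mergedSeqs <- c(H = h, R0 = r0)
    prov <- data.frame(
      merged_id = c("H", "H", "R0"),
      component_id = c("R1", "Q1", "R0"),
      source = c("ref", "query", "ref"), stringsAsFactors = FALSE)
    mergedRecs <- lapply(seq_len(nShared), function(i)
      rec(genes[i], if (includeUnmerged) "Duplicated" else "Complete",
          "H", gStart[i], gStart[i] + geneLen - 1L, scores[i]))
    if (includeUnmerged) {
      mergedSeqs <- c(mergedSeqs, Q2 = q2)
      prov <- rbind(prov, data.frame(merged_id = "Q2", component_id = "Q2",
                                     source = "query"))
      mergedRecs <- c(mergedRecs, lapply(seq_len(nShared), function(i)
        rec(genes[i], "Duplicated", "Q2", gStart[i],
            gStart[i] + geneLen - 1L, scores[i])))
    }

    truth <- if (includeUnmerged)
      data.frame(busco_ids = paste(genes, collapse = ","),
                 carrier_seq_ids = "H,Q2", mechanism = "merge_failure",
                 stringsAsFactors = FALSE)
    else
      data.frame(busco_ids = character(0), carrier_seq_ids = character(0),
                 mechanism = character(0), stringsAsFactors = FALSE)

    querySeqs <- c(Q1 = q1)
    if (includeUnmerged) querySeqs <- c(querySeqs, Q2 = q2)
    if (includeControl) {
      q3 <- mkSeg(); q4 <- mkSeg()
      ctrlScore <- round(runif(1, 200, 300), 1)
      qryRecs <- c(qryRecs, list(
        rec("g006", "Duplicated", "Q3", 4000L, 4000L + geneLen - 1L,
            ctrlScore),
        rec("g006", "Duplicated", "Q4", 7000L, 7000L + geneLen - 1L,
            ctrlScore)))
      mergedRecs <- c(mergedRecs, list(
        rec("g006", "Duplicated", "Q3", 4000L, 4000L + geneLen - 1L,
            ctrlScore),
        rec("g006", "Duplicated", "Q4", 7000L, 7000L + geneLen - 1L,
            ctrlScore)))
      querySeqs <- c(querySeqs, Q3 = q3, Q4 = q4)
      mergedSeqs <- c(mergedSeqs, Q3 = q3, Q4 = q4)
      prov <- rbind(prov,
                    data.frame(merged_id = c("Q3", "Q4"),
                               component_id = c("Q3", "Q4"),
                               source = "query"))
      truth <- rbind(truth,
                     data.frame(busco_ids = "g006",
                                carrier_seq_ids = "Q3,Q4",
                                mechanism = "preexisting",
                                stringsAsFactors = FALSE))
    }

    asSet <- function(v) {
      x <- Biostrings::DNAStringSet(unname(v)); names(x) <- names(v); x
    }
    bt <- function(recs, nm) BuscoTable(
      if (length(recs)) do.call(rbind, c(recs, make.row.names = FALSE))
      else data.frame(), nm)
    list(
      ref = asSet(c(R1 = r1, R0 = r0)),
      query = asSet(querySeqs),
      merged = asSet(mergedSeqs),
      refBusco = bt(refRecs, "ref"),
      queryBusco = bt(qryRecs, "query"),
      mergedBusco = bt(mergedRecs, "merged"),
      provenance = prov,
      truth = truth)
  })
}
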