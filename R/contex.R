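#' Extract the flanking sequences of a donor gene
#'
#' Takes up to \code{flankLen} bases on each side of the gene interval
#' (1-based inclusive coordinates on the donor scaffold), truncating at
#' scaffold ends. A flank shorter than \code{k} cannot produce a single
#' k-mer and is marked unusable.
#'
#' @param donorSeq donor scaffold sequence (character or DNAString),
#'   already in the focal orientation.
#' @param geneStart,geneEnd 1-based inclusive gene coordinates.
#' @param flankLen flank length in bp (default 1000).
#' @param k k-mer size the anchors will use (usability threshold).
#' @return list with elements \code{left} and \code{right}, each a list
#'   \code{(start, end, seq, usable, truncated)} in donor coordinates;
#'   an absent flank (gene at the scaffold edge) has \code{seq = ""}.
#' @export
extractFlanks <- function(donorSeq, geneStart, geneEnd, flankLen = 1000L,
                          k = 31L) {
  if (methods::is(donorSeq, "DNAStringSet")) donorSeq <- donorSeq[[1L]]
  if (methods::is(donorSeq, "DNAString")) donorSeq <- as.character(donorSeq)
  len <- nchar(donorSeq)
  geneStart <- as.integer(geneStart); geneEnd <- as.integer(geneEnd)
  stopifnot(geneStart >= 1L, geneEnd <= len, geneStart <= geneEnd)
  ls <- max(1L, geneStart - as.integer(flankLen)); le <- geneStart - 1L
  rs <- geneEnd + 1L; re <- min(len, geneEnd + as.integer(flankLen))
  mk <- function(s, e, truncated) {
    w <- e - s + 1L
    list(start = s, end = e,
         seq = if (w >= 1L) substr(donorSeq, s, e) else "",
         usable = w >= k, truncated = truncated)
  }
  list(left = mk(ls, le, ls > geneStart - flankLen),
       right = mk(rs, re, re < geneEnd + flankLen))
}

.emptyPlans <- function() {
  data.frame(
    busco_id = character(0), focal_seq_id = character(0),
    donor_assembly_name = character(0), donor_seq_id = character(0),
    donor_start = integer(0), donor_end = integer(0),
    donor_score = numeric(0), orientation = character(0),
    status = character(0), reason = character(0),
    replaced_start = integer(0), replaced_end = integer(0),
    left_anchor_start = integer(0), left_anchor_end = integer(0),
    right_anchor_start = integer(0), right_anchor_end = integer(0),
    segment_len = integer(0), length_delta = integer(0),
    donor_segment_seq = character(0), stringsAsFactors = FALSE)
}

# One plan row, with NA defaults everywhere a stage did not run.
.planRow <- function(case, status, reason = NA_character_,
                     orientation = NA_character_,
                     replaced = c(NA_integer_, NA_integer_),
                     leftAnchor = c(NA_integer_, NA_integer_),
                     rightAnchor = c(NA_integer_, NA_integer_),
                     segSeq = NA_character_) {
  data.frame(
    busco_id = case$busco_id,
    focal_seq_id = case$focal_seq_id,
    donor_assembly_name = case$donor_assembly_name,
    donor_seq_id = case$donor_seq_id,
    donor_start = case$donor_start, donor_end = case$donor_end,
    donor_score = case$donor_score,
    orientation = orientation,
    status = status, reason = reason,
    replaced_start = replaced[1L], replaced_end = replaced[2L],
    left_anchor_start = leftAnchor[1L], left_anchor_end = leftAnchor[2L],
    right_anchor_start = rightAnchor[1L], right_anchor_end = rightAnchor[2L],
    segment_len = ifelse(is.na(segSeq), NA_integer_, nchar(segSeq)),
    length_delta = ifelse(is.na(segSeq) | is.na(replaced[1L]), NA_integer_,
                          nchar(segSeq) - (replaced[2L] - replaced[1L] + 1L)),
    donor_segment_seq = segSeq,
    stringsAsFactors = FALSE)
}

#' Plan the replacement of the contig(s) enclosing a fragmented gene
#'
#' Given resolved anchors for both donor flanks on the focal scaffold, the
#' replaced interval is the span of all focal contigs intersecting the
#' region between the anchors — the enclosing contig(s); interior gaps are
#' swallowed by the replacement, gaps outside it are untouched. The plan
#' is demoted to a skip when the anchors are out of order
#' (\code{skipped_inconsistent}) or when the replaced interval overlaps
#' another complete gene on the focal scaffold
#' (\code{skipped_neighbor_conflict}) — translocations that would disturb
#' neighboring genes are never applied.
#'
#' @param case one-row data.frame as produced by
#'   \code{\link{findRescuableGenes}} (a rescuable gene with its donor).
#' @param focalScaffold \linkS4class{Scaffold} of the focal carrier.
#' @param leftAnchor,rightAnchor anchor results from
#'   \code{\link{anchorFlank}} (or NULL when a flank was unusable).
#' @param orientation \code{"forward"}, \code{"reverse"} or
#'   \code{"ambiguous"}, from \code{\link{determineOrientation}}.
#' @param focalBusco the focal \linkS4class{BuscoTable} (neighbor-conflict
#'   check).
#' @param donorSegmentSeq the donor bases between the two flanks (the
#'   complete gene plus any inter-flank donor sequence), already oriented.
#' @return a one-row plan data.frame.
#' @export
planReplacement <- function(case, focalScaffold, leftAnchor, rightAnchor,
                            orientation, focalBusco, donorSegmentSeq) {
  if (identical(orientation, "ambiguous"))
    return(.planRow(case, "skipped_orientation", reason = "ambiguous",
                    orientation = orientation))
  anchorFailed <- function(a) is.null(a) || is.na(a$start)
  if (anchorFailed(leftAnchor) || anchorFailed(rightAnchor)) {
    reasons <- c(
      if (anchorFailed(leftAnchor))
        paste0("left:", if (is.null(leftAnchor)) "flank_unusable"
               else leftAnchor$reason),
      if (anchorFailed(rightAnchor))
        paste0("right:", if (is.null(rightAnchor)) "flank_unusable"
               else rightAnchor$reason))
    return(.planRow(case, "skipped_no_anchor",
                    reason = paste(reasons, collapse = ";"),
                    orientation = orientation))
  }
  la <- c(leftAnchor$start, leftAnchor$end)
  ra <- c(rightAnchor$start, rightAnchor$end)
  if (ra[1L] <= la[2L])
    return(.planRow(case, "skipped_inconsistent",
                    reason = "anchors_out_of_order",
                    orientation = orientation,
                    leftAnchor = la, rightAnchor = ra))
  if (ra[1L] - 1L < la[2L] + 1L)
    return(.planRow(case, "skipped_inconsistent",
                    reason = "anchors_adjacent", orientation = orientation,
                    leftAnchor = la, rightAnchor = ra))
  between <- IRanges::IRanges(la[2L] + 1L, ra[1L] - 1L)
  hits <- IRanges::findOverlaps(between, contigSpans(focalScaffold))
  if (length(hits) == 0L)
    return(.planRow(case, "skipped_inconsistent",
                    reason = "no_enclosing_contig",
                    orientation = orientation,
                    leftAnchor = la, rightAnchor = ra))
  enclosing <- contigSpans(focalScaffold)[S4Vectors::subjectHits(hits)]
  replaced <- c(min(IRanges::start(enclosing)), max(IRanges::end(enclosing)))
  # neighbor conflict: any OTHER complete gene on this scaffold inside the
  # interval that would be rewritten
  fr <- buscoRecords(focalBusco)
  nb <- fr[fr$status %in% c("Complete", "Duplicated") &
           !is.na(fr$seq_id) & fr$seq_id == case$focal_seq_id &
           fr$busco_id != case$busco_id &
           !is.na(fr$start) & !is.na(fr$end), , drop = FALSE]
  if (nrow(nb) && any(nb$start <= replaced[2L] & nb$end >= replaced[1L]))
    return(.planRow(case, "skipped_neighbor_conflict",
                    reason = paste0("overlaps:", paste(
                      nb$busco_id[nb$start <= replaced[2L] &
                                  nb$end >= replaced[1L]], collapse = ",")),
                    orientation = orientation, replaced = replaced,
                    leftAnchor = la, rightAnchor = ra))
  .planRow(case, "applied", orientation = orientation, replaced = replaced,
           leftAnchor = la, rightAnchor = ra, segSeq = donorSegmentSeq)
}

# Overlapping applied plans on one scaffold: keep the higher donor score
# (earlier row on ties), demote the rest to skipped_inconsistent.
.resolvePlanConflicts <- function(plans) {
  app <- which(plans$status == "applied")
  if (length(app) < 2L) return(plans)
  ord <- app[order(-plans$donor_score[app], app)]
  kept <- list()
  for (i in ord) {
    sid <- plans$focal_seq_id[i]
    clash <- any(vapply(kept, function(j) {
      plans$focal_seq_id[j] == sid &&
        plans$replaced_start[i] <= plans$replaced_end[j] &&
        plans$replaced_end[i] >= plans$replaced_start[j]
    }, logical(1)))
    if (clash) {
      plans$status[i] <- "skipped_inconsistent"
      plans$reason[i] <- "overlaps_higher_scoring_plan"
      plans$donor_segment_seq[i] <- NA_character_
      plans$length_delta[i] <- NA_integer_
      plans$segment_len[i] <- NA_integer_
    } else kept[[length(kept) + 1L]] <- i
  }
  plans
}

#' Apply replacement plans to an assembly
#'
#' Substitutes each applied plan's replaced interval with its donor
#' segment; every base outside the replaced intervals — including all gap
#' spans — is untouched. Applied plans on one scaffold must have disjoint
#' replaced intervals (conflicts are resolved upstream, in
#' \code{\link{correctAssembly}}, by donor score then input order).
#'
#' @param assembly named \code{DNAStringSet}.
#' @param plans plan data.frame (any mix of statuses; only
#'   \code{applied} rows edit the assembly).
#' @param params list of run parameters recorded in the report.
#' @param unrescuable data.frame of fragmented genes with no donor.
#' @return list with \code{assembly} (corrected \code{DNAStringSet}) and
#'   \code{report} (\linkS4class{CorrectionReport}).
#' @export
applyReplacements <- function(assembly, plans, params = list(),
                              unrescuable = NULL) {
  assembly <- .asSeqSet(assembly)
  if (is.null(unrescuable))
    unrescuable <- data.frame(busco_id = character(0),
                              reason = character(0),
                              stringsAsFactors = FALSE)
  app <- plans[plans$status == "applied", , drop = FALSE]
  seqs <- as.character(assembly)
  delta <- setNames(numeric(0), character(0))
  if (nrow(app)) {
    missing <- setdiff(app$focal_seq_id, names(seqs))
    if (length(missing))
      stop("applied plan references unknown scaffold '", missing[1L], "'",
           call. = FALSE)
    for (sid in unique(app$focal_seq_id)) {
      p <- app[app$focal_seq_id == sid, , drop = FALSE]
      o <- order(p$replaced_start)
      if (any(p$replaced_start[o][-1L] <= p$replaced_end[o][-nrow(p)]))
        stop("overlapping applied plans on scaffold '", sid,
             "' must be resolved before applyReplacements()", call. = FALSE)
      s <- seqs[[sid]]
      for (i in rev(o)) {    # right-to-left keeps left coordinates valid
        s <- paste0(substr(s, 1L, p$replaced_start[i] - 1L),
                    p$donor_segment_seq[i],
                    substr(s, p$replaced_end[i] + 1L, nchar(s)))
      }
      delta[sid] <- sum(nchar(p$donor_segment_seq) -
                        (p$replaced_end - p$replaced_start + 1L))
      seqs[[sid]] <- s
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(assembly)
  mcols(out) <- mcols(assembly)
  report <- methods::new("CorrectionReport", plans = plans,
                         unrescuable = unrescuable,
                         lengthDelta = delta, params = params)
  list(assembly = out, report = report)
}

#' Rescue fragmented genes by k-mer-anchored contig replacement
#'
#' End-to-end cross-assembly correction: identifies genes fragmented in
#' the focal assembly but complete and single-copy in an alternative
#' assembly, syncs the orientation of each donor scaffold by shared k-mer
#' majority, anchors the donor gene's flanking sequences on the focal
#' scaffold via unique collinear k-mer matching, and replaces the focal
#' contig(s) enclosing the fragmented gene with the donor segment between
#' the flanks. Cases that cannot be translocated safely — ambiguous
#' orientation, unanchorable (e.g. repeat-borne) flanks, interference
#' with a neighboring complete gene, or inconsistent anchors — are
#' skipped with the reason recorded, and the accounting always conserves:
#' identified = applied + skipped.
#'
#' @param focal focal assembly: named \code{DNAStringSet} or FASTA path.
#' @param focalBusco focal \linkS4class{BuscoTable} or full_table path.
#' @param donors list of donor assemblies (\code{DNAStringSet}s or FASTA
#'   paths), in tie-break priority order.
#' @param donorBuscos list of matching \linkS4class{BuscoTable}s or paths.
#' @param k k-mer size for orientation and anchoring (default 31).
#' @param flankLen donor flank length in bp (default 1000).
#' @param minShared minimum shared k-mers for an orientation call.
#' @param minMatchFrac minimum unique-collinear k-mer fraction per flank.
#' @param minGapLen contig-breaking N-run length on the focal scaffold.
#' @return list with \code{assembly} (corrected \code{DNAStringSet}) and
#'   \code{report} (\linkS4class{CorrectionReport}).
#' @export
correctAssembly <- function(focal, focalBusco, donors, donorBuscos,
                            k = 31L, flankLen = 1000L, minShared = 50L,
                            minMatchFrac = 0.8, minGapLen = 10L) {
  if (is.character(focal) && length(focal) == 1L && file.exists(focal))
    focal <- readSequences(focal)
  if (is.character(focalBusco)) focalBusco <- parseBuscoFullTable(focalBusco)
  if (methods::is(donors, "DNAStringSet")) donors <- list(donors)
  if (methods::is(donorBuscos, "BuscoTable")) donorBuscos <- list(donorBuscos)
  stopifnot(length(donors) == length(donorBuscos))
  donors <- lapply(donors, function(d)
    if (is.character(d)) readSequences(d) else .asSeqSet(d))
  donorBuscos <- lapply(donorBuscos, function(b)
    if (is.character(b)) parseBuscoFullTable(b) else b)
  names(donors) <- vapply(donorBuscos, assemblyName, character(1))

  params <- list(k = as.integer(k), flankLen = as.integer(flankLen),
                 minShared = as.integer(minShared),
                 minMatchFrac = minMatchFrac,
                 minGapLen = as.integer(minGapLen))

  if (length(donors) == 0L)
    return(applyReplacements(focal, .emptyPlans(), params = params))

  rescue <- findRescuableGenes(focalBusco, donorBuscos)
  cases <- rescue$cases

  idxCache <- new.env(parent = emptyenv())
  scafCache <- new.env(parent = emptyenv())
  focalIndexOf <- function(sid) {
    if (is.null(idxCache[[sid]])) {
      if (!sid %in% names(focal))
        stop("focal scaffold '", sid, "' referenced by the BUSCO table is ",
             "absent from the assembly", call. = FALSE)
      idxCache[[sid]] <- kmerIndex(focal[[sid]], k = k, id = sid)
    }
    idxCache[[sid]]
  }
  focalScaffoldOf <- function(sid) {
    if (is.null(scafCache[[sid]]))
      scafCache[[sid]] <- segmentScaffold(focal[[sid]], minGapLen = minGapLen,
                                          id = sid)
    scafCache[[sid]]
  }

  plans <- lapply(seq_len(nrow(cases)), function(ci) {
    case <- cases[ci, , drop = FALSE]
    donorAsm <- donors[[case$donor_assembly_name]]
    if (!case$donor_seq_id %in% names(donorAsm))
      stop("donor scaffold '", case$donor_seq_id, "' absent from assembly '",
           case$donor_assembly_name, "'", call. = FALSE)
    dseq <- as.character(donorAsm[[case$donor_seq_id]])
    fidx <- focalIndexOf(case$focal_seq_id)
    orientation <- determineOrientation(fidx, dseq, minShared = minShared)
    if (orientation == "ambiguous")
      return(planReplacement(case, focalScaffoldOf(case$focal_seq_id),
                             NULL, NULL, "ambiguous", focalBusco, NA))
    gs <- case$donor_start; ge <- case$donor_end
    if (orientation == "reverse") {
      len <- nchar(dseq)
      dseq <- .revcomChar(dseq)
      tmp <- gs
      gs <- len - ge + 1L
      ge <- len - tmp + 1L
    }
    fl <- extractFlanks(dseq, gs, ge, flankLen = flankLen, k = k)
    leftAnchor <- if (fl$left$usable)
      anchorFlank(fidx, fl$left$seq, minMatchFrac = minMatchFrac) else NULL
    rightAnchor <- if (fl$right$usable)
      anchorFlank(fidx, fl$right$seq, minMatchFrac = minMatchFrac) else NULL
    seg <- substr(dseq, gs, ge)
    planReplacement(case, focalScaffoldOf(case$focal_seq_id),
                    leftAnchor, rightAnchor, orientation, focalBusco, seg)
  })
  plans <- if (length(plans)) do.call(rbind, c(plans, make.row.names = FALSE))
           else .emptyPlans()
  plans <- .resolvePlanConflicts(plans)
  applyReplacements(focal, plans, params = params,
                    unrescuable = rescue$unrescuable)
}

#' Write a CorrectionReport as TSV
#'
#' One row per rescuable case (the plan table, without the raw donor
#' segment sequence) followed by nothing else; unrescuable genes go to a
#' companion file when \code{unrescuablePath} is given.
#'
#' @param report a \linkS4class{CorrectionReport}.
#' @param path output TSV path.
#' @param unrescuablePath optional TSV path for the no-donor genes.
#' @return \code{path}, invisibly.
#' @export
writeCorrectionReport <- function(report, path, unrescuablePath = NULL) {
  stopifnot(methods::is(report, "CorrectionReport"))
  p <- replacementPlans(report)
  p$donor_segment_seq <- NULL
  .writeTsv(p, path)
  if (!is.null(unrescuablePath))
    .writeTsv(unrescuableGenes(report), unrescuablePath)
  invisible(path)
}
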