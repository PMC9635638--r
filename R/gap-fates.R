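#' Classify the fate of every pre-assembly gap after gap filling
#'
#' For each N-run gap of the pre-assembly, the \code{flankLen} bases on
#' either side of the gap are anchored in the post (gap-filled) assembly
#' with the same unique, collinear k-mer machinery used for gene
#' translocation (\code{\link{anchorFlank}}). When both flanks anchor on
#' one post sequence in order, the inter-flank distance and its residual N
#' count decide the fate:
#' \itemize{
#'   \item \code{closed}: no N left between the flanks;
#'   \item \code{partially_filled}: N remains and the inter-flank span is
#'     no longer than the original gap;
#'   \item \code{overfilled}: N remains and the span grew — reads
#'     extended inward from both sides without meeting, expanding the gap
#'     instead of closing it;
#'   \item \code{unresolved}: a flank failed to anchor, anchored on
#'     several sequences, or the anchors are discordant.
#' }
#'
#' @param pre pre-assembly (named \code{DNAStringSet} or FASTA path).
#' @param post post-assembly (same forms).
#' @param k k-mer size for anchoring (default 31).
#' @param flankLen flank length in bp (default 500).
#' @param minGapLen contig-breaking N-run length in the pre-assembly.
#' @param minMatchFrac minimum unique-collinear k-mer fraction per flank.
#' @return data.frame with one row per pre-assembly gap: \code{gap_id},
#'   \code{pre_seq_id}, \code{gap_index}, \code{original_len},
#'   \code{post_seq_id}, \code{post_interflank_len}, \code{residual_n},
#'   \code{klass}.
#' @export
classifyGapFates <- function(pre, post, k = 31L, flankLen = 500L,
                             minGapLen = 10L, minMatchFrac = 0.8) {
  if (is.character(pre) && length(pre) == 1L && file.exists(pre))
    pre <- readSequences(pre)
  if (is.character(post) && length(post) == 1L && file.exists(post))
    post <- readSequences(post)
  pre <- .asSeqSet(pre); post <- .asSeqSet(post)

  postIdx <- lapply(seq_along(post), function(i)
    kmerIndex(post[[i]], k = k, id = names(post)[i]))
  names(postIdx) <- names(post)
  postChar <- as.character(post)

  rows <- list()
  for (si in seq_along(pre)) {
    sid <- names(pre)[si]
    sc <- segmentScaffold(pre[[si]], minGapLen = minGapLen, id = sid)
    g <- gapSpans(sc)
    if (!length(g)) next
    preSeq <- as.character(scaffoldSeq(sc))
    for (gi in seq_along(g)) {
      gs <- IRanges::start(g)[gi]; ge <- IRanges::end(g)[gi]
      origLen <- ge - gs + 1L
      lf <- substr(preSeq, max(1L, gs - flankLen), gs - 1L)
      rf <- substr(preSeq, ge + 1L, min(nchar(preSeq), ge + flankLen))
      fate <- .gapFateOne(lf, rf, postIdx, postChar, k, origLen,
                          minMatchFrac)
      rows[[length(rows) + 1L]] <- data.frame(
        gap_id = paste0(sid, ":gap", gi),
        pre_seq_id = sid, gap_index = gi, original_len = origLen,
        post_seq_id = fate$post_seq_id,
        post_interflank_len = fate$len, residual_n = fate$nres,
        klass = fate$klass, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gap_id = character(0), pre_seq_id = character(0),
                      gap_index = integer(0), original_len = integer(0),
                      post_seq_id = character(0),
                      post_interflank_len = integer(0),
                      residual_n = integer(0), klass = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

.gapFateOne <- function(leftFlank, rightFlank, postIdx, postChar, k,
                        origLen, minMatchFrac) {
  unresolved <- list(post_seq_id = NA_character_, len = NA_integer_,
                     nres = NA_integer_, klass = "unresolved")
  if (nchar(leftFlank) < k || nchar(rightFlank) < k) return(unresolved)
  hits <- list()
  for (pid in names(postIdx)) {
    la <- anchorFlank(postIdx[[pid]], leftFlank, minMatchFrac = minMatchFrac)
    if (is.na(la$start)) next
    ra <- anchorFlank(postIdx[[pid]], rightFlank, minMatchFrac = minMatchFrac)
    if (is.na(ra$start)) next
    hits[[pid]] <- list(la = la, ra = ra)
  }
  if (length(hits) != 1L) return(unresolved)
  pid <- names(hits)[1L]
  la <- hits[[1L]]$la; ra <- hits[[1L]]$ra
  if (ra$start <= la$end) return(unresolved)       # discordant order
  s <- la$end + 1L; e <- ra$start - 1L
  len <- e - s + 1L
  if (len < 0L) len <- 0L
  inter <- if (len > 0L) substr(postChar[[pid]], s, e) else ""
  nres <- .countN(inter)
  klass <- if (nres == 0L) "closed"
           else if (len > origLen) "overfilled"
           else "partially_filled"
  list(post_seq_id = pid, len = len, nres = nres, klass = klass)
}
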