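#' Segment a scaffold into contig and gap spans
#'
#' A gap is a maximal run of at least \code{minGapLen} consecutive N bases;
#' everything between gaps is a contig (shorter N runs stay inside their
#' contig). Spans are IRanges (1-based, closed) that tile the sequence.
#'
#' @param seq a \code{DNAString}, single-element \code{DNAStringSet}, or
#'   character string over {A,C,G,T,N}.
#' @param minGapLen minimum N-run length (bp) that breaks a contig;
#'   default 10 matches common contiguity-tool behavior.
#' @param id scaffold id; taken from \code{names(seq)} when available.
#' @return a \linkS4class{Scaffold}.
#' @examples
#' sc <- segmentScaffold(paste0("ACGT", strrep("N", 10), "TTGA"))
#' contigSpans(sc)
#' gapSpans(sc)
#' @export
segmentScaffold <- function(seq, minGapLen = 10L, id = NULL) {
  if (is.null(id)) id <- names(seq)[1L]
  if (is.null(id) || is.na(id)) id <- "scaffold"
  if (methods::is(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(.normalizeSeq(seq))
  minGapLen <- as.integer(minGapLen)
  stopifnot(minGapLen >= 1L)
  len <- length(seq)
  nruns <- Biostrings::matchPattern("N", seq)
  nruns <- IRanges::reduce(methods::as(nruns, "IRanges"))
  gapsR <- nruns[IRanges::width(nruns) >= minGapLen]
  contigsR <- IRanges::setdiff(IRanges::IRanges(1L, len), gapsR)
  methods::new("Scaffold", id = as.character(id), seq = seq,
               contigs = contigsR, gaps = gapsR, minGapLen = minGapLen)
}

#' Contiguity statistics for an assembly
#'
#' Computes the usual assembly report card: scaffold and contig counts and
#' totals, scaffold/contig N50, largest scaffold, and Ns per 100 kb
#' (\code{1e5 * totalN / total_scaffold_len}). Contigs are obtained by
#' segmenting every scaffold at N runs of at least \code{minGapLen}.
#'
#' N50 is the smallest length L such that sequences of length >= L sum to
#' at least half the total; it is always one of the observed lengths.
#'
#' @param assembly a named \code{DNAStringSet} (or character vector).
#' @param minGapLen contig-breaking N-run length, as in
#'   \code{\link{segmentScaffold}}.
#' @return a one-row data.frame with columns \code{n_scaffolds},
#'   \code{n_contigs}, \code{total_scaffold_len}, \code{total_contig_len},
#'   \code{scaffold_n50}, \code{contig_n50}, \code{largest},
#'   \code{ns_per_100kb}.
#' @export
assemblyStats <- function(assembly, minGapLen = 10L) {
  assembly <- .asSeqSet(assembly)
  if (length(assembly) == 0L) stop("empty assembly", call. = FALSE)
  scafLens <- BiocGenerics::width(assembly)
  nCounts <- Biostrings::letterFrequency(assembly, "N")[, 1L]
  contigLens <- unlist(lapply(seq_along(assembly), function(i) {
    sc <- segmentScaffold(assembly[[i]], minGapLen = minGapLen,
                          id = names(assembly)[i])
    IRanges::width(contigSpans(sc))
  }))
  totalScaf <- sum(as.numeric(scafLens))
  data.frame(
    n_scaffolds = length(assembly),
    n_contigs = length(contigLens),
    total_scaffold_len = totalScaf,
    total_contig_len = sum(as.numeric(contigLens)),
    scaffold_n50 = n50(scafLens),
    contig_n50 = n50(contigLens),
    largest = max(scafLens),
    ns_per_100kb = 1e5 * sum(as.numeric(nCounts)) / totalScaf
  )
}

#' N50 of a set of lengths
#'
#' Smallest length L, present in the input, such that all lengths >= L sum
#' to at least half the total.
#'
#' @param lengths positive integer lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0L, all(lengths > 0))
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  l[which(cumsum(l) >= sum(l) / 2)[1L]]
}

#' Reverse complement every scaffold of an assembly
#'
#' A <-> T, C <-> G, N -> N, order reversed; ids and their order are
#' preserved. Useful for probing orientation-dependent gene
#' classifications.
#'
#' @param assembly a named \code{DNAStringSet} (or character vector).
#' @return a \code{DNAStringSet} of the same names and widths.
#' @export
reverseComplementAssembly <- function(assembly) {
  assembly <- .asSeqSet(assembly)
  out <- Biostrings::reverseComplement(assembly)
  names(out) <- names(assembly)
  out
}

#' Split a scaffold into two at one of its gaps
#'
#' Breaks the scaffold at the chosen gap, dropping the gap's N bases; the
#' two products are named \code{<id>.1} and \code{<id>.2}, so
#' \code{length(left) + length(right) + gap width = original length}.
#'
#' @param scaffold a \linkS4class{Scaffold} (or a sequence accepted by
#'   \code{\link{segmentScaffold}}).
#' @param gapIndex 1-based index into the scaffold's gap list.
#' @param minGapLen used only when \code{scaffold} is a raw sequence.
#' @return a named \code{DNAStringSet} of length 2.
#' @export
splitScaffoldAtGap <- function(scaffold, gapIndex, minGapLen = 10L) {
  if (!methods::is(scaffold, "Scaffold"))
    scaffold <- segmentScaffold(scaffold, minGapLen = minGapLen)
  g <- gapSpans(scaffold)
  gapIndex <- as.integer(gapIndex)
  if (length(g) == 0L)
    stop("scaffold '", scaffoldId(scaffold), "' has no gaps", call. = FALSE)
  if (gapIndex < 1L || gapIndex > length(g))
    stop("gapIndex ", gapIndex, " out of range (scaffold has ",
         length(g), " gaps)", call. = FALSE)
  s <- scaffoldSeq(scaffold)
  left <- Biostrings::subseq(s, 1L, IRanges::start(g)[gapIndex] - 1L)
  right <- Biostrings::subseq(s, IRanges::end(g)[gapIndex] + 1L, length(s))
  out <- Biostrings::DNAStringSet(list(left, right))
  names(out) <- paste0(scaffoldId(scaffold), c(".1", ".2"))
  out
}
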