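#' KmerIndex: positions of every N-free k-mer on one scaffold strand
#'
#' Maps each k-mer (forward strand only) of one scaffold to its sorted
#' 1-based start positions. The index is the anchoring substrate for
#' cross-assembly gene translocation and gap-fate classification.
#'
#' @slot k k-mer size (odd, default 31).
#' @slot seqId id of the indexed scaffold.
#' @slot seqLen scaffold length in bp.
#' @slot table a \code{data.table} with columns \code{kmer}, \code{pos},
#'   keyed by \code{kmer}; N-containing k-mers are excluded.
#' @slot counts a \code{data.table} (kmer, n) of occurrence counts.
#'
#' @exportClass KmerIndex
setClass("KmerIndex",
  representation(k = "integer", seqId = "character", seqLen = "integer",
                 table = "ANY", counts = "ANY"))

# All k-mers of a character sequence, in position order; entries containing
# N are returned as NA so callers can keep positional bookkeeping.
.kmerize <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  km <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  km[grepl("N", km, fixed = TRUE)] <- NA_character_
  km
}

#' Build a k-mer position index for one scaffold
#'
#' @param seq scaffold sequence (character, \code{DNAString}, or
#'   single-element \code{DNAStringSet}).
#' @param k k-mer size; default 31, must be odd so no k-mer is its own
#'   reverse complement.
#' @param id scaffold id recorded in the index.
#' @return a \linkS4class{KmerIndex}.
#' @export
kmerIndex <- function(seq, k = 31L, id = NULL) {
  if (is.null(id)) id <- names(seq)[1L]
  if (is.null(id) || is.na(id)) id <- "scaffold"
  if (methods::is(seq, "DNAStringSet")) seq <- seq[[1L]]
  if (methods::is(seq, "DNAString")) seq <- as.character(seq)
  k <- as.integer(k)
  stopifnot(k >= 3L, k %% 2L == 1L, nchar(seq) >= k)
  km <- .kmerize(seq, k)
  keep <- !is.na(km)
  dt <- data.table(kmer = km[keep], pos = which(keep))
  setkey(dt, kmer)
  counts <- dt[, list(n = .N), by = "kmer"]
  setkey(counts, kmer)
  methods::new("KmerIndex", k = k, seqId = as.character(id),
               seqLen = nchar(seq), table = dt, counts = counts)
}

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex of '", object@seqId, "': ", object@seqLen, " bp, k=",
      object@k, ", ", nrow(object@counts), " distinct k-mer(s)\n", sep = "")
})

#' Decide the relative orientation of a donor scaffold
#'
#' Counts how many donor k-mers (forward, and of the donor's reverse
#' complement) occur anywhere in the focal scaffold's index. The majority
#' orientation wins only when its count reaches \code{minShared} and is at
#' least twice the opposing count; anything weaker is \code{ambiguous} and
#' the donor is not used — an ambiguous orientation is one of the
#' documented reasons a gene cannot be safely translocated.
#'
#' @param focalIndex \linkS4class{KmerIndex} of the focal scaffold.
#' @param donorSeq donor scaffold sequence.
#' @param minShared minimum shared k-mer count for a call (default 50).
#' @return \code{"forward"}, \code{"reverse"} or \code{"ambiguous"}.
#' @export
determineOrientation <- function(focalIndex, donorSeq, minShared = 50L) {
  stopifnot(methods::is(focalIndex, "KmerIndex"))
  if (methods::is(donorSeq, "DNAStringSet")) donorSeq <- donorSeq[[1L]]
  if (methods::is(donorSeq, "DNAString")) donorSeq <- as.character(donorSeq)
  k <- focalIndex@k
  if (nchar(donorSeq) < k) return("ambiguous")
  countShared <- function(s) {
    km <- .kmerize(s, k)
    km <- km[!is.na(km)]
    if (!length(km)) return(0L)
    hits <- focalIndex@counts[data.table(kmer = km), on = "kmer",
                              nomatch = NULL]
    nrow(hits)
  }
  fwd <- countShared(donorSeq)
  rev <- countShared(.revcomChar(donorSeq))
  hi <- max(fwd, rev); lo <- min(fwd, rev)
  if (hi >= minShared && hi >= 2L * lo)
    if (fwd >= rev) "forward" else "reverse"
  else "ambiguous"
}

# Longest strictly increasing subsequence: returns the indices (into x) of
# one optimal subsequence, via patience sorting with predecessor links.
.lisIndices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)      # smallest tail value per LIS length
  tailIdx <- integer(0)    # index into x achieving that tail
  prev <- integer(n)       # predecessor links
  for (i in seq_len(n)) {
    pos <- findInterval(x[i] - 0.5, tails) + 1L
    prev[i] <- if (pos > 1L) tailIdx[pos - 1L] else 0L
    tails[pos] <- x[i]
    tailIdx[pos] <- i
  }
  out <- integer(length(tails))
  j <- tailIdx[length(tailIdx)]
  for (p in rev(seq_along(out))) { out[p] <- j; j <- prev[j] }
  out
}

#' Anchor a donor flank on a focal scaffold by unique, collinear k-mers
#'
#' Matches the flank's N-free k-mers against the focal index, keeping only
#' k-mers that occur exactly once on the focal scaffold (repeat-borne
#' k-mers would invite mistranslocation). The anchor is accepted when at
#' least \code{minMatchFrac} of the flank's N-free k-mers participate in a
#' collinear, strictly increasing run of focal positions; the anchored
#' interval spans from the first to the last matched position plus k-1.
#'
#' @param focalIndex \linkS4class{KmerIndex} of the focal scaffold.
#' @param flankSeq flank sequence (character or DNAString), length >= k.
#' @param minMatchFrac minimum fraction of N-free flank k-mers that must
#'   match uniquely and collinearly (default 0.8).
#' @return a list with \code{start}, \code{end} (1-based inclusive focal
#'   coordinates, NA on failure), \code{matchedFrac}, and \code{reason}
#'   (NA on success; otherwise \code{no_unique_kmers}, \code{below_frac}
#'   or \code{non_collinear}).
#' @export
anchorFlank <- function(focalIndex, flankSeq, minMatchFrac = 0.8) {
  stopifnot(methods::is(focalIndex, "KmerIndex"))
  if (methods::is(flankSeq, "DNAStringSet")) flankSeq <- flankSeq[[1L]]
  if (methods::is(flankSeq, "DNAString")) flankSeq <- as.character(flankSeq)
  k <- focalIndex@k
  fail <- function(reason, frac = 0) list(
    start = NA_integer_, end = NA_integer_, matchedFrac = frac,
    reason = reason)
  if (nchar(flankSeq) < k) return(fail("no_unique_kmers"))
  km <- .kmerize(flankSeq, k)
  ok <- !is.na(km)
  nFree <- sum(ok)
  if (nFree == 0L) return(fail("no_unique_kmers"))
  # unique-on-focal k-mers only
  cnt <- focalIndex@counts[data.table(kmer = km[ok]), on = "kmer"]
  uniq <- !is.na(cnt$n) & cnt$n == 1L
  if (!any(uniq)) return(fail("no_unique_kmers"))
  hit <- focalIndex@table[data.table(kmer = km[ok][uniq]), on = "kmer",
                          mult = "first"]
  posSeq <- hit$pos                    # focal positions in flank order
  matchedFrac <- length(posSeq) / nFree
  lis <- .lisIndices(posSeq)
  lisFrac <- length(lis) / nFree
  if (lisFrac >= minMatchFrac) {
    runPos <- posSeq[lis]
    return(list(start = min(runPos), end = max(runPos) + k - 1L,
                matchedFrac = lisFrac, reason = NA_character_))
  }
  if (matchedFrac >= minMatchFrac) fail("non_collinear", lisFrac)
  else fail("below_frac", matchedFrac)
}
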