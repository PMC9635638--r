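#' Construct a SamplingSpec
#'
#' Parameters of a seeded, length-windowed subsample of long reads to a
#' target coverage. The genome size is always supplied explicitly —
#' coverage means \code{total bases / genomeSize} and nothing else.
#'
#' @param genomeSize estimated genome size in bp.
#' @param targetCoverage target fold coverage (e.g. 70).
#' @param minLen,maxLen inclusive read-length window in bp; \code{maxLen}
#'   may be \code{Inf} for no upper bound.
#' @param seed integer seed; the selection is a pure function of
#'   (reads, spec).
#' @return a \linkS4class{SamplingSpec}.
#' @export
SamplingSpec <- function(genomeSize, targetCoverage, minLen = 1,
                         maxLen = Inf, seed = 1L) {
  methods::new("SamplingSpec", genomeSize = as.numeric(genomeSize),
               targetCoverage = as.numeric(targetCoverage),
               minLen = as.numeric(minLen), maxLen = as.numeric(maxLen),
               seed = as.integer(seed))
}

#' Partition reads by an inclusive length window
#'
#' @param reads named \code{DNAStringSet} (or character vector).
#' @param minLen,maxLen inclusive bounds in bp (\code{maxLen} may be Inf).
#' @return list with \code{eligible} (the retained \code{DNAStringSet}),
#'   and counts \code{nEligible}, \code{nExcludedShort},
#'   \code{nExcludedLong} partitioning the input.
#' @export
filterByLength <- function(reads, minLen = 1, maxLen = Inf) {
  reads <- .asSeqSet(reads)
  w <- BiocGenerics::width(reads)
  short <- w < minLen
  long <- w > maxLen
  keep <- !short & !long
  list(eligible = reads[keep],
       nEligible = sum(keep),
       nExcludedShort = sum(short),
       nExcludedLong = sum(long))
}

#' Randomly subsample reads to a target coverage
#'
#' Draws reads uniformly at random without replacement from the
#' length-eligible pool, in an order fully determined by the spec's seed,
#' stopping as soon as the cumulative bases reach
#' \code{genomeSize * targetCoverage} — the read that crosses the
#' threshold is included, so when the pool suffices,
#' \code{target <= totalBases < target + maxLen}. If the eligible pool
#' holds fewer bases than the target, every eligible read is returned and
#' the result is flagged \code{exhausted} (a partial draw is a normal
#' outcome, not an error); an empty eligible pool is an error.
#'
#' @param reads named \code{DNAStringSet} (or character vector). Multiple
#'   input files should be concatenated before the call; the seeded
#'   permutation is over the whole pool.
#' @param spec a \linkS4class{SamplingSpec}.
#' @return a \linkS4class{SampleResult}.
#' @examples
#' reads <- setNames(rep(strrep("A", 100), 20), paste0("r", 1:20))
#' sampleToCoverage(reads, SamplingSpec(1000, 1, seed = 7))
#' @export
sampleToCoverage <- function(reads, spec) {
  reads <- .asSeqSet(reads)
  stopifnot(methods::is(spec, "SamplingSpec"))
  methods::validObject(spec)
  flt <- filterByLength(reads, spec@minLen, spec@maxLen)
  if (flt$nEligible == 0L)
    stop("no reads are eligible under the length window [",
         spec@minLen, ", ", spec@maxLen, "]", call. = FALSE)
  elig <- flt$eligible
  w <- as.numeric(BiocGenerics::width(elig))
  target <- spec@genomeSize * spec@targetCoverage
  perm <- .withSeed(spec@seed, sample.int(length(elig)))
  cum <- cumsum(w[perm])
  if (cum[length(cum)] < target) {
    takeIdx <- perm
    exhausted <- TRUE
    warning("eligible pool exhausted at ",
            round(cum[length(cum)] / spec@genomeSize, 2),
            "x of the ", spec@targetCoverage, "x target", call. = FALSE)
  } else {
    nTake <- which(cum >= target)[1L]
    takeIdx <- perm[seq_len(nTake)]
    exhausted <- FALSE
  }
  total <- sum(w[takeIdx])
  methods::new("SampleResult",
               selectedIds = names(elig)[takeIdx],
               totalBases = total,
               achievedCoverage = total / spec@genomeSize,
               nEligible = as.integer(flt$nEligible),
               nExcludedShort = as.integer(flt$nExcludedShort),
               nExcludedLong = as.integer(flt$nExcludedLong),
               exhausted = exhausted,
               spec = spec)
}

#' Write a subsample and its reconstruction report
#'
#' Writes exactly the selected reads, in selection order, in the requested
#' format (FASTQ preserves the qualities retained by
#' \code{\link{readSequences}}), plus a one-row TSV report carrying the
#' full spec — including the seed — so the run can be reconstructed.
#'
#' @param reads the read set the result was drawn from.
#' @param result a \linkS4class{SampleResult}.
#' @param path output sequence file; \code{.gz} compresses.
#' @param format \code{"fasta"} or \code{"fastq"} (default matches the
#'   path extension, falling back to fasta).
#' @param reportPath optional TSV report path.
#' @return \code{path}, invisibly.
#' @export
writeSample <- function(reads, result, path, format = NULL,
                        reportPath = NULL) {
  reads <- .asSeqSet(reads)
  stopifnot(methods::is(result, "SampleResult"))
  ids <- selectedIds(result)
  missing <- setdiff(ids, names(reads))
  if (length(missing))
    stop("selected id '", missing[1L], "' is absent from the read set",
         call. = FALSE)
  sel <- reads[ids]
  if (is.null(format))
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  if (format == "fastq") writeFastq(sel, path) else writeFasta(sel, path)
  if (!is.null(reportPath)) {
    sp <- result@spec
    .writeTsv(data.frame(
      genome_size_bp = sp@genomeSize, target_coverage = sp@targetCoverage,
      min_len = sp@minLen, max_len = sp@maxLen, seed = sp@seed,
      n_selected = length(ids), total_bases = result@totalBases,
      achieved_coverage = result@achievedCoverage,
      n_eligible = result@nEligible,
      n_excluded_short = result@nExcludedShort,
      n_excluded_long = result@nExcludedLong,
      exhausted = result@exhausted), reportPath)
  }
  invisible(path)
}
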