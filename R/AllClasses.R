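#' Scaffold: a sequence segmented into contig and gap spans
#'
#' A scaffold is a single assembly sequence together with its segmentation
#' into contigs (gap-free spans) and gaps (maximal runs of at least
#' \code{minGapLen} consecutive N bases). Spans are stored as
#' \link[IRanges]{IRanges} in the package-wide 1-based closed convention of
#' IRanges; they are disjoint, sorted, and tile the whole sequence.
#'
#' @slot id scaffold identifier.
#' @slot seq the sequence as a \link[Biostrings]{DNAString}.
#' @slot contigs \link[IRanges]{IRanges} of contig spans.
#' @slot gaps \link[IRanges]{IRanges} of gap spans.
#' @slot minGapLen the N-run length (bp) that breaks a contig.
#'
#' @exportClass Scaffold
setClass("Scaffold",
  representation(
    id = "character",
    seq = "DNAString",
    contigs = "IRanges",
    gaps = "IRanges",
    minGapLen = "integer"
  )
)

setValidity("Scaffold", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  len <- length(object@seq)
  all <- c(object@contigs, object@gaps)
  if (length(all)) {
    o <- order(IRanges::start(all))
    all <- all[o]
    if (sum(IRanges::width(all)) != len ||
        IRanges::start(all)[1L] != 1L ||
        IRanges::end(all)[length(all)] != len ||
        (length(all) > 1L &&
         any(IRanges::start(all)[-1L] != IRanges::end(all)[-length(all)] + 1L)))
      msg <- c(msg, "contig and gap spans must tile [1, length] disjointly")
  } else if (len > 0L) {
    msg <- c(msg, "non-empty sequence with no spans")
  }
  if (length(msg)) msg else TRUE
})

#' BuscoTable: parsed BUSCO full-table results for one assembly
#'
#' Holds one record per BUSCO full-table data line: the gene (ortholog) id,
#' its classification (Complete, Duplicated, Fragmented, Missing), and,
#' when placed, the carrier sequence, coordinates (1-based inclusive, as
#' printed by BUSCO), strand (v5 only), score and gene-model length.
#'
#' @slot assemblyName label for the assembly the table describes.
#' @slot dialect \code{"v3"} or \code{"v5"} full-table column layout.
#' @slot records data.frame with columns \code{busco_id}, \code{status},
#'   \code{seq_id}, \code{start}, \code{end}, \code{strand}, \code{score},
#'   \code{length}.
#'
#' @exportClass BuscoTable
setClass("BuscoTable",
  representation(
    assemblyName = "character",
    dialect = "character",
    records = "data.frame"
  )
)

.BUSCO_STATUSES <- c("Complete", "Duplicated", "Fragmented", "Missing")
.BUSCO_COLS <- c("busco_id", "status", "seq_id", "start", "end",
                 "strand", "score", "length")

setValidity("BuscoTable", function(object) {
  msg <- character(0)
  r <- object@records
  if (!all(.BUSCO_COLS %in% names(r)))
    msg <- c(msg, paste("records must have columns:",
                        paste(.BUSCO_COLS, collapse = ", ")))
  else {
    if (!all(r$status %in% .BUSCO_STATUSES))
      msg <- c(msg, "unknown status token in records")
    miss <- r$status == "Missing"
    if (any(miss & (!is.na(r$seq_id) | !is.na(r$start) | !is.na(r$end))))
      msg <- c(msg, "Missing records must have no location")
    ok <- !is.na(r$start) & !is.na(r$end)
    if (any(ok & r$start > r$end))
      msg <- c(msg, "start must be <= end when both present")
    key <- paste(r$busco_id, r$seq_id, r$start, r$end)
    if (anyDuplicated(key))
      msg <- c(msg, "(busco_id, seq_id, start, end) must be unique")
    dup <- r$busco_id[r$status == "Duplicated"]
    if (length(dup) && any(table(dup) < 2L))
      msg <- c(msg, "a Duplicated busco_id must appear at least twice")
  }
  if (!object@dialect %in% c("v3", "v5"))
    msg <- c(msg, "dialect must be 'v3' or 'v5'")
  if (length(msg)) msg else TRUE
})

#' SamplingSpec: parameters of a seeded coverage-targeted read subsample
#'
#' @slot genomeSize estimated genome size in bp; coverage is computed
#'   against this value, which is always supplied explicitly.
#' @slot targetCoverage target fold coverage (e.g. 70 for 70x).
#' @slot minLen,maxLen inclusive read-length window in bp (\code{maxLen}
#'   may be \code{Inf}).
#' @slot seed integer seed fixing the random draw completely.
#'
#' @exportClass SamplingSpec
setClass("SamplingSpec",
  representation(
    genomeSize = "numeric",
    targetCoverage = "numeric",
    minLen = "numeric",
    maxLen = "numeric",
    seed = "integer"
  )
)

setValidity("SamplingSpec", function(object) {
  msg <- character(0)
  if (object@genomeSize <= 0) msg <- c(msg, "genomeSize must be > 0")
  if (object@targetCoverage <= 0) msg <- c(msg, "targetCoverage must be > 0")
  if (object@minLen <= 0 || object@minLen > object@maxLen)
    msg <- c(msg, "need 0 < minLen <= maxLen")
  if (length(msg)) msg else TRUE
})

#' SampleResult: outcome of a coverage-targeted subsample
#'
#' @slot selectedIds read ids in selection order (distinct).
#' @slot totalBases total bases across selected reads.
#' @slot achievedCoverage \code{totalBases / genomeSize}.
#' @slot nEligible,nExcludedShort,nExcludedLong length-window accounting;
#'   the three partition the input read set.
#' @slot exhausted TRUE when the eligible pool ran out before the target.
#' @slot spec the \linkS4class{SamplingSpec} that produced the result.
#'
#' @exportClass SampleResult
setClass("SampleResult",
  representation(
    selectedIds = "character",
    totalBases = "numeric",
    achievedCoverage = "numeric",
    nEligible = "integer",
    nExcludedShort = "integer",
    nExcludedLong = "integer",
    exhausted = "logical",
    spec = "SamplingSpec"
  )
)

setValidity("SampleResult", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@selectedIds))
    msg <- c(msg, "selectedIds must be distinct")
  cov <- object@totalBases / object@spec@genomeSize
  if (!isTRUE(all.equal(cov, object@achievedCoverage)))
    msg <- c(msg, "achievedCoverage must equal totalBases / genomeSize")
  if (length(msg)) msg else TRUE
})

#' CorrectionReport: accounting of a cross-assembly gene-rescue run
#'
#' One row of \code{plans} per rescuable case (a gene fragmented in the
#' focal assembly with a complete single-copy donor), carrying the decision
#' status (\code{applied}, \code{skipped_orientation},
#' \code{skipped_no_anchor}, \code{skipped_neighbor_conflict},
#' \code{skipped_inconsistent}), the replaced focal interval, the donor
#' segment and the anchors. Genes with no complete donor anywhere are kept
#' in \code{unrescuable} so the identified-vs-total accounting is complete.
#'
#' @slot plans data.frame, one row per rescuable case.
#' @slot unrescuable data.frame of fragmented genes with no complete
#'   single-copy donor (reason \code{no_complete_donor}).
#' @slot lengthDelta named numeric: net bp change per edited scaffold.
#' @slot params list of run parameters (k, flankLen, minShared,
#'   minMatchFrac).
#'
#' @exportClass CorrectionReport
setClass("CorrectionReport",
  representation(
    plans = "data.frame",
    unrescuable = "data.frame",
    lengthDelta = "numeric",
    params = "list"
  )
)

.PLAN_STATUSES <- c("applied", "skipped_orientation", "skipped_no_anchor",
                    "skipped_neighbor_conflict", "skipped_inconsistent")

setValidity("CorrectionReport", function(object) {
  msg <- character(0)
  if (nrow(object@plans) && !all(object@plans$status %in% .PLAN_STATUSES))
    msg <- c(msg, "unknown plan status")
  if (length(msg)) msg else TRUE
})
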