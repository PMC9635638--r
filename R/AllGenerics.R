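#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
NULL

#' @export
setGeneric("scaffoldId", function(x) standardGeneric("scaffoldId"))
#' @export
setGeneric("scaffoldSeq", function(x) standardGeneric("scaffoldSeq"))
#' @export
setGeneric("contigSpans", function(x) standardGeneric("contigSpans"))
#' @export
setGeneric("gapSpans", function(x) standardGeneric("gapSpans"))

#' @export
setGeneric("assemblyName", function(x) standardGeneric("assemblyName"))
#' @export
setGeneric("buscoDialect", function(x) standardGeneric("buscoDialect"))
#' @export
setGeneric("buscoRecords", function(x) standardGeneric("buscoRecords"))
#' @export
setGeneric("buscoSummary", function(x) standardGeneric("buscoSummary"))

#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))
#' @export
setGeneric("achievedCoverage", function(x) standardGeneric("achievedCoverage"))

#' @export
setGeneric("replacementPlans", function(x) standardGeneric("replacementPlans"))
#' @export
setGeneric("unrescuableGenes", function(x) standardGeneric("unrescuableGenes"))
#' @export
setGeneric("casesIdentified", function(x) standardGeneric("casesIdentified"))
#' @export
setGeneric("statusCounts", function(x) standardGeneric("statusCounts"))

# ---- Scaffold accessors -----------------------------------------------------

#' @describeIn Scaffold-class scaffold identifier.
#' @param x a \code{Scaffold}.
#' @export
setMethod("scaffoldId", "Scaffold", function(x) x@id)

#' @describeIn Scaffold-class the sequence as a \code{DNAString}.
#' @export
setMethod("scaffoldSeq", "Scaffold", function(x) x@seq)

#' @describeIn Scaffold-class contig spans as \code{IRanges}.
#' @export
setMethod("contigSpans", "Scaffold", function(x) x@contigs)

#' @describeIn Scaffold-class gap spans as \code{IRanges}.
#' @export
setMethod("gapSpans", "Scaffold", function(x) x@gaps)

setMethod("show", "Scaffold", function(object) {
  cat("Scaffold '", object@id, "': ", length(object@seq), " bp, ",
      length(object@contigs), " contig(s), ", length(object@gaps),
      " gap(s) (minGapLen=", object@minGapLen, ")\n", sep = "")
})

# ---- BuscoTable accessors ---------------------------------------------------

#' @describeIn BuscoTable-class assembly label.
#' @param x a \code{BuscoTable}.
#' @export
setMethod("assemblyName", "BuscoTable", function(x) x@assemblyName)

#' @describeIn BuscoTable-class full-table dialect ("v3" or "v5").
#' @export
setMethod("buscoDialect", "BuscoTable", function(x) x@dialect)

#' @describeIn BuscoTable-class the per-line records as a data.frame.
#' @export
setMethod("buscoRecords", "BuscoTable", function(x) x@records)

setMethod("show", "BuscoTable", function(object) {
  s <- buscoSummary(object)
  cat("BuscoTable '", object@assemblyName, "' (", object@dialect, "): ",
      nrow(object@records), " records | C:", s[["C"]], " (S:", s[["CS"]],
      " D:", s[["CD"]], ") F:", s[["F"]], " M:", s[["M"]], "\n", sep = "")
})

# ---- SampleResult accessors -------------------------------------------------

#' @describeIn SampleResult-class read ids in selection order.
#' @param x a \code{SampleResult}.
#' @export
setMethod("selectedIds", "SampleResult", function(x) x@selectedIds)

#' @describeIn SampleResult-class achieved fold coverage.
#' @export
setMethod("achievedCoverage", "SampleResult", function(x) x@achievedCoverage)

setMethod("show", "SampleResult", function(object) {
  cat("SampleResult: ", length(object@selectedIds), " reads, ",
      format(object@totalBases, big.mark = ",", scientific = FALSE), " bp (",
      round(object@achievedCoverage, 2), "x of ",
      format(object@spec@genomeSize, big.mark = ",", scientific = FALSE), " bp; target ",
      object@spec@targetCoverage, "x)",
      if (object@exhausted) " [pool exhausted]" else "", "\n", sep = "")
})

# ---- CorrectionReport accessors ---------------------------------------------

#' @describeIn CorrectionReport-class one row per rescuable case.
#' @param x a \code{CorrectionReport}.
#' @export
setMethod("replacementPlans", "CorrectionReport", function(x) x@plans)

#' @describeIn CorrectionReport-class fragmented genes without any complete
#'   single-copy donor.
#' @export
setMethod("unrescuableGenes", "CorrectionReport", function(x) x@unrescuable)

#' @describeIn CorrectionReport-class number of rescuable cases identified
#'   (equals the sum of the per-status plan counts).
#' @export
setMethod("casesIdentified", "CorrectionReport", function(x) {
  nrow(x@plans)
})

#' @describeIn CorrectionReport-class named integer vector of plan counts by
#'   status, over all defined statuses.
#' @export
setMethod("statusCounts", "CorrectionReport", function(x) {
  counts <- setNames(integer(length(.PLAN_STATUSES)), .PLAN_STATUSES)
  if (nrow(x@plans)) {
    tab <- table(factor(x@plans$status, levels = .PLAN_STATUSES))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
})

setMethod("show", "CorrectionReport", function(object) {
  sc <- statusCounts(object)
  cat("CorrectionReport: ", casesIdentified(object), " case(s) identified (",
      paste(names(sc), sc, sep = "=", collapse = ", "), "); ",
      nrow(object@unrescuable), " unrescuable gene(s)\n", sep = "")
})
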