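#' Attribute duplicated BUSCO genes in a merged assembly to a mechanism
#'
#' After merging a long-read reference assembly with a short-read query
#' assembly, a gene can appear duplicated because one query sequence
#' merged with the reference into a hybrid while another query sequence
#' carrying the same genes failed to merge with that same reference and
#' survived alongside. This detector groups the merged table's duplicated
#' genes by their carrier set and labels each group:
#' \itemize{
#'   \item \code{merge_failure}: one carrier is a hybrid whose provenance
#'     contains a reference sequence bearing the genes, and another
#'     carrier is an unmerged query sequence bearing the same genes;
#'   \item \code{preexisting}: the genes were already duplicated in the
#'     reference table alone or the query table alone;
#'   \item \code{unknown}: anything else (including carriers absent from
#'     the provenance map, which raise a warning).
#' }
#'
#' @param mergedBusco \linkS4class{BuscoTable} of the merged assembly.
#' @param refBusco,queryBusco \linkS4class{BuscoTable}s of the two inputs.
#' @param provenance data.frame mapping merged sequences to their
#'   components: columns \code{merged_id}, \code{component_id},
#'   \code{source} (\code{"ref"} or \code{"query"}). An unmerged sequence
#'   carried through maps to itself.
#' @return data.frame with one row per duplicate case: comma-joined
#'   \code{busco_ids}, comma-joined \code{carrier_seq_ids},
#'   \code{mechanism}, and \code{n_genes}.
#' @export
detectMergeFailureDuplicates <- function(mergedBusco, refBusco, queryBusco,
                                         provenance) {
  stopifnot(methods::is(mergedBusco, "BuscoTable"),
            methods::is(refBusco, "BuscoTable"),
            methods::is(queryBusco, "BuscoTable"),
            all(c("merged_id", "component_id", "source") %in%
                names(provenance)))
  empty <- data.frame(busco_ids = character(0),
                      carrier_seq_ids = character(0),
                      mechanism = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
  mStatus <- .geneStatus(mergedBusco)
  dupIds <- names(mStatus)[mStatus == "Duplicated"]
  if (!length(dupIds)) return(empty)

  mr <- buscoRecords(mergedBusco)
  carriersOf <- function(id)
    sort(unique(mr$seq_id[mr$busco_id == id & !is.na(mr$seq_id)]))
  carrierKey <- vapply(dupIds, function(id)
    paste(carriersOf(id), collapse = ","), character(1))
  groups <- split(dupIds, carrierKey)

  refStatus <- .geneStatus(refBusco)
  qryStatus <- .geneStatus(queryBusco)
  rr <- buscoRecords(refBusco)
  qr <- buscoRecords(queryBusco)

  cases <- lapply(names(groups), function(key) {
    genes <- sort(groups[[key]])
    carriers <- strsplit(key, ",", fixed = TRUE)[[1L]]
    known <- carriers %in% provenance$merged_id
    if (!all(known)) {
      warning("carrier(s) ", paste(carriers[!known], collapse = ", "),
              " absent from provenance; mechanism set to unknown",
              call. = FALSE)
      mech <- "unknown"
    } else {
      comp <- function(cid) provenance[provenance$merged_id == cid, ,
                                       drop = FALSE]
      isHybridWithGenes <- vapply(carriers, function(cid) {
        p <- comp(cid)
        if (!any(p$source == "ref") || !any(p$source == "query"))
          return(FALSE)
        refComps <- p$component_id[p$source == "ref"]
        any(rr$busco_id %in% genes & rr$seq_id %in% refComps)
      }, logical(1))
      isUnmergedQueryWithGenes <- vapply(carriers, function(cid) {
        p <- comp(cid)
        if (!(nrow(p) == 1L && p$source == "query")) return(FALSE)
        any(qr$busco_id %in% genes & qr$seq_id %in% p$component_id)
      }, logical(1))
      mech <- if (any(isHybridWithGenes) && any(isUnmergedQueryWithGenes))
        "merge_failure"
      else if (any(refStatus[genes] == "Duplicated", na.rm = TRUE) ||
               any(qryStatus[genes] == "Duplicated", na.rm = TRUE))
        "preexisting"
      else "unknown"
    }
    data.frame(busco_ids = paste(genes, collapse = ","),
               carrier_seq_ids = key, mechanism = mech,
               n_genes = length(genes), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(cases, make.row.names = FALSE))
}
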