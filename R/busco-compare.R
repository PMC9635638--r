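#' Find fragmented genes rescuable from alternative assemblies
#'
#' Scans a focal BUSCO table for fragmented genes and, for each, looks for
#' an alternative assembly in which the same gene is complete and
#' single-copy (a duplicated donor copy is ambiguous and never used). When
#' several alternatives qualify, the donor with the highest BUSCO score
#' wins; ties are broken by the order the alternatives were supplied, so a
#' run is reproducible. Fragmented genes complete in no alternative are
#' returned separately with reason \code{no_complete_donor}, keeping the
#' identified-vs-total accounting intact.
#'
#' A gene id present in the focal table but absent from an alternative
#' table raises a warning and is treated as Missing there.
#'
#' @param focal the focal \linkS4class{BuscoTable}.
#' @param alternatives list of \linkS4class{BuscoTable}s for the donor
#'   assemblies, in priority order for tie-breaking.
#' @return a list with elements \code{cases} (data.frame, one row per
#'   rescuable gene: focal and donor locations, donor assembly, donor
#'   strand and score) and \code{unrescuable} (data.frame of fragmented
#'   genes with no eligible donor).
#' @export
findRescuableGenes <- function(focal, alternatives) {
  stopifnot(methods::is(focal, "BuscoTable"))
  if (methods::is(alternatives, "BuscoTable"))
    alternatives <- list(alternatives)
  stopifnot(all(vapply(alternatives, methods::is, logical(1), "BuscoTable")))

  emptyCases <- data.frame(
    busco_id = character(0), focal_seq_id = character(0),
    focal_start = integer(0), focal_end = integer(0),
    donor_assembly_name = character(0), donor_seq_id = character(0),
    donor_start = integer(0), donor_end = integer(0),
    donor_strand = character(0), donor_score = numeric(0),
    stringsAsFactors = FALSE)
  emptyUnresc <- data.frame(
    busco_id = character(0), focal_seq_id = character(0),
    focal_start = integer(0), focal_end = integer(0),
    reason = character(0), stringsAsFactors = FALSE)

  focalStatus <- .geneStatus(focal)
  fragIds <- sort(names(focalStatus)[focalStatus == "Fragmented"])
  if (!length(fragIds))
    return(list(cases = emptyCases, unrescuable = emptyUnresc))

  altStatus <- lapply(alternatives, .geneStatus)
  for (i in seq_along(alternatives)) {
    missing <- setdiff(names(focalStatus), names(altStatus[[i]]))
    if (length(missing))
      warning(length(missing), " focal gene id(s) absent from alternative '",
              assemblyName(alternatives[[i]]), "'; treated as Missing there",
              call. = FALSE)
  }

  fr <- buscoRecords(focal)
  focalLoc <- function(id) {
    rows <- fr[fr$busco_id == id & fr$status == "Fragmented", , drop = FALSE]
    if (!nrow(rows))
      rows <- fr[fr$busco_id == id, , drop = FALSE]
    rows[order(-ifelse(is.na(rows$score), -Inf, rows$score)), ][1L, ]
  }

  cases <- list(); unresc <- list()
  for (id in fragIds) {
    floc <- focalLoc(id)
    best <- NULL
    for (i in seq_along(alternatives)) {
      st <- altStatus[[i]]
      if (!id %in% names(st) || st[[id]] != "Complete") next
      ar <- buscoRecords(alternatives[[i]])
      drow <- ar[ar$busco_id == id & ar$status == "Complete", , drop = FALSE][1L, ]
      score <- if (is.na(drow$score)) -Inf else drow$score
      # strict > keeps the earliest alternative on ties
      if (is.null(best) || score > best$score)
        best <- list(i = i, row = drow, score = score)
    }
    if (is.null(best)) {
      unresc[[id]] <- data.frame(
        busco_id = id, focal_seq_id = floc$seq_id,
        focal_start = floc$start, focal_end = floc$end,
        reason = "no_complete_donor", stringsAsFactors = FALSE)
    } else {
      cases[[id]] <- data.frame(
        busco_id = id, focal_seq_id = floc$seq_id,
        focal_start = floc$start, focal_end = floc$end,
        donor_assembly_name = assemblyName(alternatives[[best$i]]),
        donor_seq_id = best$row$seq_id,
        donor_start = best$row$start, donor_end = best$row$end,
        donor_strand = if (is.na(best$row$strand)) "+" else best$row$strand,
        donor_score = best$row$score, stringsAsFactors = FALSE)
    }
  }
  list(
    cases = if (length(cases)) do.call(rbind, c(cases, make.row.names = FALSE))
            else emptyCases,
    unrescuable = if (length(unresc))
            do.call(rbind, c(unresc, make.row.names = FALSE))
            else emptyUnresc
  )
}

.STATUS_LETTER <- c(Complete = "C", Duplicated = "D",
                    Fragmented = "F", Missing = "M")

#' Compare two BUSCO tables gene by gene
#'
#' Reports one event per gene whose classification, reported gene-model
#' length, or carrier sequence differs between the two tables — e.g. an
#' assembly and its reverse complement, where fragmented genes can flip to
#' complete with an accompanying length change. Identical tables give an
#' empty result.
#'
#' @param a,b \linkS4class{BuscoTable}s over the same gene universe.
#' @return data.frame with one row per changed gene: statuses, lengths,
#'   carrier seq_ids before (\code{a}) and after (\code{b}),
#'   \code{length_delta}, and a compact \code{transition} label such as
#'   \code{"F->C"}. Use \code{table(events$transition)} for the summary
#'   counts by transition.
#' @export
compareReclassification <- function(a, b) {
  stopifnot(methods::is(a, "BuscoTable"), methods::is(b, "BuscoTable"))
  sa <- .geneStatus(a); sb <- .geneStatus(b)
  ids <- sort(union(names(sa), names(sb)))
  repLoc <- function(tab, id) {
    r <- buscoRecords(tab)
    rows <- r[r$busco_id == id, , drop = FALSE]
    if (!nrow(rows))
      return(list(len = NA_integer_, seq = NA_character_))
    rows <- rows[order(match(rows$status, .BUSCO_STATUSES),
                       -ifelse(is.na(rows$score), -Inf, rows$score)), ]
    list(len = rows$length[1L], seq = rows$seq_id[1L])
  }
  events <- lapply(ids, function(id) {
    stA <- if (id %in% names(sa)) sa[[id]] else "Missing"
    stB <- if (id %in% names(sb)) sb[[id]] else "Missing"
    la <- repLoc(a, id); lb <- repLoc(b, id)
    same <- stA == stB &&
      identical(la$len, lb$len) &&
      ((is.na(la$seq) && is.na(lb$seq)) ||
       (!is.na(la$seq) && !is.na(lb$seq) && la$seq == lb$seq))
    if (same) return(NULL)
    data.frame(
      busco_id = id,
      status_before = stA, status_after = stB,
      length_before = la$len, length_after = lb$len,
      length_delta = ifelse(is.na(la$len) | is.na(lb$len),
                            NA_integer_, lb$len - la$len),
      seq_id_before = la$seq, seq_id_after = lb$seq,
      transition = paste0(.STATUS_LETTER[[stA]], "->", .STATUS_LETTER[[stB]]),
      stringsAsFactors = FALSE)
  })
  events <- events[!vapply(events, is.null, logical(1))]
  if (!length(events))
    return(data.frame(
      busco_id = character(0), status_before = character(0),
      status_after = character(0), length_before = integer(0),
      length_after = integer(0), length_delta = integer(0),
      seq_id_before = character(0), seq_id_after = character(0),
      transition = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(events, make.row.names = FALSE))
}
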