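#' Construct a BuscoTable from records
#'
#' Programmatic constructor used by the parsers and the synthetic-data
#' generators. Missing columns are filled with NA; coordinates are the
#' 1-based inclusive positions as printed by BUSCO.
#'
#' @param records data.frame with (a subset of) columns \code{busco_id},
#'   \code{status}, \code{seq_id}, \code{start}, \code{end}, \code{strand},
#'   \code{score}, \code{length}.
#' @param assemblyName label for the assembly.
#' @param dialect \code{"v3"} or \code{"v5"}.
#' @return a \linkS4class{BuscoTable}.
#' @export
BuscoTable <- function(records, assemblyName = "assembly", dialect = "v3") {
  full <- data.frame(
    busco_id = character(0), status = character(0), seq_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    score = numeric(0), length = integer(0), stringsAsFactors = FALSE
  )
  if (nrow(records)) {
    for (col in .BUSCO_COLS)
      if (is.null(records[[col]]))
        records[[col]] <- rep(methods::as(NA, class(full[[col]])),
                              nrow(records))
    records <- records[, .BUSCO_COLS]
    records$start <- as.integer(records$start)
    records$end <- as.integer(records$end)
    records$score <- as.numeric(records$score)
    records$length <- as.integer(records$length)
    full <- records
  }
  rownames(full) <- NULL
  methods::new("BuscoTable", assemblyName = assemblyName,
               dialect = dialect, records = full)
}

#' Parse a BUSCO full_table TSV
#'
#' Reads the per-gene \code{full_table.tsv} that BUSCO writes, accepting
#' both the v3 column layout (Busco id, Status, Contig, Start, End, Score,
#' Length) and the v5 layout (Busco id, Status, Sequence, Gene Start,
#' Gene End, Strand, Score, Length, ...). The dialect is auto-detected
#' from the commented header and can be forced. BUSCO's 1-based inclusive
#' coordinates are kept as printed.
#'
#' @param path path to a full_table TSV (may be gzipped).
#' @param dialect \code{"auto"} (default), \code{"v3"} or \code{"v5"}.
#' @param assemblyName label for the assembly; defaults to the file name.
#' @return a \linkS4class{BuscoTable}.
#' @export
parseBuscoFullTable <- function(path, dialect = c("auto", "v3", "v5"),
                                assemblyName = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(assemblyName))
    assemblyName <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  isComment <- startsWith(lines, "#")
  header <- lines[isComment]
  if (dialect == "auto") {
    colLine <- grep("Busco id", header, ignore.case = TRUE, value = TRUE)
    dialect <- if (length(colLine) &&
                   grepl("Gene Start|Strand|Sequence", colLine[1L]))
      "v5" else "v3"
  }
  dataLines <- lines[!isComment & nzchar(lines)]
  if (!length(dataLines))
    return(BuscoTable(data.frame(), assemblyName, dialect))
  fields <- strsplit(dataLines, "\t", fixed = TRUE)
  recs <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    lineNo <- which(!isComment & nzchar(lines))[i]
    if (length(f) < 2L)
      stop("line ", lineNo, " of '", path, "': fewer than 2 fields",
           call. = FALSE)
    status <- f[2L]
    if (!status %in% .BUSCO_STATUSES)
      stop("line ", lineNo, " of '", path, "': unknown status token '",
           status, "'", call. = FALSE)
    get <- function(j) if (length(f) >= j && nzchar(f[j])) f[j] else NA
    if (dialect == "v5") {
      out <- list(busco_id = f[1L], status = status, seq_id = get(3L),
                  start = get(4L), end = get(5L), strand = get(6L),
                  score = get(7L), length = get(8L))
    } else {
      out <- list(busco_id = f[1L], status = status, seq_id = get(3L),
                  start = get(4L), end = get(5L), strand = NA,
                  score = get(6L), length = get(7L))
    }
    for (cc in c("start", "end", "length")) {
      if (!is.na(out[[cc]])) {
        v <- suppressWarnings(as.numeric(out[[cc]]))
        if (is.na(v) || v != round(v))
          stop("line ", lineNo, " of '", path, "': non-integer ", cc,
               " '", out[[cc]], "'", call. = FALSE)
        out[[cc]] <- as.integer(v)
      } else out[[cc]] <- NA_integer_
    }
    out$score <- if (is.na(out$score)) NA_real_ else as.numeric(out$score)
    out$seq_id <- as.character(out$seq_id)
    out$strand <- as.character(out$strand)
    out
  })
  records <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  BuscoTable(records, assemblyName, dialect)
}

#' Write a BuscoTable as a BUSCO-style full_table TSV
#'
#' Emits the column layout of the table's dialect, with a commented header
#' line, so generated tables round-trip through
#' \code{\link{parseBuscoFullTable}}.
#'
#' @param table a \linkS4class{BuscoTable}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBuscoFullTable <- function(table, path) {
  stopifnot(methods::is(table, "BuscoTable"))
  r <- buscoRecords(table)
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  if (buscoDialect(table) == "v5") {
    header <- "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength"
    body <- paste(r$busco_id, r$status, fmt(r$seq_id), fmt(r$start),
                  fmt(r$end), fmt(r$strand), fmt(r$score), fmt(r$length),
                  sep = "\t")
  } else {
    header <- "# Busco id\tStatus\tContig\tStart\tEnd\tScore\tLength"
    body <- paste(r$busco_id, r$status, fmt(r$seq_id), fmt(r$start),
                  fmt(r$end), fmt(r$score), fmt(r$length), sep = "\t")
  }
  body <- sub("\t+$", "", body)   # Missing lines carry no location fields
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Summarize a BuscoTable into C/CS/CD/F/M counts
#'
#' Counts distinct genes per class: \code{CS} complete single-copy,
#' \code{CD} complete duplicated (a gene with two or more Complete or
#' Duplicated placements counts once), \code{C = CS + CD}, \code{F}
#' fragmented, \code{M} missing.
#'
#' @param x a \linkS4class{BuscoTable}.
#' @return named integer vector with elements C, CS, CD, F, M.
#' @export
setMethod("buscoSummary", "BuscoTable", function(x) {
  r <- buscoRecords(x)
  if (!nrow(r))
    return(c(C = 0L, CS = 0L, CD = 0L, F = 0L, M = 0L))
  byGene <- split(r$status, r$busco_id)
  klass <- vapply(byGene, function(st) {
    if (any(st == "Duplicated") || sum(st == "Complete") >= 2L) "CD"
    else if (any(st == "Complete")) "CS"
    else if (any(st == "Fragmented")) "F"
    else "M"
  }, character(1))
  cs <- sum(klass == "CS"); cd <- sum(klass == "CD")
  c(C = cs + cd, CS = cs, CD = cd,
    F = sum(klass == "F"), M = sum(klass == "M"))
})

# Status of each distinct gene in a table, as a named character vector.
# A gene is "Complete" only when single-copy; two or more Complete
# placements, or any Duplicated record, make it "Duplicated".
.geneStatus <- function(table) {
  r <- buscoRecords(table)
  if (!nrow(r)) return(setNames(character(0), character(0)))
  byGene <- split(r$status, r$busco_id)
  vapply(byGene, function(st) {
    if (any(st == "Duplicated") || sum(st == "Complete") >= 2L) "Duplicated"
    else if (any(st == "Complete")) "Complete"
    else if (any(st == "Fragmented")) "Fragmented"
    else "Missing"
  }, character(1))
}
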