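#' Parse pairwise alignments from PAF or nucmer show-coords output
#'
#' Normalizes both formats to one block table: 0-based half-open
#' coordinates with query coordinates on the query's forward strand (PAF
#' already reports them that way; show-coords reports a minus-strand hit
#' with reversed query coordinates, which are swapped here). Identity
#' comes from PAF matches/alignment-length or from the coords %IDY column.
#'
#' @param path alignment file.
#' @param format \code{"auto"}, \code{"paf"} (12+ tab columns) or
#'   \code{"coords"} (tab-separated \code{show-coords -T} output:
#'   S1 E1 S2 E2 LEN1 LEN2 \%IDY ... REF QUERY).
#' @return data.frame with columns \code{ref_id}, \code{query_id},
#'   \code{ref_start}, \code{ref_end}, \code{query_start},
#'   \code{query_end}, \code{strand}, \code{identity_pct},
#'   \code{block_len}.
#' @export
parseAlignments <- function(path, format = c("auto", "paf", "coords")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(
    ref_id = character(0), query_id = character(0),
    ref_start = integer(0), ref_end = integer(0),
    query_start = integer(0), query_end = integer(0),
    strand = character(0), identity_pct = numeric(0),
    block_len = integer(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    f1 <- fields[[1L]]
    format <- if (length(f1) >= 12L && f1[5L] %in% c("+", "-"))
      "paf" else "coords"
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    bad <- function(why) stop("line ", i, " of '", path, "': ", why,
                              call. = FALSE)
    if (format == "paf") {
      if (length(f) < 12L) bad("PAF needs at least 12 columns")
      if (!f[5L] %in% c("+", "-")) bad("invalid strand column")
      num <- suppressWarnings(as.numeric(f[c(2:4, 7:11)]))
      if (anyNA(num)) bad("non-numeric coordinate field")
      qs <- num[2L]; qe <- num[3L]; ts <- num[5L]; te <- num[6L]
      nmatch <- num[7L]; alen <- num[8L]
      if (qs >= qe || ts >= te) bad("start must be < end")
      data.frame(ref_id = f[6L], query_id = f[1L],
                 ref_start = as.integer(ts), ref_end = as.integer(te),
                 query_start = as.integer(qs), query_end = as.integer(qe),
                 strand = f[5L],
                 identity_pct = 100 * nmatch / alen,
                 block_len = as.integer(alen), stringsAsFactors = FALSE)
    } else {
      # show-coords -T: skip header/separator lines without 7 leading
      # numeric fields
      num <- suppressWarnings(as.numeric(f[seq_len(min(7L, length(f)))]))
      if (length(f) < 9L || anyNA(num)) {
        if (i <= 4L) return(NULL)        # coords preamble
        bad("expected 7 numeric fields then ref and query ids")
      }
      s1 <- num[1L]; e1 <- num[2L]; s2 <- num[3L]; e2 <- num[4L]
      idy <- num[7L]
      strand <- if (e2 < s2) "-" else "+"
      qs <- min(s2, e2); qe <- max(s2, e2)
      data.frame(ref_id = f[length(f) - 1L], query_id = f[length(f)],
                 ref_start = as.integer(min(s1, e1) - 1L),
                 ref_end = as.integer(max(s1, e1)),
                 query_start = as.integer(qs - 1L),
                 query_end = as.integer(qe),
                 strand = strand,
                 identity_pct = idy,
                 block_len = as.integer(num[5L]), stringsAsFactors = FALSE)
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Filter alignment blocks on identity and length
#'
#' Keeps a block iff \code{identity_pct >= minIdentityPct} and
#' \code{block_len >= minAlignLen} — both thresholds inclusive, in the
#' spirit of delta-filter's \code{-i}/\code{-l} sweep (0, 1000, 5000,
#' 10000 are the usual length presets).
#'
#' @param blocks data.frame from \code{\link{parseAlignments}}.
#' @param minIdentityPct minimum percent identity (default 95).
#' @param minAlignLen minimum alignment length in bp (default 0).
#' @return the retained blocks.
#' @export
filterAlignments <- function(blocks, minIdentityPct = 95, minAlignLen = 0) {
  blocks[blocks$identity_pct >= minIdentityPct &
         blocks$block_len >= minAlignLen, , drop = FALSE]
}

#' OVL/n-OVL merge-decision assessment for one ref-query pair
#'
#' Diagnostic model of the overlap-ratio rule that gates contig merging in
#' hybrid assembly: OVL is the union length of the aligned query
#' intervals, the aligned extent runs from the first to the last aligned
#' query base, n-OVL is the extent minus OVL, and the pair is merged iff
#' \code{OVL / n-OVL >= ratioThreshold} (ratio \code{Inf} when n-OVL is
#' 0). A single distant spurious block inflates the extent, producing a
#' falsely high n-OVL and a merge failure — the documented failure mode
#' this diagnostic reproduces.
#'
#' @param blocks alignment blocks, all sharing one (ref_id, query_id).
#' @param ratioThreshold merge threshold on OVL/n-OVL (default 1.5; a
#'   ratio below it fails).
#' @param refLen,queryLen optional sequence lengths, carried into the
#'   result for reporting.
#' @return one-row data.frame: \code{ref_id}, \code{query_id},
#'   \code{ovl_bp}, \code{novl_bp}, \code{ratio}, \code{merge_decision},
#'   \code{n_blocks}, \code{ref_len}, \code{query_len}.
#' @export
assessOverlap <- function(blocks, ratioThreshold = 1.5,
                          refLen = NA_integer_, queryLen = NA_integer_) {
  if (is.null(blocks) || nrow(blocks) == 0L)
    stop("assessOverlap needs at least one alignment block", call. = FALSE)
  if (length(unique(blocks$ref_id)) != 1L ||
      length(unique(blocks$query_id)) != 1L)
    stop("all blocks must share one (ref_id, query_id) pair", call. = FALSE)
  # query intervals, 0-based half-open -> IRanges closed
  ir <- IRanges::IRanges(blocks$query_start + 1L, blocks$query_end)
  ovl <- sum(IRanges::width(IRanges::reduce(ir)))
  extent <- max(blocks$query_end) - min(blocks$query_start)
  novl <- extent - ovl
  ratio <- if (novl == 0L) Inf else ovl / novl
  data.frame(
    ref_id = blocks$ref_id[1L], query_id = blocks$query_id[1L],
    ovl_bp = ovl, novl_bp = novl, ratio = ratio,
    merge_decision = ratio >= ratioThreshold,
    n_blocks = nrow(blocks),
    ref_len = refLen, query_len = queryLen,
    stringsAsFactors = FALSE)
}

#' Assess every ref-query pair in a block table
#'
#' @param blocks data.frame from \code{\link{parseAlignments}} (typically
#'   after \code{\link{filterAlignments}}).
#' @param ratioThreshold merge threshold on OVL/n-OVL.
#' @return data.frame with one \code{\link{assessOverlap}} row per pair.
#' @export
assessAllOverlaps <- function(blocks, ratioThreshold = 1.5) {
  key <- paste(blocks$ref_id, blocks$query_id, sep = "\r")
  parts <- split(blocks, key)
  do.call(rbind, c(unname(lapply(parts, assessOverlap,
                                 ratioThreshold = ratioThreshold)),
                   make.row.names = FALSE))
}
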