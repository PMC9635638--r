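#' Read assembly or read sequences from FASTA/FASTQ
#'
#' Reads a FASTA or FASTQ file (plain or gzip-compressed, detected
#' transparently) into a named \link[Biostrings]{DNAStringSet}. Sequences
#' are normalized to the strict {A,C,G,T,N} alphabet: lowercase is
#' uppercased, U is mapped to T, and any other character is an error
#' (silent masking hides real problems in assembly forensics). FASTQ
#' quality strings are retained in \code{mcols(x)$quality} so a subsample
#' can be re-written as FASTQ, but no operation in the package interprets
#' them. Record descriptions (text after the first whitespace in the
#' header) are kept in \code{mcols(x)$description}.
#'
#' @param path path to the sequence file.
#' @param format \code{"auto"} (default; decided by extension, falling
#'   back to the first record character), \code{"fasta"} or \code{"fastq"}.
#' @return a \code{DNAStringSet} named by record id (first header token),
#'   in file order, with \code{mcols} columns \code{description} and
#'   \code{quality} (NA for FASTA input).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a toy record", "acgtn"), tf)
#' readSequences(tf)
#' @export
readSequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .sniffFormat(path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) {
      stop("malformed ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("record ", which(!nzchar(ids))[1L], " in '", path,
         "' has an empty id", call. = FALSE)
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stop("duplicate sequence id '", d, "' in '", path, "'", call. = FALSE)
  }
  if (any(BiocGenerics::width(raw) == 0L))
    stop("record '", ids[BiocGenerics::width(raw) == 0L][1L],
         "' has an empty sequence", call. = FALSE)
  seqs <- .normalizeSeq(as.character(raw), what = ids)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  qual <- if (format == "fastq") {
    q <- tryCatch(as.character(mcols(raw)$qualities), error = function(e)
      stop("malformed fastq file '", path, "': bad quality lines",
           call. = FALSE))
    if (any(nchar(q) != nchar(seqs)))
      stop("malformed fastq file '", path, "': quality length differs ",
           "from sequence length (record '",
           ids[which(nchar(q) != nchar(seqs))[1L]], "')", call. = FALSE)
    q
  } else rep(NA_character_, length(out))
  mcols(out) <- DataFrame(description = desc, quality = qual)
  out
}

.sniffFormat <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    return("fastq")
  if (grepl("\\.(fa|fasta|fna|ffn)(\\.gz)?$", path, ignore.case = TRUE))
    return("fasta")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (!length(first)) return("fasta")        # empty file: empty FASTA
  if (startsWith(first, "@")) "fastq" else "fasta"
}

#' Write sequences as FASTA
#'
#' Round-trip contract: \code{readSequences(writeFasta(x))} reproduces ids
#' and sequences exactly.
#'
#' @param x a named \code{DNAStringSet} (or coercible character vector).
#' @param path output path; a \code{.gz} suffix triggers gzip compression.
#' @param lineWidth sequence line width in the output (default 60).
#' @return the output path, invisibly.
#' @export
writeFasta <- function(x, path, lineWidth = 60L) {
  x <- .asSeqSet(x)
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              width = as.integer(lineWidth),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences as FASTQ
#'
#' Qualities come from \code{mcols(x)$quality} when present (as retained by
#' \code{\link{readSequences}}); records without a stored quality get a
#' constant maximal placeholder ("I" = Q40).
#'
#' @inheritParams writeFasta
#' @return the output path, invisibly.
#' @export
writeFastq <- function(x, path) {
  x <- .asSeqSet(x)
  qual <- mcols(x)$quality
  if (is.null(qual)) qual <- rep(NA_character_, length(x))
  qual <- ifelse(is.na(qual),
                 vapply(BiocGenerics::width(x),
                        function(w) strrep("I", w), character(1)),
                 qual)
  stopifnot(all(nchar(qual) == BiocGenerics::width(x)))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  # records are written directly (4 lines each): long-read records exceed
  # the record size the installed FASTQ serializer supports
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(x)) {
    lines <- rbind(paste0("@", names(x)), as.character(x), "+", qual)
    writeLines(as.vector(lines), con)
  }
  invisible(path)
}

.asSeqSet <- function(x) {
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(.normalizeSeq(unname(x)))
    names(out) <- names(x)
    x <- out
  }
  if (!methods::is(x, "DNAStringSet"))
    stop("expected a DNAStringSet or named character vector", call. = FALSE)
  if (is.null(names(x)) && length(x))
    stop("sequences must be named", call. = FALSE)
  x
}
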